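# Trace selection, HMM segmentation, dwell times and lifetimes, classification.

test_that("a noiseless single-bleach trace is accepted with the right range", {
  cfg <- generator_config(noise_sd = 0, donor_bleach_rate = 0,
                          acceptor_bleach_rate = 0.01, trace_length = 500,
                          state_emission = list(U = c(0.4, 0)))
  p <- data.frame(state = "U", entry_time = 0)
  tr <- withr::with_seed(61, {
    repeat {
      t0 <- render_trace(p, cfg, seed = sample.int(2^31 - 1, 1))
      bf <- t0$truth$acceptor_bleach_frame
      if (is.finite(bf) && bf > 20 && bf < 2400) break
    }
    t0
  })
  sel <- select_traces(tr)
  expect_true(sel$accepted[1])
  expect_equal(sel$usable_range[[1]][2],
               as.integer(tr$truth$acceptor_bleach_frame - 1))
})

test_that("two acceptor bleaching steps cause rejection", {
  cfg <- generator_config(noise_sd = 10, donor_bleach_rate = 0,
                          acceptor_bleach_rate = 0.005, trace_length = 500,
                          acceptor_copies = 2,
                          state_emission = list(U = c(0.4, 0.02)))
  p <- data.frame(state = "U", entry_time = 0)
  tr <- withr::with_seed(62, {
    repeat {
      t0 <- render_trace(p, cfg, seed = sample.int(2^31 - 1, 1))
      aa <- t0$frames$F_AA
      lev <- round((aa - 50) / cfg$total_intensity)
      # require both copies to bleach well inside the trace, separated
      if (lev[1] == 2 && lev[length(lev)] == 0 &&
          sum(lev == 1) > 100 && sum(lev == 2) > 100) break
    }
    t0
  })
  expect_false(select_traces(tr)$accepted[1])
})

test_that("a bleach-free trace is accepted over its full length", {
  cfg <- generator_config(noise_sd = 20, donor_bleach_rate = 0,
                          acceptor_bleach_rate = 0, trace_length = 200,
                          state_emission = list(U = c(0.4, 0.03)))
  tr <- render_trace(data.frame(state = "U", entry_time = 0), cfg, seed = 63)
  sel <- select_traces(tr)
  expect_true(sel$accepted[1])
  expect_equal(sel$usable_range[[1]], c(1L, nrow(tr$frames)))
})

test_that("a constant trace yields a single-state model", {
  r <- fit_hmm(rep(0.4, 100), max_states = 4)
  expect_equal(r$n_states, 1L)
  expect_equal(r$state_means, 0.4)
  expect_true(all(r$state_path == 1L))
})

test_that("two well-separated states are recovered with accurate decoding", {
  sim <- sim_discrete_trace(c(0.2, 0.8), 0.05, n_frames = 2500,
                            mean_dwell = 20, seed = 64)
  r <- fit_hmm(sim$E, max_states = 4, seed = 1)
  expect_equal(r$n_states, 2L)
  expect_lt(max(abs(r$state_means - c(0.2, 0.8))), 0.02)
  expect_gte(mean(r$state_path == sim$path), 0.95)
  # invariants of the fitted object
  expect_true(all(abs(rowSums(r$transition_matrix) - 1) < 1e-9))
  expect_true(!is.unsorted(r$state_means))
  expect_true(all(r$state_path <= r$n_states))
})

test_that("four states at the observed efficiencies are recovered", {
  truth <- c(0.2, 0.4, 0.6, 0.8)
  sim <- sim_discrete_trace(truth, 0.05, n_frames = 2500,
                            mean_dwell = 20, seed = 65)
  r <- fit_hmm(sim$E, max_states = 6, seed = 1)
  expect_equal(r$n_states, 4L)
  expect_lt(max(abs(r$state_means - truth)), 0.03)
})

test_that("model selection finds the true state count on separated data", {
  truth <- c(0.2, 0.8)
  hits <- vapply(1:30, function(s) {
    sim <- sim_discrete_trace(truth, 0.05, n_frames = 800,
                              mean_dwell = 15, seed = 600 + s)
    fit_hmm(sim$E, max_states = 4, seed = 1)$n_states == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("relabelling HMM states leaves dwells and classification unchanged", {
  sim <- sim_discrete_trace(c(0.2, 0.8), 0.05, n_frames = 1500,
                            mean_dwell = 25, seed = 66)
  r <- fit_hmm(sim$E, max_states = 3, seed = 1)
  d <- extract_dwells(r, frame_time = 0.2)
  # permute the decoded labels and state metadata consistently
  perm <- c(2L, 1L)
  r2 <- r
  r2$state_means <- r$state_means[perm]
  r2$state_sds <- r$state_sds[perm]
  r2$state_path <- match(r$state_path, perm)
  d2 <- extract_dwells(r2, frame_time = 0.2)
  expect_equal(d2$duration_s, d$duration_s)
  expect_equal(d2$state_mean, d$state_mean)
  expect_equal(classify_trace(r2)$group, classify_trace(r)$group)
})

test_that("dwell extraction run-length encodes the decoded path", {
  r <- fake_hmm(c(1, 1, 1, 2, 2, 1), means = c(0.2, 0.8))
  d <- extract_dwells(r)
  expect_equal(d$duration_s, c(0.6, 0.4, 0.2))
  expect_equal(d$state, c(1, 2, 1))
  expect_equal(d$censored_left, c(TRUE, FALSE, FALSE))
  expect_equal(d$censored_right, c(FALSE, FALSE, TRUE))
  # single-state path: one fully censored dwell
  d1 <- extract_dwells(fake_hmm(rep(1, 10), means = 0.4))
  expect_equal(nrow(d1), 1L)
  expect_true(d1$censored_left && d1$censored_right)
})

test_that("uncensored exponential dwells average to the true lifetime", {
  d <- withr::with_seed(67, dwell_set(state = 1, duration_s = rexp(10000, 0.5)))
  est <- fit_dwell_lifetime(d, 1)
  se <- sd(d$duration_s) / sqrt(nrow(d))
  expect_lt(abs(est$lifetime - 2), 3 * se)
})

test_that("lifetime estimators agree and recover simulated lifetimes", {
  expect_equal(fit_dwell_lifetime(dwell_set(1, rep(2, 10)), 1)$lifetime, 2)
  d <- withr::with_seed(68, {
    dwell_set(state = 1, duration_s = 0.2 * pmax(1, round(rexp(1000, 1 / 5) / 0.2)))
  })
  mle <- fit_dwell_lifetime(d, 1, method = "mle")
  expect_lt(abs(mle$lifetime - 5) / 5, 0.1)
  hist_fit <- fit_dwell_lifetime(d, 1, method = "histogram", bin_width = 0.6)
  joint_se <- sqrt(mle$se^2 + hist_fit$se^2)
  expect_lt(abs(mle$lifetime - hist_fit$lifetime), 2 * joint_se)
  expect_error(fit_dwell_lifetime(dwell_set(1, rep(1, 5)), 1), "at least 10")
})

test_that("traces are classified by their highest visited state", {
  low <- fake_hmm(c(rep(1, 30), rep(2, 30)), means = c(0.2, 0.4))
  expect_equal(classify_trace(low)$group, "low")
  high <- fake_hmm(c(rep(1, 30), rep(2, 30)), means = c(0.4, 0.8))
  expect_equal(classify_trace(high)$group, "high")
  # direct lowest-to-highest jump sets the flag
  direct <- fake_hmm(c(rep(1, 30), rep(3, 30)), means = c(0.2, 0.4, 0.8))
  cl <- classify_trace(direct)
  expect_equal(cl$group, "high")
  expect_true(cl$has_direct_low_high_transition)
  # passing through the intermediate does not
  stepped <- fake_hmm(c(rep(1, 20), rep(2, 20), rep(3, 20)),
                      means = c(0.2, 0.4, 0.8))
  expect_false(classify_trace(stepped)$has_direct_low_high_transition)
  # an infinite threshold classifies everything low
  expect_equal(classify_trace(high, threshold = Inf)$group, "low")
})

test_that("dwell CSV export flattens per-trace dwell sets", {
  d1 <- extract_dwells(fake_hmm(c(1, 1, 2, 2, 2, 1), means = c(0.2, 0.8)))
  d2 <- extract_dwells(fake_hmm(c(2, 2, 1), means = c(0.3, 0.7)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dwells(list(d1, d2), path)
  x <- read.csv(path)
  expect_equal(nrow(x), nrow(d1) + nrow(d2))
  expect_equal(unique(x$trace_id), c(1, 2))
  expect_equal(x$duration_s[x$trace_id == 1], d1$duration_s)
})

test_that("HMM segmentations serialise to JSON with an RLE path", {
  sim <- sim_discrete_trace(c(0.2, 0.8), 0.05, n_frames = 400,
                            mean_dwell = 25, seed = 70)
  r <- fit_hmm(sim$E, max_states = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(r, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$n_states, r$n_states)
  expect_equal(x$state_means, r$state_means, tolerance = 1e-12)
  expect_equal(rep(x$path_rle$states, x$path_rle$lengths), r$state_path)
})
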