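# Synthetic trace generator: CTMC paths, trace rendering, time-course ensembles.

test_that("an absorbing start yields a single path segment", {
  m0 <- kinetic_model(0, 0, 0, 0)
  p <- sample_ctmc_path(m0, t_max = 10, initial_state = "U", seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$state, "U")
  expect_equal(p$entry_time, 0)
})

test_that("unknown initial state is reported by name", {
  expect_error(sample_ctmc_path(fix_model(), 10, initial_state = "Z"), "'Z'")
})

test_that("holding times are exponential with the model's exit rate", {
  # two-state chain, k = 1/s both ways: mean U-holding time 1 s
  Q <- two_state_Q(1, 1)
  holds <- withr::with_seed(5, {
    unlist(lapply(1:2000, function(i) {
      p <- sample_ctmc_path(Q, t_max = 100)
      ends <- c(p$entry_time[-1], 100)
      (ends - p$entry_time)[p$state == "U" & ends < 100]
    }))
  })
  se <- sd(holds) / sqrt(length(holds))
  expect_lt(abs(mean(holds) - 1.0), 3 * se)
})

test_that("first nucleation is equidistributed over the five positions", {
  m <- fix_model(k_f = 5, k_u = 1e-4)
  first <- withr::with_seed(6, {
    vapply(1:10000, function(i) {
      p <- sample_ctmc_path(m, t_max = 50)
      p$state[2]
    }, character(1))
  })
  counts <- table(factor(first, levels = paste0("P", 2:6)))
  pval <- chisq.test(counts, p = rep(1 / 5, 5))$p.value
  expect_gt(pval, 0.01)
})

test_that("empirical per-transition rates match the generator matrix", {
  m <- fix_model(k_f = 0.5, k_u = 0.2, k_f2 = 0.8, k_u2 = 0.3)
  Q <- rate_matrix(m)
  s <- m$states
  n_trans <- matrix(0, 7, 7, dimnames = list(s, s))
  t_occ <- setNames(numeric(7), s)
  withr::with_seed(9, {
    for (i in 1:10000) {
      p <- sample_ctmc_path(m, t_max = 10)
      ends <- c(p$entry_time[-1], 10)
      durs <- ends - p$entry_time
      for (k in seq_len(nrow(p))) t_occ[p$state[k]] <- t_occ[p$state[k]] + durs[k]
      if (nrow(p) > 1)
        for (k in seq_len(nrow(p) - 1))
          n_trans[p$state[k], p$state[k + 1]] <-
            n_trans[p$state[k], p$state[k + 1]] + 1
    }
  })
  for (i in s) for (j in s) {
    if (i == j || Q[i, j] == 0) next
    rate_hat <- n_trans[i, j] / t_occ[i]
    se <- sqrt(n_trans[i, j]) / t_occ[i]
    expect_lt(abs(rate_hat - Q[i, j]), 3 * se + 1e-12)
  }
})

test_that("a symmetric distortion-free render gives equal channels at E = 0.5", {
  cfg <- clean_config(state_emission = list(U = c(0.5, 0)),
                      trace_length = 10)
  p <- data.frame(state = "U", entry_time = 0)
  tr <- render_trace(p, cfg, seed = 1)
  expect_equal(tr$frames$F_AD, tr$frames$F_DD, tolerance = 1e-12)
})

test_that("correction round-trip restores the true efficiency exactly", {
  # full distortions (alpha 0.15, delta 0.05, gamma 1.2) but zero channel noise
  cfg <- generator_config(noise_sd = 0, donor_bleach_rate = 0,
                          acceptor_bleach_rate = 0, trace_length = 100)
  m <- fix_model()
  p <- sample_ctmc_path(m, t_max = 100, seed = 3)
  tr <- render_trace(p, cfg, seed = 4)
  ct <- correct_trace(tr, correction_factors(alpha = 0.15, delta = 0.05,
                                             gamma = 1.2, background = 50))
  expect_lt(max(abs(ct$E - tr$truth$E)), 1e-10)
})

test_that("with distortions disabled the correction is the raw gamma ratio", {
  cfg <- clean_config(trace_length = 20)
  p <- sample_ctmc_path(fix_model(), t_max = 20, seed = 11)
  tr <- render_trace(p, cfg, seed = 12)
  ct <- correct_trace(tr, correction_factors(0, 0, 1, 0))
  expect_equal(ct$E, tr$frames$F_AD / (tr$frames$F_AD + tr$frames$F_DD))
})

test_that("truth states and zero-width emissions are consistent", {
  cfg <- clean_config(state_emission = lapply(default_state_emission(),
                                              function(v) c(v[1], 0)),
                      trace_length = 200)
  m <- fix_model(k_f = 0.5, k_u = 0.2, k_f2 = 0.8, k_u2 = 0.3)
  p <- sample_ctmc_path(m, t_max = 200, seed = 13)
  tr <- render_trace(p, cfg, seed = 14)
  f_mean <- cfg$state_emission$F[1]
  # frames wholly inside an F dwell carry exactly the F emission mean; blurred
  # boundary frames are a strict subset of frames labelled F by occupancy
  expect_true(all(tr$truth$E[tr$truth$E == f_mean] >= f_mean - 1e-12))
  expect_gte(sum(tr$truth$state == "F"), sum(tr$truth$E == f_mean))
  expect_true(all(tr$truth$state[tr$truth$E == f_mean] == "F"))
})

test_that("identical seeds reproduce byte-identical trace tables", {
  cfg <- generator_config(trace_length = 50)
  m <- fix_model()
  p <- sample_ctmc_path(m, t_max = 50, seed = 17)
  t1 <- render_trace(p, cfg, seed = 18)
  t2 <- render_trace(p, cfg, seed = 18)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(t1, f1); write_trace_csv(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("acceptor bleach times are exponential with the configured rate", {
  cfg <- generator_config(acceptor_bleach_rate = 0.01, donor_bleach_rate = 0,
                          noise_sd = 0, trace_length = 500)
  m0 <- kinetic_model(0, 0, 0, 0)
  p <- data.frame(state = "U", entry_time = 0)
  frames <- withr::with_seed(19, {
    vapply(1:1000, function(i)
      render_trace(p, cfg, seed = sample.int(2^31 - 1, 1))$truth$acceptor_bleach_frame,
      numeric(1))
  })
  # dequantize within the frame, then probability-integral transform
  # against the window-truncated exponential
  t_bleach <- withr::with_seed(20, (frames[is.finite(frames)] - 1 +
                                      runif(sum(is.finite(frames)))) *
                                     cfg$frame_time)
  u <- (1 - exp(-0.01 * t_bleach)) / (1 - exp(-0.01 * 500))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("time-course ensembles start unfolded and reach equilibrium", {
  m <- fix_model(k_f = 0.5, k_u = 0.2, k_f2 = 0.8, k_u2 = 0.3)
  cfg <- clean_config(trace_length = 1, state_emission =
                        lapply(default_state_emission(), function(v) c(v[1], 0)))
  # frozen start: no folding at all
  m0 <- kinetic_model(0, 0, 0, 0)
  ds0 <- generate_timecourse_dataset(m0, cfg, timepoints = 0,
                                     n_molecules = 3, seed = 30)
  for (tr in ds0[[1]]$traces)
    expect_true(all(abs(tr$truth$E - 0.2) < 1e-12))
  expect_equal(unname(ds0[[1]]$truth_occupancy["U"]), 1)

  # long-time window occupancy matches the stationary law within MC error
  t_eq <- 10 / min(rate_matrix(m)[rate_matrix(m) > 0])
  n <- 400
  ds <- generate_timecourse_dataset(m, cfg, timepoints = c(0, t_eq),
                                    n_molecules = n, seed = 31)
  pi <- equilibrium(m)
  occ <- ds[[2]]$truth_occupancy
  se <- pmax(sqrt(pi * (1 - pi) / n), 1 / n)
  expect_true(all(abs(occ - pi) <= 3.5 * se))

  # degenerate: zero molecules is a valid empty structure
  ds_empty <- generate_timecourse_dataset(m, cfg, timepoints = c(0, 1),
                                          n_molecules = 0, seed = 32)
  expect_length(ds_empty[[1]]$traces, 0)
  expect_error(generate_timecourse_dataset(m, cfg, timepoints = numeric(0),
                                           n_molecules = 1), "non-empty")
})

test_that("trace CSVs and manifests round-trip", {
  cfg <- generator_config(trace_length = 5)
  p <- sample_ctmc_path(fix_model(), 5, seed = 40)
  traces <- lapply(1:3, function(i) render_trace(p, cfg, seed = 40 + i))
  dir <- withr::local_tempdir()
  write_trace_set(traces, dir, timepoints = c(0, 60, 120), seed = 40)
  back <- read_trace_set(dir, frame_time = cfg$frame_time)
  expect_equal(back$manifest$timepoint_s, c(0, 60, 120))
  expect_equal(back$traces[[2]]$frames$F_AD, traces[[2]]$frames$F_AD)
  expect_equal(back$traces[[2]]$truth$E, traces[[2]]$truth$E)
})

test_that("generator config files are read back faithfully", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(frame_time = 0.1, trace_length = 50,
                            total_intensity = 800, alpha = 0.1,
                            delta = 0.02, gamma = 1.1,
                            background = list(F_DD = 10, F_AD = 20, F_AA = 30),
                            state_emission = list(U = c(0.2, 0.05),
                                                  F = c(0.8, 0.05))),
                       path, auto_unbox = TRUE)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$frame_time, 0.1)
  expect_equal(unname(cfg$background), c(10, 20, 30))
  expect_equal(cfg$state_emission$F, c(0.8, 0.05))
})

test_that("config invariants are enforced", {
  expect_error(generator_config(alpha = 1.2), "alpha")
  expect_error(generator_config(gamma = 0), "gamma")
  expect_error(generator_config(frame_time = 0), "frame_time")
  expect_error(generator_config(state_emission = list(U = c(1.5, 0.05))),
               "emission means")
})
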