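# Shared fixture builders. Everything is generated in code; no stored data.

# default off-path model with distinct, realistic rates (1/s)
fix_model <- function(k_f = 0.02, k_u = 0.005, k_f2 = 0.05, k_u2 = 0.01, ...) {
  kinetic_model(k_f = k_f, k_u = k_u, k_f2 = k_f2, k_u2 = k_u2, ...)
}

# random model with log-uniform rates; RNG state of the caller is used
random_model <- function(lo = 1e-3, hi = 10) {
  r <- exp(runif(4, log(lo), log(hi)))
  kinetic_model(k_f = r[1], k_u = r[2], k_f2 = r[3], k_u2 = r[4])
}

# noiseless, distortion-free generator config
clean_config <- function(...) {
  generator_config(noise_sd = 0, background = 0, alpha = 0, delta = 0,
                   gamma = 1, donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                   ...)
}

# corrected_trace with prescribed efficiencies (identity correction)
ct_from_E <- function(E, frame_time = 0.2) {
  raw <- list(frames = data.frame(frame = seq_along(E),
                                  F_DD = 100 * (1 - E), F_AD = 100 * E,
                                  F_AA = 100),
              frame_time = frame_time)
  correct_trace(raw, correction_factors(alpha = 0, delta = 0, gamma = 1))
}

# discrete-time Markov FRET trace: uniform jumps between k states,
# geometric dwells with the given mean (frames); returns list(E, path)
sim_discrete_trace <- function(means, sd_E, n_frames, mean_dwell = 20,
                               seed = 1) {
  k <- length(means)
  withr::with_seed(seed, {
    p_stay <- 1 - 1 / mean_dwell
    P <- matrix((1 - p_stay) / (k - 1), k, k)
    diag(P) <- p_stay
    path <- integer(n_frames)
    path[1] <- sample.int(k, 1)
    for (t in 2:n_frames)
      path[t] <- sample.int(k, 1, prob = P[path[t - 1], ])
    list(E = means[path] + rnorm(n_frames, 0, sd_E), path = path)
  })
}

# two-state CTMC generator matrix for path-sampling tests
two_state_Q <- function(k_uf = 1, k_fu = 1) {
  Q <- matrix(c(-k_uf, k_uf, k_fu, -k_fu), 2, 2, byrow = TRUE,
              dimnames = list(c("U", "F"), c("U", "F")))
  Q
}

# a hand-built trace_hmm object for decoding-independent tests
fake_hmm <- function(path, means, frame_time = 0.2) {
  k <- length(means)
  structure(list(n_states = k, state_means = means,
                 state_sds = rep(0.05, k),
                 transition_matrix = diag(k), initial_probs = rep(1 / k, k),
                 state_path = as.integer(path),
                 log_likelihood = NA_real_, bic = NA_real_,
                 bic_by_k = NA_real_, frame_time = frame_time),
            class = "trace_hmm")
}

# named rate vector of a model
coef_of <- function(m) c(k_f = m$k_f, k_u = m$k_u, k_f2 = m$k_f2,
                         k_u2 = m$k_u2)
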