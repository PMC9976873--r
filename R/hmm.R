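#' Select traces with single-step photobleaching
#'
#' Reproducible proxy for the visual single-molecule curation step: a
#' trace is kept only when each bleaching-sensitive channel shows at most
#' one downward intensity step. Donor bleaching is detected on the summed
#' donor-excitation signal F_DD + F_AD (both channels fall to background);
#' acceptor bleaching on the alternating-excitation channel F_AA, which
#' carries the full acceptor brightness and is insensitive to FRET
#' dynamics. Steps are located by recursive two-segment mean fits and
#' accepted when larger than 3x the channel noise (estimated from
#' successive differences). Traces with more than one downward step in
#' either channel (e.g. two acceptor fluorophores) are rejected; traces
#' with no bleach at all are accepted with their full length usable.
#'
#' @param raws list of \code{raw_trace} (a single trace is wrapped).
#' @param min_seg minimum segment length in frames for a detected step.
#' @return list with \code{accepted} (logical per trace),
#'   \code{usable_range} (list of \code{c(first, last)} per accepted trace,
#'   NULL where rejected), and \code{n_steps} (two-column matrix: donor-sum
#'   and acceptor-channel downward step counts).
#' @export
select_traces <- function(raws, min_seg = 5) {
  if (inherits(raws, "raw_trace")) raws <- list(raws)
  stopifnot(length(raws) > 0)
  res <- lapply(raws, function(tr) {
    fr <- tr$frames
    dsum <- fr$F_DD + fr$F_AD
    steps_d <- find_down_steps(dsum, min_seg)
    steps_a <- find_down_steps(fr$F_AA, min_seg)
    ok <- length(steps_d) <= 1L && length(steps_a) <= 1L
    ur <- NULL
    if (ok) {
      first_bleach <- min(c(steps_d, steps_a, nrow(fr) + 1L))
      ur <- c(1L, as.integer(first_bleach - 1L))
      if (ur[2] < ur[1]) { ok <- FALSE; ur <- NULL }
    }
    list(ok = ok, ur = ur, n = c(length(steps_d), length(steps_a)))
  })
  n_steps <- do.call(rbind, lapply(res, `[[`, "n"))
  colnames(n_steps) <- c("donor_sum", "acceptor")
  list(accepted = vapply(res, `[[`, logical(1), "ok"),
       usable_range = lapply(res, `[[`, "ur"),
       n_steps = n_steps)
}

## recursive binary segmentation for downward mean steps; returns the
## 1-based index of the first frame after each step
#' @noRd
find_down_steps <- function(y, min_seg = 5) {
  noise <- mad(diff(y)) / sqrt(2)
  min_step <- 3 * noise + 1e-8 * (abs(mean(y)) + 1)
  segs <- list(c(1L, length(y)))
  steps <- integer(0)
  while (length(segs) > 0) {
    s <- segs[[1]]; segs <- segs[-1]
    n <- s[2] - s[1] + 1L
    if (n < 2L * min_seg) next
    yy <- y[s[1]:s[2]]
    cs <- cumsum(yy)
    cand <- min_seg:(n - min_seg)
    m1 <- cs[cand] / cand
    m2 <- (cs[n] - cs[cand]) / (n - cand)
    gain <- cand * (n - cand) / n * (m1 - m2)^2
    c_best <- cand[which.max(gain)]
    dstep <- m1[match(c_best, cand)] - m2[match(c_best, cand)]
    if (abs(dstep) >= min_step) {
      if (dstep > 0)                         # downward step only
        steps <- c(steps, s[1] + c_best)
      segs <- c(segs, list(c(s[1], s[1] + c_best - 1L)),
                list(c(s[1] + c_best, s[2])))
    }
  }
  sort(steps)
}

#' Fit a Gaussian hidden Markov model to a corrected FRET trace
#'
#' Segments a corrected efficiency trace into discrete FRET states with a
#' Gaussian-emission hidden Markov model. Models with 1 to
#' \code{max_states} states are fitted by expectation-maximization
#' (Baum-Welch), each restarted \code{n_restarts} times from seeded
#' perturbed quantile initialisations, and the number of states is chosen
#' by the Bayesian information criterion. States are relabelled in
#' ascending order of mean efficiency and the most likely path is decoded
#' by the Viterbi algorithm. A zero-variance trace returns a one-state
#' result directly.
#'
#' @param trace a [correct_trace()] result, or a bare numeric vector of
#'   efficiencies.
#' @param max_states largest number of states to consider (default 4).
#' @param n_restarts EM restarts per state count (default 5).
#' @param seed integer seed making restarts deterministic.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return an object of class \code{trace_hmm}: \code{n_states},
#'   \code{state_means}, \code{state_sds}, \code{transition_matrix}
#'   (row-stochastic per-frame probabilities), \code{initial_probs},
#'   \code{state_path}, \code{log_likelihood}, \code{bic} (selected model)
#'   and \code{bic_by_k}, plus \code{frame_time} when known.
#' @export
fit_hmm <- function(trace, max_states = 4, n_restarts = 5, seed = 1,
                    max_iter = 150, tol = 1e-6) {
  x <- if (inherits(trace, "corrected_trace")) usable_E(trace)
       else as.numeric(trace[is.finite(trace)])
  frame_time <- if (inherits(trace, "corrected_trace")) trace$frame_time
                else NA_real_
  stopifnot(max_states >= 1)
  if (length(x) < 20) stop("need at least 20 usable frames, got ", length(x))

  if (sd(x) < 1e-10) {
    return(new_trace_hmm(1L, mean(x), 1e-10, matrix(1, 1, 1), 1,
                         rep(1L, length(x)), Inf, NA_real_,
                         setNames(NA_real_, "1"), frame_time))
  }

  fits <- with_seed(seed, {
    lapply(seq_len(max_states), function(k) {
      best <- NULL
      for (r in seq_len(if (k == 1) 1 else n_restarts)) {
        f <- tryCatch(em_gaussian_hmm(x, k, restart = r, max_iter = max_iter,
                                      tol = tol),
                      error = function(e) NULL)
        if (!is.null(f) && (is.null(best) || f$loglik > best$loglik))
          best <- f
      }
      best
    })
  })
  n_par <- function(k) (k - 1) + k * (k - 1) + 2 * k
  bic <- vapply(seq_len(max_states), function(k) {
    if (is.null(fits[[k]])) return(Inf)
    -2 * fits[[k]]$loglik + n_par(k) * log(length(x))
  }, numeric(1))
  k_hat <- which.min(bic)
  f <- fits[[k_hat]]

  ord <- order(f$mu)
  mu <- f$mu[ord]; sg <- f$sigma[ord]
  A <- f$A[ord, ord, drop = FALSE]
  pi0 <- f$pi0[ord]
  path <- hmm_viterbi(x, mu, sg, A, pi0)
  new_trace_hmm(k_hat, mu, sg, A, pi0, path, f$loglik, bic[k_hat],
                setNames(bic, seq_len(max_states)), frame_time)
}

#' @noRd
new_trace_hmm <- function(k, mu, sg, A, pi0, path, ll, bic, bic_by_k,
                          frame_time) {
  structure(list(n_states = as.integer(k), state_means = unname(mu),
                 state_sds = unname(sg),
                 transition_matrix = unname(A), initial_probs = unname(pi0),
                 state_path = as.integer(path),
                 log_likelihood = ll, bic = bic, bic_by_k = bic_by_k,
                 frame_time = frame_time),
            class = "trace_hmm")
}

## one Baum-Welch run; restart 1 starts from quantile means, later
## restarts jitter them (RNG already seeded by the caller)
#' @noRd
em_gaussian_hmm <- function(x, k, restart = 1, max_iter = 200, tol = 1e-7) {
  n <- length(x)
  mu <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  if (restart > 1) mu <- mu + rnorm(k, 0, sd(x) / 2)
  sg <- rep(max(sd(x) / max(1, k), 1e-3), k)
  A <- matrix(0.05 / max(1, k - 1), k, k)
  diag(A) <- 0.95
  if (k == 1) A <- matrix(1, 1, 1)
  pi0 <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- hmm_forward_backward(x, mu, sg, A, pi0)
    g <- fb$gamma
    wk <- colSums(g)
    if (any(wk < 1e-6)) stop("empty state during EM")
    mu <- colSums(g * x) / wk
    sg <- sqrt(pmax(colSums(g * (outer(x, mu, `-`)^2)) / wk, 1e-8))
    if (k > 1) {
      A <- fb$xi / rowSums(fb$xi)
      A[!is.finite(A)] <- 1 / k
    }
    pi0 <- g[1, ] / sum(g[1, ])
    if (abs(fb$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
      ll_old <- fb$loglik
      break
    }
    ll_old <- fb$loglik
  }
  list(mu = mu, sigma = sg, A = A, pi0 = pi0, loglik = ll_old)
}

#' @export
print.trace_hmm <- function(x, ...) {
  cat(sprintf("trace_hmm: %d state(s) over %d frames (BIC %.1f)\n",
              x$n_states, length(x$state_path), x$bic))
  cat("  means:", sprintf("%.3f", x$state_means), "\n")
  cat("  sds:  ", sprintf("%.3f", x$state_sds), "\n")
  invisible(x)
}

#' @export
summary.trace_hmm <- function(object, ...) {
  d <- extract_dwells(object)
  occ <- tabulate(object$state_path, object$n_states) /
    length(object$state_path)
  data.frame(state = seq_len(object$n_states),
             mean_E = object$state_means, sd_E = object$state_sds,
             occupancy = occ,
             n_dwells = tabulate(d$state, object$n_states))
}

#' Extract dwell times from a decoded state path
#'
#' Run-length encodes the most-likely state path: each maximal run of one
#' state becomes a dwell of duration (run length x frame time). The first
#' and last dwells are flagged censored — their true durations extend
#' beyond the observation window.
#'
#' @param result a [fit_hmm()] result.
#' @param frame_time frame duration in seconds; defaults to the one stored
#'   in \code{result}.
#' @return a data frame of class \code{dwell_set}: \code{state},
#'   \code{state_mean}, \code{duration_s}, \code{censored_left},
#'   \code{censored_right}.
#' @export
extract_dwells <- function(result, frame_time = NULL) {
  stopifnot(inherits(result, "trace_hmm"))
  if (is.null(frame_time)) frame_time <- result$frame_time
  if (is.null(frame_time) || is.na(frame_time))
    stop("frame_time is unknown; supply it explicitly")
  r <- rle(result$state_path)
  n <- length(r$lengths)
  dwell_set(state = r$values,
            duration_s = r$lengths * frame_time,
            censored_left = seq_len(n) == 1L,
            censored_right = seq_len(n) == n,
            state_mean = result$state_means[r$values])
}

#' Construct a dwell set
#'
#' @param state integer state labels.
#' @param duration_s positive dwell durations in seconds.
#' @param censored_left,censored_right censoring flags (dwells truncated by
#'   the start/end of the observation window).
#' @param state_mean optional state mean efficiencies.
#' @return data frame of class \code{dwell_set}.
#' @export
dwell_set <- function(state, duration_s, censored_left = FALSE,
                      censored_right = FALSE, state_mean = NA_real_) {
  stopifnot(all(duration_s > 0))
  structure(data.frame(state = state, state_mean = state_mean,
                       duration_s = duration_s,
                       censored_left = censored_left,
                       censored_right = censored_right),
            class = c("dwell_set", "data.frame"))
}

#' Exponential dwell lifetime of a state
#'
#' Estimates the mean lifetime of a state from its uncensored dwell times,
#' assuming exponentially distributed dwells (a memoryless single-step
#' escape). Two estimators are provided: the maximum-likelihood mean of
#' the uncensored dwells (default), and a binned dwell-time histogram
#' fitted with a single exponential decay by nonlinear least squares —
#' the classical trace-analysis route.
#'
#' @param dwells a [dwell_set()].
#' @param state the state label to analyse.
#' @param method \code{"mle"} or \code{"histogram"}.
#' @param bin_width histogram bin width in seconds (default: the smallest
#'   dwell duration, i.e. one frame for path-derived dwells).
#' @param min_dwells minimum number of uncensored dwells (default 10).
#' @return list with \code{lifetime} (s), \code{se}, \code{n},
#'   \code{method}, and for the histogram method the fitted \code{nls}
#'   object.
#' @export
fit_dwell_lifetime <- function(dwells, state,
                               method = c("mle", "histogram"),
                               bin_width = NULL, min_dwells = 10) {
  method <- match.arg(method)
  stopifnot(inherits(dwells, "dwell_set"))
  d <- dwells$duration_s[dwells$state == state &
                         !dwells$censored_left & !dwells$censored_right]
  n <- length(d)
  if (n < min_dwells)
    stop("need at least ", min_dwells, " uncensored dwells in state ",
         state, ", got ", n)
  if (method == "mle") {
    tau <- mean(d)
    return(list(lifetime = tau, se = tau / sqrt(n), n = n, method = "mle"))
  }
  if (is.null(bin_width)) bin_width <- min(d)
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  mid <- (head(edges, -1) + tail(edges, -1)) / 2
  keep <- counts > 0
  ## log-linear start, then single-exponential least squares
  lf <- stats::lm(log(counts[keep]) ~ mid[keep])
  tau0 <- max(-1 / coef(lf)[2], bin_width)
  fit <- nls(counts ~ A * exp(-mid / tau),
             start = list(A = exp(coef(lf)[1]), tau = tau0),
             control = list(maxiter = 200, warnOnly = TRUE))
  est <- summary(fit)$coefficients
  list(lifetime = unname(est["tau", "Estimate"]),
       se = unname(est["tau", "Std. Error"]),
       n = n, method = "histogram", fit = fit)
}

#' Classify a trace into the low/high FRET groups
#'
#' A trace belongs to the high-FRET group when any visited state has mean
#' efficiency at or above the threshold (fully folded conformations were
#' reached), and to the low-FRET group otherwise. Additionally flags the
#' rare direct transitions between the lowest and highest FRET states:
#' consecutive dwells jumping from a state with mean <= 0.25 to one with
#' mean >= 0.6 or vice versa, without passing through intermediates.
#'
#' @param result a [fit_hmm()] result.
#' @param threshold efficiency threshold for the high group (default 0.6).
#' @param low_mean,high_mean bounds defining a direct low/high jump.
#' @return list with \code{group} (\code{"low"} or \code{"high"}),
#'   \code{visited_states} (mean efficiencies of states present in the
#'   path) and \code{has_direct_low_high_transition}.
#' @export
classify_trace <- function(result, threshold = 0.6,
                           low_mean = 0.25, high_mean = 0.6) {
  stopifnot(inherits(result, "trace_hmm"))
  visited <- sort(unique(result$state_path))
  means <- result$state_means[visited]
  seq_means <- result$state_means[rle(result$state_path)$values]
  direct <- FALSE
  if (length(seq_means) > 1) {
    a <- head(seq_means, -1); b <- tail(seq_means, -1)
    direct <- any((a <= low_mean & b >= high_mean) |
                  (a >= high_mean & b <= low_mean))
  }
  list(group = if (any(means >= threshold)) "high" else "low",
       visited_states = means,
       has_direct_low_high_transition = direct)
}

#' Write dwell times as CSV
#'
#' Columns \code{trace_id}, \code{state_mean}, \code{duration_s},
#' \code{censored_left}, \code{censored_right}.
#'
#' @param dwell_list a \code{dwell_set} or list of them (one per trace).
#' @param path file path.
#' @export
write_dwells <- function(dwell_list, path) {
  if (inherits(dwell_list, "dwell_set")) dwell_list <- list(dwell_list)
  rows <- do.call(rbind, lapply(seq_along(dwell_list), function(i) {
    d <- dwell_list[[i]]
    data.frame(trace_id = i, state_mean = d$state_mean,
               duration_s = d$duration_s,
               censored_left = d$censored_left,
               censored_right = d$censored_right)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write an HMM segmentation as a JSON record
#'
#' Serialises the fitted state parameters, transition matrix and the
#' run-length-encoded Viterbi path of one trace.
#'
#' @param result a [fit_hmm()] result.
#' @param path file path.
#' @export
write_hmm_json <- function(result, path) {
  stopifnot(inherits(result, "trace_hmm"))
  r <- rle(result$state_path)
  jsonlite::write_json(
    list(n_states = result$n_states,
         state_means = result$state_means,
         state_sds = result$state_sds,
         transition_matrix = result$transition_matrix,
         initial_probs = result$initial_probs,
         path_rle = list(lengths = r$lengths, states = r$values),
         log_likelihood = result$log_likelihood,
         bic = result$bic,
         frame_time = result$frame_time),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
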