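## Deterministic and stochastic propagation of the folding model.

#' Matrix exponential propagation helper
#'
#' Returns occupancies p0 %*% expm(Q t) for all requested times from a single
#' eigendecomposition of Q; falls back to scaling-and-squaring Taylor series
#' when Q is numerically defective.
#' @noRd
propagate_occupancy <- function(Q, p0, times) {
  n <- nrow(Q)
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  Vinv <- NULL
  if (!is.null(ev) && all(is.finite(Mod(ev$values)))) {
    Vinv <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- Re(ev$vectors %*% (ev$values * Vinv))
      if (max(abs(recon - Q)) > 1e-8 * max(1, max(abs(Q)))) Vinv <- NULL
    }
  }
  out <- matrix(NA_real_, length(times), n)
  if (!is.null(Vinv)) {
    a <- as.vector(p0 %*% ev$vectors)  # possibly complex
    for (i in seq_along(times)) {
      p <- Re((a * exp(ev$values * times[i])) %*% Vinv)
      out[i, ] <- p
    }
  } else {
    for (i in seq_along(times))
      out[i, ] <- as.vector(p0 %*% expm_taylor(Q * times[i]))
  }
  ## stiff generators can defeat the eigen route; fall back to the stable
  ## scaling-and-squaring path before cleaning round-off
  if (!all(is.finite(out)) || isTRUE(any(out < -1e-6, na.rm = TRUE))) {
    for (i in seq_along(times))
      out[i, ] <- as.vector(p0 %*% expm_taylor(Q * times[i]))
  }
  out[out < 0] <- 0
  out / rowSums(out)
}

## scaling-and-squaring truncated Taylor expm; adequate for small generators
#' @noRd
expm_taylor <- function(A) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, norm(A, "1")))))
  A <- A / 2^s
  E <- diag(n) + A
  term <- A
  for (k in 2:30) {
    term <- term %*% A / k
    E <- E + term
    if (max(abs(term)) < 1e-16) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Solve the folding rate equations
#'
#' Propagates an initial occupancy through the rate equations
#' \eqn{dp/dt = p Q} of the off-path folding model, where \eqn{Q} is the
#' generator from [rate_matrix()]. The solution is the exact matrix
#' exponential of the fixed generator, so probabilities are conserved to
#' machine precision at every time.
#'
#' @param model a [kinetic_model()].
#' @param p0 named initial occupancy over the model states (must sum to 1),
#'   or a single state name meaning a point mass there.
#' @param times numeric vector of times (s), non-negative.
#' @return data frame with a \code{time} column and one occupancy column per
#'   state.
#' @export
simulate_ode <- function(model, p0 = "U", times) {
  stopifnot(inherits(model, "kinetic_model"))
  p0 <- as_occupancy(p0, model$states)
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0))
  Q <- rate_matrix(model)
  occ <- propagate_occupancy(Q, p0, times)
  colnames(occ) <- model$states
  data.frame(time = times, occ, check.names = FALSE)
}

#' @noRd
as_occupancy <- function(p0, states) {
  if (is.character(p0) && length(p0) == 1L) {
    if (!p0 %in% states) stop("unknown state '", p0, "'")
    p <- setNames(numeric(length(states)), states)
    p[p0] <- 1
    return(p)
  }
  stopifnot(is.numeric(p0))
  if (is.null(names(p0))) {
    if (length(p0) != length(states)) stop("p0 must cover all model states")
    names(p0) <- states
  }
  p <- setNames(numeric(length(states)), states)
  p[names(p0)] <- p0
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p0 must be a normalized occupancy (non-negative, summing to 1)")
  p
}

#' Stochastic simulation of the folding model
#'
#' Exact (Gillespie) stochastic simulation of \code{n_molecules} independent
#' molecules evolving under the model's generator, reporting empirical state
#' frequencies at the requested times with binomial standard errors
#' \eqn{\sqrt{p(1-p)/n}}. The simulation is the stochastic twin of
#' [simulate_ode()] and is used to validate it (and vice versa).
#'
#' @inheritParams simulate_ode
#' @param n_molecules number of molecules (>= 1).
#' @param seed integer seed for reproducibility.
#' @return data frame with \code{time}, one frequency column per state, and
#'   attribute \code{"se"} (matrix of binomial standard errors) and
#'   \code{"n_molecules"}.
#' @export
simulate_gillespie <- function(model, n_molecules, times, p0 = "U",
                               seed = NULL) {
  stopifnot(inherits(model, "kinetic_model"),
            n_molecules >= 1, all(times >= 0))
  p0 <- as_occupancy(p0, model$states)
  Q <- rate_matrix(model)
  ns <- length(model$states)
  exit <- -diag(Q)
  jumpP <- Q
  diag(jumpP) <- 0
  pos <- exit > 0
  jumpP[pos, ] <- jumpP[pos, , drop = FALSE] / exit[pos]

  ord <- order(times)
  tq <- times[ord]
  freq <- matrix(0, length(tq), ns,
                 dimnames = list(NULL, model$states))
  with_seed(seed, {
    state <- sample.int(ns, n_molecules, replace = TRUE, prob = p0)
    t_now <- numeric(n_molecules)
    t_next <- t_now + ifelse(exit[state] > 0,
                             rexp(n_molecules, exit[state]), Inf)
    for (i in seq_along(tq)) {
      repeat {
        due <- which(t_next <= tq[i])
        if (length(due) == 0L) break
        st_due <- state[due]
        for (s in unique(st_due)) {
          idx <- due[st_due == s]
          state[idx] <- sample.int(ns, length(idx), replace = TRUE,
                                   prob = jumpP[s, ])
        }
        t_now[due] <- t_next[due]
        r <- exit[state[due]]
        t_next[due] <- t_now[due] + ifelse(r > 0, rexp(length(due), r), Inf)
      }
      freq[i, ] <- tabulate(state, nbins = ns) / n_molecules
    }
  })
  freq[ord, ] <- freq
  out <- data.frame(time = times, freq, check.names = FALSE)
  se <- sqrt(freq * (1 - freq) / n_molecules)
  se[ord, ] <- se
  attr(out, "se") <- se
  attr(out, "n_molecules") <- n_molecules
  out
}

#' Folded-fraction time course from occupancies
#'
#' Collapses a state-occupancy series into the experimentally observed
#' quantity: the fraction of molecules whose FRET efficiency is at or above
#' the full-folding threshold (E >= 0.6). Under the default emission map
#' only the two-G4 state \code{F} emits at or above 0.6, so the fraction is
#' the probability of \code{F}; other mappings can be supplied.
#'
#' @param occupancies data frame from [simulate_ode()] or
#'   [simulate_gillespie()] (\code{time} column plus state columns).
#' @param folded_states character vector of states counted as fully folded.
#' @return a \code{timecourse} data frame with columns \code{time} and
#'   \code{fraction} (and \code{sd} when the input carries standard errors).
#' @export
folded_fraction_curve <- function(occupancies, folded_states = "F") {
  stopifnot(is.data.frame(occupancies), "time" %in% names(occupancies),
            all(folded_states %in% names(occupancies)))
  frac <- rowSums(occupancies[, folded_states, drop = FALSE])
  se <- attr(occupancies, "se")
  sd <- if (!is.null(se))
    sqrt(rowSums(se[, colnames(se) %in% folded_states, drop = FALSE]^2))
  timecourse(occupancies$time, frac, sd)
}

#' Folded-fraction time-course container
#'
#' @param times observation times (s), sorted, non-negative.
#' @param fraction folded fractions in [0, 1].
#' @param sd optional per-point standard deviations.
#' @return data frame of class \code{timecourse}.
#' @export
timecourse <- function(times, fraction, sd = NULL) {
  stopifnot(is.numeric(times), all(times >= 0), !is.unsorted(times),
            length(times) == length(fraction),
            all(fraction >= -1e-9 & fraction <= 1 + 1e-9))
  out <- data.frame(time = times, fraction = pmin(1, pmax(0, fraction)))
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(times), all(sd >= 0))
    out$sd <- sd
  }
  class(out) <- c("timecourse", "data.frame")
  out
}

#' Read / write a folded-fraction time course as CSV
#'
#' Columns \code{time_s}, \code{fraction} and optionally \code{sd}.
#' @param path file path.
#' @param tc a \code{timecourse} (for writing).
#' @return \code{read_timecourse} returns a \code{timecourse}.
#' @export
read_timecourse <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("time_s", "fraction") %in% names(x)))
  timecourse(x$time_s, x$fraction, x$sd)
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  out <- data.frame(time_s = tc$time, fraction = tc$fraction)
  if (!is.null(tc$sd)) out$sd <- tc$sd
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
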