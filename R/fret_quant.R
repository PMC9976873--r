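#' ALEX FRET correction factors
#'
#' Holds the averaged trace-derived correction factors used to convert raw
#' two-colour intensities into accurate FRET efficiencies: donor leakage
#' into the acceptor channel (\code{alpha}), acceptor direct excitation
#' under donor-laser illumination (\code{delta}, measured via the
#' alternating-excitation acceptor channel), the detection-imbalance
#' \code{gamma} factor, and per-channel constant backgrounds.
#'
#' @param alpha donor-leakage fraction, in [0, 1) (default 0.15).
#' @param delta direct-excitation fraction, in [0, 1) (default 0.05).
#' @param gamma detection-imbalance factor, > 0 (default 1.2).
#' @param background per-channel backgrounds (single number or named
#'   \code{c(F_DD=, F_AD=, F_AA=)}; default 0).
#' @return an object of class \code{correction_factors}.
#' @export
correction_factors <- function(alpha = 0.15, delta = 0.05, gamma = 1.2,
                               background = 0) {
  stopifnot(alpha >= 0, alpha < 1, delta >= 0, delta < 1, gamma > 0)
  if (length(background) == 1L)
    background <- setNames(rep(background, 3), c("F_DD", "F_AD", "F_AA"))
  stopifnot(all(c("F_DD", "F_AD", "F_AA") %in% names(background)))
  structure(list(alpha = alpha, delta = delta, gamma = gamma,
                 background = background[c("F_DD", "F_AD", "F_AA")]),
            class = "correction_factors")
}

#' Correct a raw trace to FRET efficiencies
#'
#' Applies the standard ALEX correction chain per frame: backgrounds are
#' subtracted from every channel, donor leakage \code{alpha * F_DD'} and
#' direct excitation \code{delta * F_AA'} are removed from the acceptor
#' channel, and the efficiency is computed as
#' \deqn{E = F'_{A|D} / (F'_{A|D} + \gamma F'_{D|D}).}
#' E is deliberately not clipped to [0, 1]; frames whose corrected
#' denominator is not positive (e.g. after donor photobleaching) are
#' flagged invalid rather than raising an error, and are excluded from
#' histograms downstream.
#'
#' @param raw a \code{raw_trace} (or any list with a \code{frames} data
#'   frame carrying \code{F_DD}, \code{F_AD}, \code{F_AA} and a
#'   \code{frame_time}).
#' @param corr a [correction_factors()].
#' @param usable_range optional \code{c(first, last)} frame interval to
#'   retain (e.g. the pre-bleach window from [select_traces()]); defaults
#'   to the full trace.
#' @return an object of class \code{corrected_trace}: \code{E} (per frame,
#'   NA where invalid), \code{valid} logical, \code{frame_time},
#'   \code{usable_range}.
#' @examples
#' tr <- list(frames = data.frame(frame = 1, F_DD = 100, F_AD = 85, F_AA = 200),
#'            frame_time = 0.2)
#' correct_trace(tr, correction_factors())$E  # (85-15-10)/(60+1.2*100) = 1/3
#' @export
correct_trace <- function(raw, corr = correction_factors(),
                          usable_range = NULL) {
  stopifnot(inherits(corr, "correction_factors"))
  fr <- raw$frames
  stopifnot(is.data.frame(fr), nrow(fr) > 0,
            all(c("F_DD", "F_AD", "F_AA") %in% names(fr)))
  n <- nrow(fr)
  if (is.null(usable_range)) usable_range <- c(1L, n)
  stopifnot(length(usable_range) == 2L, usable_range[1] >= 1,
            usable_range[2] <= n, usable_range[1] <= usable_range[2])
  bg <- corr$background
  F_DD <- fr$F_DD - bg[["F_DD"]]
  F_AA <- fr$F_AA - bg[["F_AA"]]
  F_AD <- fr$F_AD - bg[["F_AD"]] - corr$alpha * F_DD - corr$delta * F_AA
  denom <- F_AD + corr$gamma * F_DD
  valid <- is.finite(denom) & denom > 0
  E <- rep(NA_real_, n)
  E[valid] <- F_AD[valid] / denom[valid]
  structure(list(E = E, valid = valid, frame_time = raw$frame_time,
                 usable_range = as.integer(usable_range)),
            class = "corrected_trace")
}

#' @export
print.corrected_trace <- function(x, ...) {
  ur <- x$usable_range
  cat(sprintf("corrected_trace: %d frames, usable %d..%d (%d valid)\n",
              length(x$E), ur[1], ur[2],
              sum(x$valid[ur[1]:ur[2]])))
  invisible(x)
}

## usable, valid E values of one corrected trace
#' @noRd
usable_E <- function(ct) {
  idx <- ct$usable_range[1]:ct$usable_range[2]
  ct$E[idx][ct$valid[idx]]
}

#' Ensemble (bulk) FRET efficiency
#'
#' The uncorrected proximity ratio used for cuvette FRET-melting data:
#' \code{E = I_DA / (I_DA + I_DD)}.
#'
#' @param I_DA acceptor emission intensity under donor excitation.
#' @param I_DD donor emission intensity.
#' @return the ratio; errors when \code{I_DA + I_DD <= 0}.
#' @export
ensemble_fret <- function(I_DA, I_DD) {
  s <- I_DA + I_DD
  if (any(!is.finite(s)) || any(s <= 0))
    stop("I_DA + I_DD must be positive")
  I_DA / s
}

#' Build a frame-weighted FRET efficiency histogram
#'
#' Each usable, valid frame of every trace contributes one count, as in
#' single-molecule FRET population histograms. Bin edges are anchored so
#' that one edge falls exactly at the full-folding threshold E = 0.6 and
#' cover the fixed range [-0.1, 1.1] (corrected E can leave [0, 1] under
#' noise). Frames outside the range are excluded and counted in
#' \code{n_excluded}.
#'
#' @param traces a \code{corrected_trace} or list of them.
#' @param bin_width bin width in E units (default 0.025).
#' @param range histogram range (default \code{c(-0.1, 1.1)}).
#' @return an object of class \code{fret_histogram}: \code{bin_edges},
#'   \code{counts}, \code{n_frames}, \code{n_traces}, \code{n_excluded}.
#' @export
build_histogram <- function(traces, bin_width = 0.025,
                            range = c(-0.1, 1.1)) {
  if (inherits(traces, "corrected_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0, bin_width > 0, range[1] < 0.6, range[2] > 0.6)
  E <- unlist(lapply(traces, usable_E))
  if (length(E) == 0L) stop("no usable frames in any trace")
  ## edges anchored at the 0.6 threshold
  lo <- 0.6 - bin_width * ceiling((0.6 - range[1]) / bin_width - 1e-9)
  edges <- seq(lo, range[2] + bin_width - 1e-12, by = bin_width)
  keep <- E >= edges[1] & E <= edges[length(edges)]
  idx <- pmin(findInterval(E[keep], edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 n_frames = sum(counts), n_traces = length(traces),
                 n_excluded = sum(!keep)),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("fret_histogram: %d frames from %d traces in %d bins (%d excluded)\n",
              x$n_frames, x$n_traces, length(x$counts), x$n_excluded))
  invisible(x)
}

#' Plot a FRET histogram
#' @param x a \code{fret_histogram}.
#' @param threshold draw the full-folding threshold line (NULL to omit).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fret_histogram <- function(x, threshold = 0.6, ...) {
  mid <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
  graphics::plot(mid, x$counts, type = "h", lwd = 3, lend = 1,
                 xlab = "FRET efficiency E", ylab = "frames", ...)
  if (!is.null(threshold))
    graphics::abline(v = threshold, lty = 2, col = "grey40")
  invisible(x)
}

#' Fully folded fraction from a FRET histogram
#'
#' Fraction of histogram counts at or above the full-folding efficiency
#' threshold (E >= 0.6 identifies molecules with two G-quadruplexes).
#' The threshold must coincide with a bin edge so no bin is silently
#' split.
#'
#' @param hist a [build_histogram()] result.
#' @param threshold efficiency threshold (default 0.6).
#' @return fraction in [0, 1].
#' @export
folded_fraction <- function(hist, threshold = 0.6) {
  stopifnot(inherits(hist, "fret_histogram"))
  k <- which(abs(hist$bin_edges - threshold) < 1e-9)
  if (length(k) != 1L)
    stop("threshold ", threshold, " does not coincide with a bin edge")
  sum(hist$counts[seq_along(hist$counts) >= k]) / sum(hist$counts)
}

#' Split-sample folded fraction with uncertainty
#'
#' The trace pool is randomly partitioned (without replacement) into
#' \code{n_splits} near-equal groups, a FRET histogram is built per group,
#' and the folded fraction is computed for each; the mean and standard
#' deviation across groups estimate the population fraction and its
#' uncertainty. Remainder traces are assigned round-robin so the grouping
#' is deterministic given the seed.
#'
#' @param traces list of \code{corrected_trace}.
#' @param n_splits number of groups (default 3).
#' @param threshold full-folding threshold (default 0.6).
#' @param bin_width histogram bin width (default 0.025).
#' @param seed integer seed for the random partition.
#' @return list with \code{mean}, \code{sd}, \code{fractions} (per group),
#'   \code{n_traces}, \code{n_frames}.
#' @export
fraction_uncertainty <- function(traces, n_splits = 3, threshold = 0.6,
                                 bin_width = 0.025, seed = NULL) {
  stopifnot(is.list(traces), n_splits >= 1)
  n <- length(traces)
  if (n < n_splits)
    stop("need at least ", n_splits, " traces for ", n_splits,
         " splits, got ", n)
  perm <- with_seed(seed, sample.int(n))
  group <- rep_len(seq_len(n_splits), n)   # round-robin over the permutation
  fracs <- vapply(seq_len(n_splits), function(g) {
    h <- build_histogram(traces[perm[group == g]], bin_width = bin_width)
    folded_fraction(h, threshold)
  }, numeric(1))
  list(mean = mean(fracs), sd = sd(fracs), fractions = fracs,
       n_traces = n,
       n_frames = sum(vapply(traces, function(ct) length(usable_E(ct)),
                             numeric(1))))
}

#' Write / read a FRET histogram as CSV
#'
#' Columns \code{bin_left}, \code{bin_right}, \code{count}.
#' @param hist a \code{fret_histogram}.
#' @param path file path.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "fret_histogram"))
  write.csv(data.frame(bin_left = head(hist$bin_edges, -1),
                       bin_right = tail(hist$bin_edges, -1),
                       count = hist$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' Write folded-fraction summaries as CSV
#'
#' One row per labelled condition: \code{label, mean, sd, n_traces,
#' n_frames}, as produced by [fraction_uncertainty()].
#'
#' @param fractions a named list of [fraction_uncertainty()] results.
#' @param path file path.
#' @export
write_fractions <- function(fractions, path) {
  stopifnot(is.list(fractions), length(fractions) > 0,
            !is.null(names(fractions)))
  rows <- do.call(rbind, lapply(names(fractions), function(lb) {
    f <- fractions[[lb]]
    data.frame(label = lb, mean = f$mean, sd = f$sd,
               n_traces = f$n_traces, n_frames = f$n_frames)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
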