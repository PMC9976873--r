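#' Configuration for the synthetic trace generator
#'
#' Collects the instrument and photophysics settings used to turn a kinetic
#' state path into a three-channel intensity trace resembling prism-TIRF
#' alternating-laser-excitation (ALEX) data: 200 ms frames over 500 s
#' records, Gaussian channel noise, constant backgrounds, donor leakage
#' \code{alpha}, acceptor direct excitation \code{delta}, detection
#' imbalance \code{gamma}, and independent exponential photobleaching
#' clocks for each dye. The emission map assigns each kinetic state a FRET
#' efficiency mean and width: unfolded DNA emits near E = 0.2, one-G4
#' intermediates near 0.4, and the fully folded two-G4 conformation near
#' 0.8 by default.
#'
#' @param frame_time seconds per camera frame (default 0.2).
#' @param trace_length trace duration in seconds (default 500).
#' @param total_intensity total photons per frame in arbitrary units
#'   (default 1000).
#' @param noise_sd additive Gaussian noise sd per channel, same units
#'   (default 30).
#' @param background per-channel constant offsets, named
#'   \code{c(F_DD=, F_AD=, F_AA=)} or a single number (default 50).
#' @param alpha donor-leakage fraction (default 0.15).
#' @param delta direct-excitation fraction (default 0.05).
#' @param gamma detection-imbalance factor (default 1.2).
#' @param donor_bleach_rate,acceptor_bleach_rate bleaching rates, 1/s
#'   (default 0.002, i.e. a 500 s mean photobleaching lifetime).
#' @param state_emission named list mapping each state to
#'   \code{c(mean, sd)} in E units.
#' @param acceptor_copies number of acceptor fluorophores; 2 emulates the
#'   doubly-labelled artifact molecules that show two acceptor bleaching
#'   steps and must be rejected by trace selection (default 1).
#' @param seed optional default seed carried with the config.
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(frame_time = 0.2, trace_length = 500,
                             total_intensity = 1000, noise_sd = 30,
                             background = c(F_DD = 50, F_AD = 50, F_AA = 50),
                             alpha = 0.15, delta = 0.05, gamma = 1.2,
                             donor_bleach_rate = 0.002,
                             acceptor_bleach_rate = 0.002,
                             state_emission = default_state_emission(),
                             acceptor_copies = 1,
                             seed = NULL) {
  stopifnot(frame_time > 0, trace_length >= frame_time,
            total_intensity > 0, noise_sd >= 0,
            alpha >= 0, alpha < 1, delta >= 0, delta < 1, gamma > 0,
            donor_bleach_rate >= 0, acceptor_bleach_rate >= 0,
            acceptor_copies >= 1)
  if (length(background) == 1L)
    background <- setNames(rep(background, 3), c("F_DD", "F_AD", "F_AA"))
  stopifnot(all(c("F_DD", "F_AD", "F_AA") %in% names(background)),
            all(background >= 0))
  means <- vapply(state_emission, `[`, numeric(1), 1)
  if (any(means <= -0.2 | means >= 1.2))
    stop("state emission means must lie in (-0.2, 1.2)")
  if (any(vapply(state_emission, `[`, numeric(1), 2) < 0))
    stop("state emission sds must be >= 0")
  structure(
    list(frame_time = frame_time, trace_length = trace_length,
         total_intensity = total_intensity, noise_sd = noise_sd,
         background = background[c("F_DD", "F_AD", "F_AA")],
         alpha = alpha, delta = delta, gamma = gamma,
         donor_bleach_rate = donor_bleach_rate,
         acceptor_bleach_rate = acceptor_bleach_rate,
         state_emission = state_emission,
         acceptor_copies = acceptor_copies, seed = seed),
    class = "generator_config")
}

#' Default state-to-FRET emission map
#'
#' Unfolded (U) at E = 0.2, every one-G4 intermediate (P2..P6, the
#' partially unfolded state C) at E = 0.4, and the two-G4 state F at
#' E = 0.8 (the antiparallel fully folded population); widths 0.05 E units.
#'
#' @param sd emission width in E units (default 0.05).
#' @param folded_mean emission mean of the fully folded state (0.8; use 0.6
#'   for the lower fully folded conformation).
#' @return named list of \code{c(mean, sd)} per state.
#' @export
default_state_emission <- function(sd = 0.05, folded_mean = 0.8) {
  ems <- c(list(U = c(0.2, sd)),
           setNames(rep(list(c(0.4, sd)), 5), paste0("P", 2:6)),
           list(F = c(folded_mean, sd)))
  ems
}

#' Sample a continuous-time Markov state path
#'
#' Exact stochastic simulation of the continuous-time Markov chain defined
#' by a kinetic model's rate matrix (or any generator matrix with state
#' dimnames): exponential holding times, jump probabilities proportional to
#' the off-diagonal rates. The returned path covers \code{[0, t_max]}.
#'
#' @param model a [kinetic_model()] or a square generator matrix with
#'   dimnames (rows summing to zero).
#' @param t_max path duration, seconds (> 0).
#' @param initial_state starting state name (default \code{"U"}).
#' @param seed integer seed.
#' @return data frame of class \code{ctmc_path} with columns \code{state}
#'   and \code{entry_time}; first entry time is 0.
#' @export
sample_ctmc_path <- function(model, t_max, initial_state = "U", seed = NULL) {
  stopifnot(t_max > 0)
  Q <- if (inherits(model, "kinetic_model")) rate_matrix(model) else model
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), !is.null(rownames(Q)))
  states <- rownames(Q)
  if (!initial_state %in% states)
    stop("unknown initial state '", initial_state, "'")
  exit <- -diag(Q)
  with_seed(seed, {
    st <- character(0); tt <- numeric(0)
    cur <- initial_state; now <- 0
    repeat {
      st <- c(st, cur); tt <- c(tt, now)
      r <- exit[cur]
      if (r <= 0) break                     # absorbing
      now <- now + rexp(1, r)
      if (now >= t_max) break
      p <- Q[cur, ]; p[cur] <- 0
      cur <- sample(states, 1, prob = p)
    }
    structure(data.frame(state = st, entry_time = tt),
              class = c("ctmc_path", "data.frame"))
  })
}

## per-frame occupancy-weighted emission mean and width from a state path
#' @noRd
frame_emission <- function(path, n_frames, frame_time, emission, t_offset = 0) {
  mean_of <- vapply(emission, `[`, numeric(1), 1)
  sd_of <- vapply(emission, `[`, numeric(1), 2)
  entry <- path$entry_time - t_offset
  seg_end <- c(entry[-1], Inf)
  fm <- numeric(n_frames); fs <- numeric(n_frames); wtot <- numeric(n_frames)
  occ_best <- numeric(n_frames); best_state <- character(n_frames)
  t_end <- n_frames * frame_time
  for (k in seq_len(nrow(path))) {
    a <- max(0, entry[k]); b <- min(t_end, seg_end[k])
    if (b <= a) next
    s <- path$state[k]
    if (!s %in% names(emission))
      stop("state '", s, "' missing from the emission map")
    i0 <- floor(a / frame_time) + 1L
    i1 <- min(n_frames, ceiling(b / frame_time))
    idx <- i0:i1
    lo <- pmax(a, (idx - 1) * frame_time)
    hi <- pmin(b, idx * frame_time)
    w <- (hi - lo) / frame_time
    fm[idx] <- fm[idx] + w * mean_of[s]
    fs[idx] <- fs[idx] + w * sd_of[s]
    wtot[idx] <- wtot[idx] + w
    upd <- w > occ_best[idx]
    best_state[idx[upd]] <- s
    occ_best[idx][upd] <- w[upd]
  }
  if (any(abs(wtot - 1) > 1e-6))
    stop("state path does not cover the full trace duration")
  list(mean = fm, sd = fs, state = best_state)
}

#' Render a state path into a raw three-channel intensity trace
#'
#' Applies the full forward measurement model that the analysis must later
#' undo. Per frame, the true efficiency is the occupancy-weighted average
#' of the visited states' emission means over the frame interval (motion
#' blur at 200 ms integration), jittered by the emission width. Ideal
#' intensities are \code{F_AD = I * E} and \code{F_DD = I * (1 - E) / gamma};
#' the observed channels add donor leakage (\code{alpha * F_DD}), direct
#' acceptor excitation (\code{delta * F_AA}), the constant backgrounds and
#' Gaussian noise. Donor and acceptor photobleaching times are drawn from
#' independent exponential clocks; after the acceptor bleaches the donor
#' dequenches (E drops to 0), after the donor bleaches both
#' donor-excitation channels fall to background. Ground truth (state per
#' frame, realized E per frame, bleach frames) is recorded for validation.
#'
#' @param path a [sample_ctmc_path()] result (or any data frame with
#'   \code{state}/\code{entry_time}) covering the trace duration.
#' @param cfg a [generator_config()].
#' @param seed integer seed (defaults to the config's seed).
#' @param t_offset observation-window start on the path's clock, seconds.
#' @return an object of class \code{raw_trace}: data frame
#'   \code{frames(frame, F_DD, F_AD, F_AA)}, \code{frame_time}, and a
#'   \code{truth} list (\code{state}, \code{E},
#'   \code{donor_bleach_frame}, \code{acceptor_bleach_frame}; bleach frames
#'   are the first dark frame, \code{Inf} when no bleach occurs in-trace).
#' @export
render_trace <- function(path, cfg, seed = NULL, t_offset = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(seed)) seed <- cfg$seed
  n <- floor(cfg$trace_length / cfg$frame_time + 1e-9)
  em <- frame_emission(path, n, cfg$frame_time, cfg$state_emission, t_offset)
  with_seed(seed, {
    E <- em$mean + rnorm(n, 0, em$sd)
    ## independent exponential bleaching clocks; Inf = no bleach
    t_d <- if (cfg$donor_bleach_rate > 0)
      rexp(1, cfg$donor_bleach_rate) else Inf
    t_a <- vapply(seq_len(cfg$acceptor_copies), function(i)
      if (cfg$acceptor_bleach_rate > 0) rexp(1, cfg$acceptor_bleach_rate)
      else Inf, numeric(1))
    frame_start <- (seq_len(n) - 1) * cfg$frame_time
    donor_dark <- frame_start >= t_d
    fret_dark <- frame_start >= t_a[1]          # FRET acceptor bleached
    copies_alive <- rowSums(outer(frame_start, t_a, `<`))

    E_eff <- ifelse(fret_dark, 0, E)
    I <- cfg$total_intensity
    F_AD_i <- ifelse(donor_dark, 0, I * E_eff)
    F_DD_i <- ifelse(donor_dark, 0, I * (1 - E_eff) / cfg$gamma)
    F_AA_i <- I * copies_alive

    bg <- cfg$background
    F_DD <- F_DD_i + bg["F_DD"] + rnorm(n, 0, cfg$noise_sd)
    F_AD <- F_AD_i + cfg$alpha * F_DD_i + cfg$delta * F_AA_i +
      bg["F_AD"] + rnorm(n, 0, cfg$noise_sd)
    F_AA <- F_AA_i + bg["F_AA"] + rnorm(n, 0, cfg$noise_sd)

    truth_E <- E
    truth_E[fret_dark | donor_dark] <- NA_real_
    structure(
      list(frames = data.frame(frame = seq_len(n), F_DD = F_DD,
                               F_AD = F_AD, F_AA = F_AA),
           frame_time = cfg$frame_time,
           truth = list(
             state = em$state, E = truth_E,
             ## first fully dark frame (frame start at/after the bleach time)
             donor_bleach_frame =
               if (any(donor_dark)) which.max(donor_dark) else Inf,
             acceptor_bleach_frame =
               if (any(fret_dark)) which.max(fret_dark) else Inf)),
      class = "raw_trace")
  })
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("raw_trace: %d frames x %.3g s (%.1f s)\n",
              nrow(x$frames), x$frame_time, nrow(x$frames) * x$frame_time))
  db <- x$truth$donor_bleach_frame; ab <- x$truth$acceptor_bleach_frame
  cat(sprintf("  truth: donor bleach frame %s, acceptor bleach frame %s\n",
              format(db), format(ab)))
  invisible(x)
}

#' Generate a time-course ensemble of synthetic traces
#'
#' Emulates the buffer-exchange experiment: at t = 0 a LiCl buffer that
#' prevents G-quadruplex formation is replaced by NaCl and every molecule
#' starts unfolded. For each requested time point an observation window of
#' one trace length is opened on fresh molecules whose conformational
#' history is simulated from t = 0, so early windows catch the
#' kinetically partitioned ensemble and late windows the equilibrated one.
#' Ground-truth state occupancy at each window opening is recorded.
#'
#' @param model a [kinetic_model()].
#' @param cfg a [generator_config()].
#' @param timepoints sorted non-negative window-opening times (s); must be
#'   non-empty.
#' @param n_molecules molecules per time point (0 gives empty, valid
#'   structure).
#' @param seed integer seed.
#' @return list of class \code{timecourse_dataset}; one element per time
#'   point with fields \code{timepoint}, \code{traces} (list of
#'   \code{raw_trace}) and \code{truth_occupancy} (named state frequencies
#'   at the window opening).
#' @export
generate_timecourse_dataset <- function(model, cfg, timepoints, n_molecules,
                                        seed = NULL) {
  stopifnot(inherits(model, "kinetic_model"),
            inherits(cfg, "generator_config"), n_molecules >= 0)
  if (length(timepoints) == 0L) stop("timepoints must be non-empty")
  stopifnot(all(timepoints >= 0), !is.unsorted(timepoints))
  ns <- model$states
  with_seed(seed, {
    out <- lapply(timepoints, function(tp) {
      counts <- setNames(numeric(length(ns)), ns)
      traces <- vector("list", n_molecules)
      for (i in seq_len(n_molecules)) {
        path <- sample_ctmc_path(model, tp + cfg$trace_length,
                                 initial_state = "U",
                                 seed = sample.int(.Machine$integer.max, 1))
        at_tp <- path$state[findInterval(tp, path$entry_time)]
        counts[at_tp] <- counts[at_tp] + 1
        traces[[i]] <- render_trace(
          path, cfg, seed = sample.int(.Machine$integer.max, 1),
          t_offset = tp)
      }
      list(timepoint = tp, traces = traces,
           truth_occupancy = if (n_molecules > 0) counts / n_molecules
                             else counts)
    })
    class(out) <- "timecourse_dataset"
    out
  })
}
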