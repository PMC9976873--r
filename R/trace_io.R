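## Plain-text trace exchange: one CSV per molecule with a 1-based frame
## index column, plus a manifest for trace sets.

#' Write / read a raw trace as CSV
#'
#' Columns \code{frame} (1-based), \code{F_DD}, \code{F_AD}, \code{F_AA},
#' and, when truth annotations exist, \code{truth_state} and
#' \code{truth_E}.
#'
#' @param trace a \code{raw_trace}.
#' @param path file path.
#' @param frame_time frame duration in seconds used when reading (default
#'   0.2).
#' @return \code{read_trace_csv} returns a \code{raw_trace};
#'   \code{write_trace_csv} returns \code{path} invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  out <- trace$frames
  if (!is.null(trace$truth)) {
    out$truth_state <- trace$truth$state
    out$truth_E <- trace$truth$E
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, frame_time = 0.2) {
  x <- read.csv(path)
  stopifnot(all(c("frame", "F_DD", "F_AD", "F_AA") %in% names(x)))
  truth <- NULL
  if ("truth_state" %in% names(x))
    truth <- list(state = x$truth_state, E = x$truth_E,
                  donor_bleach_frame = Inf, acceptor_bleach_frame = Inf)
  structure(list(frames = x[c("frame", "F_DD", "F_AD", "F_AA")],
                 frame_time = frame_time, truth = truth),
            class = "raw_trace")
}

#' Write a set of traces with a manifest
#'
#' One CSV per molecule (\code{trace_0001.csv}, ...) plus
#' \code{manifest.csv} with columns \code{file}, \code{timepoint_s},
#' \code{seed}.
#'
#' @param traces list of \code{raw_trace}.
#' @param dir output directory (created if missing).
#' @param timepoints per-trace time points for the manifest (recycled).
#' @param seed seed recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_trace_set <- function(traces, dir, timepoints = 0, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trace_%04d.csv", seq_along(traces))
  for (i in seq_along(traces))
    write_trace_csv(traces[[i]], file.path(dir, files[i]))
  manifest <- data.frame(file = files,
                         timepoint_s = rep_len(timepoints, length(traces)),
                         seed = seed)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a trace set via its manifest
#'
#' @param dir directory containing \code{manifest.csv} and the trace CSVs.
#' @param frame_time frame duration (s).
#' @return list with \code{traces} (list of \code{raw_trace}) and
#'   \code{manifest} (data frame).
#' @export
read_trace_set <- function(dir, frame_time = 0.2) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  traces <- lapply(file.path(dir, manifest$file), read_trace_csv,
                   frame_time = frame_time)
  list(traces = traces, manifest = manifest)
}

#' Read a generator configuration file
#'
#' JSON (or YAML, when the yaml package is available) key-value file whose
#' keys mirror the [generator_config()] arguments; \code{state_emission}
#' maps state names to \code{[mean, sd]} pairs and \code{background} may be
#' a single number or a per-channel mapping.
#'
#' @param path file path.
#' @return a \code{generator_config}.
#' @export
read_generator_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config files requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- x[intersect(names(x), names(formals(generator_config)))]
  if (!is.null(args$background)) args$background <- unlist(args$background)
  if (!is.null(args$state_emission))
    args$state_emission <- lapply(args$state_emission, as.numeric)
  do.call(generator_config, args)
}
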