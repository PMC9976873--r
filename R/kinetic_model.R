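#' Off-path kinetic model of consecutive G-quadruplex folding
#'
#' Constructs the kinetic state space used to describe folding of two
#' consecutive G-quadruplexes on an eight-repeat telomeric strand:
#' an unfolded state \code{U}, five one-G4 states \code{P2}..\code{P6}
#' (one G-quadruplex nucleated at each of five possible repeat positions),
#' and a fully folded state \code{F} carrying two G-quadruplexes. Only the
#' terminally positioned one-G4 conformations (\code{on_path}, by default
#' \code{P2} and \code{P6}) leave enough free repeats for a second
#' G-quadruplex and can fold on to \code{F}; internally nucleated
#' conformations are off-path and must unfold through \code{U} first.
#'
#' \code{k_f} is the total nucleation rate out of \code{U}; it is split
#' across positions by \code{nucleation_weights}, so the unfolded-state
#' lifetime is \code{1/k_f} regardless of the weights. All one-G4 states
#' unfold at the common rate \code{k_u} (equal stability at every position).
#' On-path states fold the second G-quadruplex at \code{k_f2}; \code{F}
#' unfolds back to the on-path states at total rate \code{k_u2}, split in
#' proportion to their nucleation weights.
#'
#' @param k_f total first-G4 folding (nucleation) rate out of U, 1/s.
#' @param k_u one-G4 unfolding rate, 1/s, shared by all positions.
#' @param k_f2 second-G4 folding rate from on-path states, 1/s.
#' @param k_u2 total unfolding rate of the second G4 (F to on-path), 1/s.
#' @param on_path character vector of one-G4 states that permit direct
#'   second-G4 folding; default \code{c("P2", "P6")}.
#' @param nucleation_weights named numeric vector of nucleation
#'   probabilities over \code{P2}..\code{P6}; must sum to 1. Default uniform
#'   (kinetic equipartitioning).
#' @return an object of class \code{kinetic_model}.
#' @examples
#' m <- kinetic_model(k_f = 0.05, k_u = 0.01, k_f2 = 0.1, k_u2 = 0.005)
#' initial_partition(m)$on_path_fraction  # 0.4 at uniform weights
#' @export
kinetic_model <- function(k_f, k_u, k_f2, k_u2,
                          on_path = c("P2", "P6"),
                          nucleation_weights = NULL) {
  p_states <- paste0("P", 2:6)
  rates <- c(k_f = k_f, k_u = k_u, k_f2 = k_f2, k_u2 = k_u2)
  if (!all(is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  on_path <- as.character(on_path)
  if (!all(on_path %in% p_states))
    stop("on_path states must be among ", paste(p_states, collapse = ", "))
  if (k_f2 > 0 && length(on_path) == 0L)
    stop("on_path must be non-empty when k_f2 > 0")
  if (is.null(nucleation_weights))
    nucleation_weights <- setNames(rep(1 / 5, 5), p_states)
  if (is.null(names(nucleation_weights)))
    names(nucleation_weights) <- p_states
  if (!setequal(names(nucleation_weights), p_states))
    stop("nucleation_weights must be named over ", paste(p_states, collapse = ", "))
  nucleation_weights <- nucleation_weights[p_states]
  if (any(nucleation_weights < 0) ||
      abs(sum(nucleation_weights) - 1) > 1e-8)
    stop("nucleation_weights must be non-negative and sum to 1")
  structure(
    list(states = c("U", p_states, "F"),
         k_f = k_f, k_u = k_u, k_f2 = k_f2, k_u2 = k_u2,
         on_path = on_path,
         nucleation_weights = nucleation_weights),
    class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Off-path G-quadruplex folding model\n")
  cat(sprintf("  states: %s\n", paste(x$states, collapse = " ")))
  cat(sprintf("  on-path: %s (fraction %.3g)\n",
              paste(x$on_path, collapse = " "),
              sum(x$nucleation_weights[x$on_path])))
  cat(sprintf("  rates [1/s]: k_f = %.4g, k_u = %.4g, k_f2 = %.4g, k_u2 = %.4g\n",
              x$k_f, x$k_u, x$k_f2, x$k_u2))
  invisible(x)
}

#' Generator (rate) matrix of a kinetic model
#'
#' Builds the continuous-time Markov chain generator over
#' \code{U, P2..P6, F}: \code{U -> Pi} at \code{k_f * w_i}, \code{Pi -> U}
#' at \code{k_u}, \code{Pi -> F} at \code{k_f2} for on-path \code{Pi} only,
#' and \code{F -> Pi} (on-path) at \code{k_u2} split by renormalised
#' nucleation weights. Rows sum to zero.
#'
#' @param model a \code{kinetic_model}.
#' @return a 7x7 numeric matrix with state dimnames; row sums are 0.
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  s <- model$states
  Q <- matrix(0, length(s), length(s), dimnames = list(s, s))
  w <- model$nucleation_weights
  p_states <- names(w)
  Q["U", p_states] <- model$k_f * w
  Q[p_states, "U"] <- model$k_u
  if (model$k_f2 > 0)
    Q[model$on_path, "F"] <- model$k_f2
  if (model$k_u2 > 0 && length(model$on_path) > 0) {
    w_on <- w[model$on_path]
    if (sum(w_on) <= 0)
      stop("on-path nucleation weights are all zero; F cannot unfold")
    Q["F", model$on_path] <- model$k_u2 * w_on / sum(w_on)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Post-nucleation occupancy under kinetic equipartitioning
#'
#' Occupancy over the one-G4 states immediately after fast nucleation from
#' the unfolded state, i.e. the nucleation weights themselves, together
#' with the on-path fraction (the probability that the first G-quadruplex
#' lands at a position that admits direct folding of the second). With
#' uniform weights over five positions and terminal on-path positions
#' \code{P2, P6} the on-path fraction is 2/5 = 40% and the off-path
#' fraction 60%.
#'
#' @param model a \code{kinetic_model}.
#' @return list with \code{occupancy} (named vector over P2..P6),
#'   \code{on_path_fraction} and \code{off_path_fraction}.
#' @export
initial_partition <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  w <- model$nucleation_weights
  on <- sum(w[model$on_path])
  list(occupancy = w, on_path_fraction = on, off_path_fraction = 1 - on)
}

#' Stationary distribution of the folding model
#'
#' The model graph is a tree, so the stationary distribution satisfies
#' detailed balance and has a closed form:
#' \code{pi_Pi / pi_U = k_f w_i / k_u} and
#' \code{pi_F / pi_U = k_f k_f2 W_on / (k_u k_u2)} with \code{W_on} the
#' total on-path nucleation weight. Requires an irreducible chain over the
#' reachable states: \code{k_f > 0}, \code{k_u > 0}, and \code{k_u2 > 0}
#' whenever \code{k_f2 > 0}.
#'
#' @param model a \code{kinetic_model}.
#' @return named numeric vector of stationary probabilities over all states.
#' @export
equilibrium <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  if (model$k_f <= 0 || model$k_u <= 0)
    stop("equilibrium requires k_f > 0 and k_u > 0 (chain reducible otherwise)")
  if (model$k_f2 > 0 && model$k_u2 <= 0)
    stop("equilibrium requires k_u2 > 0 when k_f2 > 0 (F is absorbing)")
  w <- model$nucleation_weights
  rel <- c(U = 1, model$k_f * w / model$k_u)
  w_on <- sum(w[model$on_path])
  rel_F <- if (model$k_f2 > 0)
    model$k_f * model$k_f2 * w_on / (model$k_u * model$k_u2) else 0
  pi <- c(rel, F = rel_F)
  names(pi) <- model$states
  pi / sum(pi)
}

#' Gibbs free energy difference from a rate ratio
#'
#' Converts folding/unfolding rate constants into the standard free-energy
#' difference of the folding step, \eqn{\Delta G = -RT \ln(k_{fold}/k_{unfold})},
#' in kJ/mol. Negative values favour the folded state.
#'
#' @param k_fold folding rate constant, 1/s; must be > 0.
#' @param k_unfold unfolding rate constant, 1/s; must be > 0.
#' @param temperature absolute temperature in K (default 298.15).
#' @return free energy difference in kJ/mol.
#' @examples
#' delta_g(1, 1)           # 0
#' delta_g(exp(1), 1)      # -RT = -2.479 kJ/mol at 298.15 K
#' @export
delta_g <- function(k_fold, k_unfold, temperature = 298.15) {
  if (!is.finite(k_fold) || !is.finite(k_unfold) ||
      k_fold <= 0 || k_unfold <= 0)
    stop("both rate constants must be finite and > 0")
  stopifnot(temperature > 0)
  -.R_GAS * temperature * log(k_fold / k_unfold) / 1000
}

#' Read / write a kinetic model as JSON
#'
#' The file is a flat key-value mapping mirroring the \code{kinetic_model}
#' fields (\code{k_f}, \code{k_u}, \code{k_f2}, \code{k_u2}, \code{on_path},
#' \code{nucleation_weights}). YAML files with the same keys are accepted
#' when the yaml package is available.
#'
#' @param path file path.
#' @param model a \code{kinetic_model} (for writing).
#' @return \code{read_kinetic_model} returns a \code{kinetic_model};
#'   \code{write_kinetic_model} returns \code{path} invisibly.
#' @export
read_kinetic_model <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML model files requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  nw <- if (!is.null(x$nucleation_weights)) unlist(x$nucleation_weights)
  kinetic_model(k_f = x$k_f, k_u = x$k_u, k_f2 = x$k_f2, k_u2 = x$k_u2,
                on_path = if (is.null(x$on_path)) c("P2", "P6") else unlist(x$on_path),
                nucleation_weights = nw)
}

#' @rdname read_kinetic_model
#' @export
write_kinetic_model <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  jsonlite::write_json(
    list(k_f = model$k_f, k_u = model$k_u,
         k_f2 = model$k_f2, k_u2 = model$k_u2,
         on_path = model$on_path,
         nucleation_weights = as.list(model$nucleation_weights)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
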