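#' RMSE fitness of a candidate parameter vector
#'
#' Decodes `position` into the template model, evaluates the network on
#' every observation row and returns the root mean square error against
#' the targets: `sqrt(sum((z - z_M)^2) / N)`. A forward-pass failure on
#' any row (all firing strengths underflowing to zero) yields `Inf` with
#' a warning, so the optimizer penalizes rather than crashes.
#'
#' @param template An `anfis` model fixing the structure.
#' @param position Flat parameter vector (see [params_to_vector()]).
#' @param X Observation matrix (`N x n_inputs`).
#' @param z Numeric target vector of length `N`.
#' @return Scalar RMSE (possibly `Inf`).
#' @export
rmse_fitness <- function(template, position, X, z) {
  if (nrow(X) != length(z)) stop("X rows and z length differ")
  model <- vector_to_params(position, template)
  out <- anfis_evaluate(model, X)
  if (anyNA(out)) {
    warning("forward pass failed on ", sum(is.na(out)),
            " observation(s); fitness set to Inf")
    return(Inf)
  }
  sqrt(sum((z - out)^2) / length(z))
}

#' Train a fuzzy model on observations by particle swarm optimization
#'
#' Builds a grid-partition model over the training data's per-feature
#' ranges, then searches the full parameter vector (premise and consequent
#' parameters jointly) with the inertia-weight PSO, minimizing RMSE
#' between network outputs and the numeric targets. Particle 1 is seeded
#' at the grid-partition defaults; all other particles start uniformly
#' within the bounds.
#'
#' @param X Numeric observation matrix (`N x n` with column names).
#' @param z Numeric targets of length `N` (e.g. 0 for controls, 4 for
#'   patients).
#' @param m Membership functions per input (default 2).
#' @param cfg A [pso_config()]; its `lower`/`upper`/`init_*` slots are
#'   filled from the model bounds when `NULL`.
#' @return An object of class `anfis_fit`: `model` (trained `anfis`),
#'   `rmse` (final training RMSE), `history` (global-best RMSE per
#'   iteration) and `config`.
#' @export
anfis_train <- function(X, z, m = 2L, cfg = pso_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("no training observations")
  if (nrow(X) != length(z)) stop("X rows and z length differ")
  ranges <- t(apply(X, 2L, range))
  template <- build_grid_model(ranges, m = m)
  if (is.null(cfg$lower)) {
    bnd <- anfis_param_bounds(template)
    cfg$lower <- bnd$lower; cfg$upper <- bnd$upper
    cfg$init_lower <- bnd$init_lower; cfg$init_upper <- bnd$init_upper
  }
  D <- anfis_dim(template$n_inputs, template$m)
  fit <- pso_optimize(function(p) rmse_fitness(template, p, X, z),
                      D, cfg, init_position = params_to_vector(template))
  structure(list(model = vector_to_params(fit$par, template),
                 rmse = fit$value, history = fit$history, config = cfg),
            class = "anfis_fit")
}

#' @export
print.anfis_fit <- function(x, ...) {
  cat("<anfis_fit> trained model:", x$model$n_inputs, "inputs,",
      nrow(x$model$rule_mf), "rules\n")
  cat("  PSO:", x$config$n_particles, "particles x", x$config$max_iters,
      "iterations; RMSE", format(x$history[1L], digits = 4), "->",
      format(x$rmse, digits = 4), "\n")
  invisible(x)
}
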