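# Independent naive evaluation of the five-layer Sugeno network, written
# as plain nested loops straight from the layer equations. Used as the
# oracle against the package's vectorized forward pass; it shares no code
# with the implementation.
naive_anfis_forward <- function(model, x) {
  n <- model$n_inputs
  R <- nrow(model$rule_mf)
  w <- numeric(R)
  for (r in seq_len(R)) {
    prod_mu <- 1
    for (j in seq_len(n)) {
      i <- model$rule_mf[r, j]
      mu <- 1 / (1 + abs((x[j] - model$c[i, j]) / model$a[i, j])^
                   (2 * model$b[i, j]))
      prod_mu <- prod_mu * mu
    }
    w[r] <- prod_mu
  }
  s <- sum(w)
  out <- 0
  for (r in seq_len(R)) {
    f_r <- model$coeffs[r, n + 1]
    for (j in seq_len(n)) f_r <- f_r + model$coeffs[r, j] * x[j]
    out <- out + (w[r] / s) * f_r
  }
  out
}

# Random model with parameters in sane, non-degenerate windows; consumes
# the caller's RNG stream.
random_anfis <- function(n = 2L, m = 2L) {
  ranges <- cbind(rep(-1, n), rep(1, n))
  model <- build_grid_model(ranges, m = m)
  model$a <- matrix(runif(m * n, 0.3, 2), m, n)
  model$b <- matrix(runif(m * n, 0.5, 4), m, n)
  model$c <- matrix(runif(m * n, -1.5, 1.5), m, n)
  model$coeffs <- matrix(runif(nrow(model$rule_mf) * (n + 1), -5, 5),
                         nrow(model$rule_mf), n + 1)
  model
}

# Build a gait record from per-feature value vectors with a simple
# increasing time axis (or an explicit one).
make_record <- function(..., subject_id = "s1", group = "CO", time = NULL,
                        severity = NA_real_) {
  cols <- list(...)
  feats <- do.call(cbind, cols)
  colnames(feats) <- names(cols)
  if (is.null(time)) time <- seq_len(nrow(feats))
  gait_record(subject_id, group, time, feats, severity)
}

# Record with all five model features constant at `level` except where
# overridden; convenient for planted-truth preprocessing tests.
make_flat_record <- function(n, level = 1.1, subject_id = "s1",
                             group = "CO", time = NULL) {
  feats <- matrix(level, n, 5,
                  dimnames = list(NULL, gaitanfis::MODEL_FEATURES))
  if (is.null(time)) time <- seq_len(n)
  gait_record(subject_id, group, time, feats)
}
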