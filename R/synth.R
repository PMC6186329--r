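#' Specification of one synthetic cohort group
#'
#' Describes how to simulate gait records for one group: per-feature mean
#' and SD of the five model features (seconds), stride-to-stride lag-1
#' autocorrelation, cross-feature correlation, walk duration and the
#' hallway turn structure (subjects walk back and forth, producing a large
#' stride-time spike at each turn).
#'
#' @param label Group label (one of [GAIT_GROUPS]).
#' @param n_subjects Number of subjects to simulate.
#' @param means,sds Numeric length-5 vectors in [MODEL_FEATURES] order
#'   (seconds); SDs may be 0 for degenerate noise-free records.
#' @param phi Lag-1 autocorrelation of the stride-to-stride fluctuations,
#'   in `[0, 0.95]` (default 0.3).
#' @param rho Cross-feature correlation of the fluctuations, in
#'   `[0, 0.95]` (default 0.5).
#' @param between_frac Fraction of each feature's SD attributed to stable
#'   between-subject differences (default 0.4); the within-subject SD is
#'   shrunk so the pooled SD matches `sds`.
#' @param walk_duration_s Walk length in seconds (default 300, a 5-minute
#'   hallway walk).
#' @param gait_speed Typical walking speed in m/s, used with
#'   `hallway_length_m` to place turns.
#' @param hallway_length_m Hallway length in meters (default 77).
#' @param turn_sd_mult Turn spike magnitude in SD multiples added to both
#'   stride intervals (default 8).
#' @param severity Severity sampling spec: for ALS
#'   `list(type = "duration", mean, sd)`; for PD `list(type = "hy",
#'   n_severe)`; for HD `list(type = "tfc", n_severe)`; `NULL` for CO.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(label, n_subjects, means, sds, phi = 0.3, rho = 0.5,
                       between_frac = 0.4, walk_duration_s = 300,
                       gait_speed = 1.2, hallway_length_m = 77,
                       turn_sd_mult = 8, severity = NULL) {
  stopifnot(label %in% GAIT_GROUPS, n_subjects >= 1L,
            length(means) == 5L, length(sds) == 5L,
            all(means > 0), all(sds >= 0),
            phi >= 0, phi <= 0.95, rho >= 0, rho <= 0.95,
            between_frac >= 0, between_frac < 1,
            walk_duration_s > 0, gait_speed > 0, turn_sd_mult >= 0)
  names(means) <- names(sds) <- MODEL_FEATURES
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 means = means, sds = sds, phi = phi, rho = rho,
                 between_frac = between_frac,
                 walk_duration_s = walk_duration_s,
                 gait_speed = gait_speed,
                 hallway_length_m = hallway_length_m,
                 turn_sd_mult = turn_sd_mult, severity = severity),
            class = "group_spec")
}

#' Default group specifications
#'
#' Calibrated to the study cohort: 13 ALS, 15 PD, 20 HD and 16 CO
#' subjects, with per-group feature means and SDs matching the reported
#' summary statistics of the five gait features, and gait speeds matching
#' the reported group averages. PD and HD severity covariates are sampled
#' so that 9 subjects per group fall in the severe stratum (H&Y >= 3,
#' TFC <= 5); ALS severity is a disease-duration covariate.
#'
#' @return Named list of four [group_spec()] objects (ALS, PD, HD, CO).
#' @export
default_group_specs <- function() {
  list(
    ALS = group_spec("ALS", 13L,
      means = c(1.520, 1.520, 1.043, 1.023, 0.546),
      sds   = c(0.093, 0.095, 0.092, 0.078, 0.080),
      gait_speed = 1.05,
      severity = list(type = "duration", mean = 18.3, sd = 17.8)),
    PD = group_spec("PD", 15L,
      means = c(1.173, 1.173, 0.788, 0.814, 0.429),
      sds   = c(0.052, 0.046, 0.047, 0.052, 0.066),
      gait_speed = 1.0,
      severity = list(type = "hy", n_severe = 9L)),
    HD = group_spec("HD", 20L,
      means = c(1.146, 1.146, 0.763, 0.800, 0.416),
      sds   = c(0.093, 0.093, 0.072, 0.066, 0.071),
      gait_speed = 1.15,
      severity = list(type = "tfc", n_severe = 9L)),
    CO = group_spec("CO", 16L,
      means = c(1.112, 1.112, 0.737, 0.720, 0.345),
      sds   = c(0.083, 0.077, 0.073, 0.060, 0.057),
      gait_speed = 1.35,
      severity = NULL))
}

#' Group specifications with guaranteed class separation
#'
#' Returns the default specs with each disease group's feature means
#' pushed away from the control means wherever the existing gap is below
#' `k` pooled SDs: the adjusted mean is
#' `mean_CO + sign(delta) * max(|delta|, k * sd_pooled)` with
#' `sd_pooled = sqrt((sd_g^2 + sd_CO^2)/2)`. This is the separability
#' construction used to validate end-to-end recovery: with every feature
#' at least `k` pooled SDs from control, a working pipeline must classify
#' nearly perfectly.
#'
#' @param k Minimum separation in pooled SDs (default 3).
#' @return Named list of four [group_spec()] objects.
#' @export
separated_group_specs <- function(k = 3) {
  specs <- default_group_specs()
  co <- specs$CO
  for (g in c("ALS", "PD", "HD")) {
    delta <- specs[[g]]$means - co$means
    pooled <- sqrt((specs[[g]]$sds^2 + co$sds^2) / 2)
    s <- ifelse(delta >= 0, 1, -1)
    specs[[g]]$means <- co$means + s * pmax(abs(delta), k * pooled)
  }
  specs
}

# Stationary AR(1) innovations with cross-feature correlation rho:
# returns an n x 5 matrix with unit marginal variance per column.
ar1_noise <- function(n, phi, rho) {
  R <- matrix(rho, 5L, 5L); diag(R) <- 1
  L <- tryCatch(chol(R), error = function(e)
    stop("cross-feature correlation matrix is not positive definite"))
  E <- matrix(stats::rnorm(n * 5L), n, 5L) %*% L
  if (phi > 0 && n > 1L) {
    S <- E
    for (t in 2:n) S[t, ] <- phi * S[t - 1L, ] + sqrt(1 - phi^2) * E[t, ]
    S
  } else E
}

#' Simulate one subject's gait record
#'
#' Stride-to-stride fluctuations follow a stationary lag-1 autoregressive
#' process with truncated-Gaussian marginals; the five features share a
#' common cross-correlation. The subject's own feature means are drawn
#' around the group means (between-subject variability), elapsed time is
#' the cumulative left stride interval, and a stride-time spike is
#' injected into both stride intervals each time the cumulative distance
#' walked reaches a hallway length (a walking turn). Records that produce
#' any non-positive interval are re-drawn.
#'
#' @param spec A [group_spec()].
#' @param subject_id Subject identifier.
#' @param seed RNG seed; the record is a deterministic function of
#'   (spec, subject_id, seed).
#' @param severity Severity covariate to attach (sampled by
#'   [generate_cohort()]).
#' @param n_strides Optional stride count override (otherwise derived
#'   from walk duration and mean stride time).
#' @return A [gait_record()] with the five model features plus swing
#'   columns, and attribute `"turn_indices"` giving the planted turn rows.
#' @export
generate_subject <- function(spec, subject_id, seed, severity = NA_real_,
                             n_strides = NULL) {
  set.seed(seed)
  n <- if (is.null(n_strides))
    as.integer(ceiling(spec$walk_duration_s / spec$means["left_stride"]))
  else as.integer(n_strides)
  mu_subj <- spec$means + spec$between_frac * spec$sds *
    as.numeric(stats::rnorm(5L))
  mu_subj <- pmax(mu_subj, 0.05)
  sd_within <- spec$sds * sqrt(1 - spec$between_frac^2)

  for (attempt in 1:50) {
    V <- ar1_noise(n, spec$phi, spec$rho)
    V <- sweep(V, 2L, sd_within, "*")
    V <- sweep(V, 2L, mu_subj, "+")
    if (all(V > 0)) break
    if (attempt == 50L) stop("could not generate positive intervals; ",
                             "check the group spec means and SDs")
  }
  colnames(V) <- MODEL_FEATURES

  # plant walking turns every hallway traversal
  turn_period_s <- spec$hallway_length_m / spec$gait_speed
  t_pre <- cumsum(V[, "left_stride"])
  turn_times <- if (max(t_pre) >= turn_period_s)
    seq(turn_period_s, max(t_pre), by = turn_period_s) else numeric(0)
  turn_idx <- unique(vapply(turn_times,
                            function(tt) which.min(abs(t_pre - tt)),
                            integer(1L)))
  spike <- spec$turn_sd_mult * pmax(spec$sds[c("left_stride",
                                               "right_stride")], 1e-3)
  V[turn_idx, "left_stride"] <- V[turn_idx, "left_stride"] + spike[1L]
  V[turn_idx, "right_stride"] <- V[turn_idx, "right_stride"] + spike[2L]

  feats <- cbind(V,
                 left_swing = V[, "left_stride"] - V[, "left_stance"],
                 right_swing = V[, "right_stride"] - V[, "right_stance"])
  rec <- gait_record(subject_id, spec$label,
                     time = cumsum(feats[, "left_stride"]),
                     features = feats, severity = severity)
  attr(rec, "turn_indices") <- turn_idx
  rec
}

# Sample a group's severity covariates under the current RNG state.
sample_severities <- function(spec) {
  n <- spec$n_subjects
  sv <- spec$severity
  if (is.null(sv)) return(rep(NA_real_, n))
  switch(sv$type,
    duration = {
      x <- stats::rnorm(n, sv$mean, sv$sd)
      pmax(x, 0.5)
    },
    hy = {
      v <- sample(c(1, 1.5, 2, 2.5), n, replace = TRUE)
      sev <- sample.int(n, sv$n_severe)
      v[sev] <- sample(c(3, 3.5, 4, 4.5, 5), sv$n_severe, replace = TRUE)
      v
    },
    tfc = {
      v <- sample(6:13, n, replace = TRUE)
      sev <- sample.int(n, sv$n_severe)
      v[sev] <- sample(0:5, sv$n_severe, replace = TRUE)
      as.numeric(v)
    },
    stop("unknown severity spec type: ", sv$type))
}

#' Generate a synthetic cohort
#'
#' Simulates every subject of every group spec, optionally writing one
#' gaitndd-style file per subject plus a manifest to `dir`. Severity
#' covariates are sampled per group; subject RNG seeds derive from `seed`
#' and the subject's ordinal, so regeneration under the same seed is
#' byte-identical.
#'
#' @param specs Named list of [group_spec()] objects (e.g.
#'   [default_group_specs()]).
#' @param seed Integer base seed.
#' @param dir Output directory (created if needed); `NULL` keeps the
#'   cohort in memory only.
#' @return List with `manifest` (data.frame: file, subject, group,
#'   severity) and `records` (named list of [gait_record()] objects).
#' @export
generate_cohort <- function(specs = default_group_specs(), seed = 1L,
                            dir = NULL) {
  set.seed(seed)
  severities <- lapply(specs, sample_severities)
  records <- list()
  rows <- list()
  k <- 0L
  for (g in names(specs)) {
    spec <- specs[[g]]
    for (i in seq_len(spec$n_subjects)) {
      k <- k + 1L
      id <- sprintf("%s%02d", tolower(spec$label), i)
      rec <- generate_subject(spec, id, seed = seed + k,
                              severity = severities[[g]][i])
      records[[id]] <- rec
      rows[[k]] <- data.frame(file = paste0(id, ".ts"), subject = id,
                              group = spec$label,
                              severity = severities[[g]][i],
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in names(records))
      write_gait_record(records[[id]],
                        file.path(dir, paste0(id, ".ts")))
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
  }
  list(manifest = manifest, records = records)
}
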