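#' Define a classification experiment
#'
#' An experiment opposes a positive group set (one or more disease groups,
#' or derived strata such as `"SEVERE"`) to a negative group set (normally
#' the healthy controls). Observations of negative-group subjects carry
#' target 0 and positive-group observations target 4; a held-out subject
#' is labeled by whichever target its mean network output is closer to.
#'
#' @param positive Character vector of positive group labels
#'   (e.g. `"ALS"`, or `c("ALS", "PD", "HD")` for the combined ND class).
#' @param negative Character vector of negative group labels
#'   (default `"CO"`).
#' @param target_negative,target_positive Regression targets (0 and 4).
#' @param n_mfs Membership functions per input (default 2, giving
#'   `2^5 = 32` rules over the five gait features).
#' @param preprocess A [preprocess_config()].
#' @param pso A [pso_config()]; each cross-validation fold runs a fresh
#'   PSO whose seed is derived from `seed` and the held-out subject's id.
#' @param seed Base seed of the experiment.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(positive, negative = "CO",
                            target_negative = 0, target_positive = 4,
                            n_mfs = 2L,
                            preprocess = preprocess_config(),
                            pso = pso_config(), seed = 1L) {
  stopifnot(length(positive) >= 1L, length(negative) >= 1L,
            length(intersect(positive, negative)) == 0L,
            target_negative != target_positive)
  structure(list(positive = positive, negative = negative,
                 target_negative = target_negative,
                 target_positive = target_positive,
                 n_mfs = as.integer(n_mfs), preprocess = preprocess,
                 pso = pso, seed = as.integer(seed)),
            class = "experiment_spec")
}

# Deterministic 31-bit sub-seed from the experiment seed and a subject id,
# so fold randomness is reproducible and invariant to cohort ordering.
subject_seed <- function(base_seed, subject_id) {
  codes <- utf8ToInt(subject_id)
  h <- 0
  for (ch in codes) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(base_seed) * 7919 + h) %% (.Machine$integer.max - 1L) + 1L)
}

#' Classify one subject by the minimum-distance rule
#'
#' Evaluates the trained network on every observation of the subject,
#' averages the outputs and assigns the label whose target is closer to
#' the average. A mean output exactly at the midpoint is classified
#' positive (deterministic, clinically conservative tie-break).
#'
#' @param model A trained `anfis` model.
#' @param obs An [observation_set()].
#' @param targets Length-2 numeric vector `c(t_negative, t_positive)`.
#' @return List of class `subject_prediction` with `subject_id`, `group`,
#'   `mean_output` and `predicted` (`"positive"` or `"negative"`).
#' @export
predict_subject <- function(model, obs, targets = c(0, 4)) {
  stopifnot(inherits(obs, "observation_set"), length(targets) == 2L)
  if (nrow(obs$X) == 0L)
    stop("no observations for subject ", obs$subject_id)
  out <- anfis_evaluate(model, obs$X)
  if (anyNA(out)) {
    warning("forward pass failed on ", sum(is.na(out)),
            " observation(s) of subject ", obs$subject_id)
    out <- out[!is.na(out)]
    if (length(out) == 0L)
      stop("forward pass failed on every observation of subject ",
           obs$subject_id)
  }
  ybar <- mean(out)
  predicted <- if (abs(ybar - targets[2L]) <= abs(ybar - targets[1L]))
    "positive" else "negative"
  structure(list(subject_id = obs$subject_id, group = obs$group,
                 mean_output = ybar, predicted = predicted),
            class = "subject_prediction")
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject in turn, a fresh model is trained by PSO on the pooled
#' observations of all remaining subjects (targets assigned per group) and
#' the held-out subject is classified by the minimum-distance rule on its
#' mean output. Per-fold membership-function ranges come from that fold's
#' training data only, so no information from the held-out subject leaks
#' into training. Folds are processed in sorted subject-id order and fold
#' seeds derive from subject ids, making results invariant to the order in
#' which the cohort is supplied.
#'
#' @param observations List of [observation_set()] objects. Subjects whose
#'   group is in neither group set of the spec are ignored.
#' @param spec An [experiment_spec()].
#' @return List of class `loocv_result`: `predictions` (data.frame with
#'   subject, group, truth, mean_output, predicted), `confusion`
#'   ([confusion_matrix()]) and `metrics` ([compute_metrics()] output).
#' @export
loocv <- function(observations, spec) {
  groups <- vapply(observations, function(o) o$group, character(1L))
  keep <- groups %in% c(spec$positive, spec$negative)
  observations <- observations[keep]
  groups <- groups[keep]
  ids <- vapply(observations, function(o) o$subject_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort")
  ord <- order(ids)
  observations <- observations[ord]; groups <- groups[ord]; ids <- ids[ord]

  is_pos <- groups %in% spec$positive
  if (sum(is_pos) < 2L || sum(!is_pos) < 2L)
    stop("at least 2 subjects per class are required for LOOCV")
  targets <- ifelse(is_pos, spec$target_positive, spec$target_negative)

  preds <- vector("list", length(observations))
  for (i in seq_along(observations)) {
    train_idx <- setdiff(seq_along(observations), i)
    if (length(unique(is_pos[train_idx])) < 2L)
      stop("a class is absent from the training fold for subject ", ids[i])
    X <- do.call(rbind, lapply(observations[train_idx], function(o) o$X))
    z <- unlist(lapply(train_idx, function(j)
      rep(targets[j], nrow(observations[[j]]$X))))
    cfg <- spec$pso
    cfg$seed <- subject_seed(spec$seed, ids[i])
    fit <- anfis_train(X, z, m = spec$n_mfs, cfg = cfg)
    p <- predict_subject(fit$model, observations[[i]],
                         targets = c(spec$target_negative,
                                     spec$target_positive))
    preds[[i]] <- data.frame(
      subject = ids[i], group = groups[i],
      truth = if (is_pos[i]) "positive" else "negative",
      mean_output = p$mean_output, predicted = p$predicted,
      stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  cm <- confusion_from_labels(predictions$truth, predictions$predicted)
  structure(list(predictions = predictions, confusion = cm,
                 metrics = compute_metrics(cm)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("Leave-one-subject-out cross-validation (",
      nrow(x$predictions), " folds)\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Split the patient cohort by disease severity
#'
#' Severe impairment is defined per disease: PD patients with a Hoehn &
#' Yahr score >= 3, HD patients with a total functional capacity score
#' <= 5, and ALS patients whose mean stride time (average of left and
#' right stride intervals over the record) exceeds 1.2 s. Remaining
#' patients form the mild group; controls are not split. Patients whose
#' required covariate or record is missing are excluded with a warning.
#'
#' @param manifest Cohort manifest data.frame (columns `subject`, `group`,
#'   `severity`).
#' @param records Named list of (preprocessed) [gait_record()] objects,
#'   required for the ALS stride criterion.
#' @return List with character vectors `severe`, `mild` and `excluded`.
#' @export
severity_split <- function(manifest, records = list()) {
  severe <- mild <- excluded <- character(0)
  for (i in seq_len(nrow(manifest))) {
    grp <- manifest$group[i]; id <- manifest$subject[i]
    if (grp == "CO") next
    status <- switch(grp,
      PD = if (is.na(manifest$severity[i])) NA
           else manifest$severity[i] >= 3,
      HD = if (is.na(manifest$severity[i])) NA
           else manifest$severity[i] <= 5,
      ALS = {
        rec <- records[[id]]
        if (is.null(rec)) NA
        else mean(rec$features[, c("left_stride", "right_stride")]) > 1.2
      })
    if (is.na(status)) {
      warning("subject ", id, " (", grp,
              ") lacks its severity covariate; excluded from the split")
      excluded <- c(excluded, id)
    } else if (status) severe <- c(severe, id) else mild <- c(mild, id)
  }
  list(severe = severe, mild = mild, excluded = excluded)
}

#' Run a complete classification experiment
#'
#' Preprocesses every record, converts the retained segments to
#' observations, runs leave-one-subject-out cross-validation and returns
#' a report. Subjects left with no usable segment are dropped with a
#' warning.
#'
#' @param spec An [experiment_spec()].
#' @param records Named list of raw [gait_record()] objects with group
#'   labels set.
#' @return A list of class `gait_experiment`: the `spec`, `n_subjects`,
#'   per-subject `predictions`, `confusion`, `metrics` and `seed`.
#' @export
run_experiment <- function(spec, records) {
  obs <- list()
  for (rec in records) {
    if (!(rec$group %in% c(spec$positive, spec$negative))) next
    o <- tryCatch(
      to_observations(preprocess_record(rec, spec$preprocess)),
      error = function(e) {
        warning("subject ", rec$subject_id, " unusable: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(o)) obs[[length(obs) + 1L]] <- o
  }
  cv <- loocv(obs, spec)
  structure(list(spec = spec, n_subjects = length(obs),
                 predictions = cv$predictions, confusion = cv$confusion,
                 metrics = cv$metrics, seed = spec$seed),
            class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat("Gait classification experiment: ",
      paste(x$spec$positive, collapse = "+"), " vs ",
      paste(x$spec$negative, collapse = "+"),
      "  (", x$n_subjects, " subjects, seed ", x$seed, ")\n", sep = "")
  print(x$confusion)
  invisible(x)
}
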