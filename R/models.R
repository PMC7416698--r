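# Supervised structure-function models: two random-forest families fit to
# per-eccentricity samples, validated subject-wise.
#
# Model I uses segmentation-derived features (ONL, IS, COS, RPE thicknesses,
# the extrema count between ELM and BrM, folded eccentricity, and the
# ONL*COS / thickness*eccentricity interaction terms). Model II uses only
# the raw reflectivity vector (plus the folded eccentricity position tag).
# Each family predicts either foveal sensitivity (FS, dB) or decimal visual
# acuity (VA); the subject-level prediction is the unweighted mean of the
# subject's 21 row-level predictions (3 scans x 7 eccentricities).

#' One subject's functional targets and structural samples
#'
#' @param subject_id identifier.
#' @param group cohort label (`IRD`, `normal`, `BCM_deletion`, `BCM_C203R`).
#' @param fs_measured foveal sensitivity in dB, or `NA` for non-detectable.
#' @param va_measured decimal acuity (> 0).
#' @param samples data frame of 21 rows (3 scans x 7 eccentricities) with
#'   columns `scan_id`, `eccentricity`, `onl`, `is_len`, `cos_len`, `rpe`,
#'   `n_extrema` and `refl_*` (see [extract_samples()]).
#' @param n_scans,n_ecc expected design (defaults 3 x 7).
#' @return object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, fs_measured, va_measured,
                           samples, n_scans = 3, n_ecc = 7) {
  if (nrow(samples) != n_scans * n_ecc)
    stopf("subject %s: expected %d samples (%d scans x %d eccentricities), got %d",
          subject_id, n_scans * n_ecc, n_scans, n_ecc, nrow(samples))
  if (length(unique(samples$scan_id)) != n_scans)
    stopf("subject %s: expected %d distinct scans", subject_id, n_scans)
  if (!is.na(va_measured) && va_measured <= 0)
    stopf("va_measured must be positive")
  structure(list(subject_id = subject_id, group = group,
                 fs_measured = fs_measured, va_measured = va_measured,
                 samples = samples),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s [%s]: FS %s dB, VA %s, %d samples\n",
              x$subject_id, x$group,
              if (is.na(x$fs_measured)) "ND" else format(x$fs_measured),
              format(x$va_measured), nrow(x$samples)))
  invisible(x)
}

#' Specification of one of the four model family / target combinations
#'
#' The four models are I-FS, I-VA (segmentation features) and II-FS, II-VA
#' (reflectivity features). Forest hyperparameters default to conventional
#' regression-forest settings: 500 trees, minimum leaf size 2, and
#' `floor(p/3)` candidate features per split.
#'
#' @param family `"I"` or `"II"`.
#' @param target `"FS"` or `"VA"`.
#' @param n_trees number of trees.
#' @param min_leaf minimum observations per leaf.
#' @param features_per_split candidate features per split; `NULL` means
#'   `floor(p/3)`.
#' @param seed base RNG seed; per-fold seeds are derived from it and the
#'   held-out subject id.
#' @param ecc_tag_II include the folded eccentricity as a position tag in
#'   Model II (rows are otherwise position-ambiguous).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("I", "II"), target = c("FS", "VA"),
                       n_trees = 500, min_leaf = 2,
                       features_per_split = NULL, seed = 1,
                       ecc_tag_II = TRUE) {
  family <- match.arg(family)
  target <- match.arg(target)
  stopifnot(n_trees >= 1, min_leaf >= 1)
  structure(list(family = family, target = target, n_trees = n_trees,
                 min_leaf = min_leaf, features_per_split = features_per_split,
                 seed = seed, ecc_tag_II = ecc_tag_II),
            class = "model_spec")
}

#' Model I design matrix: segmentation features with interaction terms
#'
#' One row per sample with columns ONL, IS, COS, RPE, extrema count, folded
#' eccentricity `|ecc|`, and the interactions `ONL*COS`, `ONL*|ecc|`,
#' `COS*|ecc|`. Eccentricity enters folded (nasal/temporal symmetric).
#' A flagged (NA) thickness is imputed as 0 with a matching indicator
#' column: an absent band (e.g. an IS/OS defect) is signal, not missing at
#' random.
#'
#' @param samples samples data frame (see [subject_record()]).
#' @return numeric matrix.
#' @export
design_matrix_I <- function(samples) {
  need <- c("onl", "is_len", "cos_len", "rpe", "n_extrema", "eccentricity")
  if (!all(need %in% names(samples)))
    stopf("samples must have columns %s", paste(need, collapse = ", "))
  imp <- function(v) ifelse(is.na(v), 0, v)
  onl <- imp(samples$onl); cosl <- imp(samples$cos_len)
  ae <- abs(samples$eccentricity)
  cbind(onl = onl, is_len = imp(samples$is_len), cos_len = cosl,
        rpe = imp(samples$rpe), n_extrema = imp(samples$n_extrema),
        abs_ecc = ae,
        onl_x_cos = onl * cosl, onl_x_ecc = onl * ae, cos_x_ecc = cosl * ae,
        miss_onl = as.numeric(is.na(samples$onl)),
        miss_is = as.numeric(is.na(samples$is_len)),
        miss_cos = as.numeric(is.na(samples$cos_len)),
        miss_rpe = as.numeric(is.na(samples$rpe)))
}

#' Model II design matrix: reflectivity values only
#'
#' One row per sample holding the LRP resampled at fixed depths above BrM,
#' plus (by default) the folded eccentricity as a position tag. Samples with
#' incomplete reflectivity vectors (ragged input) are rejected.
#'
#' @param samples samples data frame.
#' @param ecc_tag include `|ecc|` column.
#' @return numeric matrix.
#' @export
design_matrix_II <- function(samples, ecc_tag = TRUE) {
  rc <- grep("^refl_", names(samples), value = TRUE)
  if (!length(rc)) stopf("samples carry no reflectivity columns")
  m <- as.matrix(samples[rc])
  if (anyNA(m)) stopf("ragged or incomplete reflectivity vectors rejected")
  if (ecc_tag) m <- cbind(m, abs_ecc = abs(samples$eccentricity))
  m
}

.target_of <- function(record, target) {
  if (target == "FS") record$fs_measured else record$va_measured
}

.design_of <- function(samples, spec) {
  if (spec$family == "I") design_matrix_I(samples)
  else design_matrix_II(samples, ecc_tag = spec$ecc_tag_II)
}

.stack_training <- function(records, spec) {
  X <- do.call(rbind, lapply(records, function(r) .design_of(r$samples, spec)))
  y <- unlist(lapply(records, function(r)
    rep(.target_of(r, spec$target), nrow(r$samples))))
  list(X = X, y = y)
}

#' Root-mean-square error
#'
#' `sqrt(mean((measured - predicted)^2))`: the per-subject differences are
#' squared, averaged, and the square root extracted.
#'
#' @param measured,predicted equal-length numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted)) stopf("length mismatch")
  if (!length(measured)) stopf("need at least one observation")
  sqrt(mean((measured - predicted)^2))
}

#' Leave-one-subject-out evaluation of a model specification
#'
#' One fold per subject: the forest is refit on all rows of the remaining
#' subjects and the held-out subject's prediction is the unweighted mean of
#' its 21 row-level predictions. No held-out row ever enters its own fold's
#' training set (the split is by subject id). Per-fold seeds are derived
#' from the spec's base seed and the held-out subject id, so the evaluation
#' is reproducible and folds are independent. Subjects with a missing
#' target (e.g. non-detectable FS) are excluded with a warning.
#'
#' @param records list of [subject_record()]s (>= 3 with targets).
#' @param spec a [model_spec()].
#' @return object of class `model_evaluation`: `per_subject` data frame
#'   (`subject_id`, `measured`, `predicted`), `rmse`, `n_folds`, `spec`.
#' @export
loso_evaluate <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  has_target <- vapply(records, function(r) !is.na(.target_of(r, spec$target)),
                       logical(1))
  if (any(!has_target))
    warning(sprintf("%d subject(s) without %s target excluded from folds",
                    sum(!has_target), spec$target))
  records <- records[has_target]
  if (length(records) < 3) stopf("need at least 3 subjects with targets")

  res <- lapply(seq_along(records), function(i) {
    train <- .stack_training(records[-i], spec)
    mtry <- spec$features_per_split %||% max(1L, floor(ncol(train$X) / 3))
    forest <- rf_fit_cpp(train$X, train$y, spec$n_trees, mtry, spec$min_leaf,
                         derive_seed(spec$seed, records[[i]]$subject_id))
    Xtest <- .design_of(records[[i]]$samples, spec)
    data.frame(subject_id = records[[i]]$subject_id,
               measured = .target_of(records[[i]], spec$target),
               predicted = mean(rf_predict_cpp(forest, Xtest)))
  })
  per_subject <- do.call(rbind, res)
  structure(list(per_subject = per_subject,
                 rmse = rmse(per_subject$measured, per_subject$predicted),
                 n_folds = nrow(per_subject), spec = spec),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("LOSO evaluation of Model %s-%s: %d folds, RMSE %.4g\n",
              x$spec$family, x$spec$target, x$n_folds, x$rmse))
  invisible(x)
}

#' Train a final model on all subjects
#'
#' Fits the forest on every row of every subject with a target. The stored
#' RMSE -- used for prediction range half-widths -- comes from
#' [loso_evaluate()]; pass a pre-computed evaluation to avoid refitting the
#' folds, otherwise it is computed here.
#'
#' @param records list of [subject_record()]s.
#' @param spec a [model_spec()].
#' @param evaluation optional `model_evaluation` for the same spec; pass
#'   `NA` to skip cross-validation entirely (the model then has no RMSE and
#'   its predictions carry no range half-width).
#' @return object of class `trained_model` with the fitted forest, `rmse`,
#'   `spec`, and the training-target range.
#' @export
train_final <- function(records, spec, evaluation = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  has_target <- vapply(records, function(r) !is.na(.target_of(r, spec$target)),
                       logical(1))
  if (any(!has_target)) stopf("untrained-target rows rejected: %d subject(s) lack a %s target",
                              sum(!has_target), spec$target)
  if (length(records) < 2) stopf("cannot train on fewer than 2 subjects")
  skip_eval <- !is.null(evaluation) && length(evaluation) == 1 &&
    is.na(evaluation)
  if (is.null(evaluation)) evaluation <- loso_evaluate(records, spec)
  if (!skip_eval) stopifnot(inherits(evaluation, "model_evaluation"))

  train <- .stack_training(records, spec)
  mtry <- spec$features_per_split %||% max(1L, floor(ncol(train$X) / 3))
  forest <- rf_fit_cpp(train$X, train$y, spec$n_trees, mtry, spec$min_leaf,
                       derive_seed(spec$seed, "final"))
  structure(list(forest = forest, spec = spec,
                 rmse = if (skip_eval) NA_real_ else evaluation$rmse,
                 evaluation = if (skip_eval) NULL else evaluation,
                 target_range = range(train$y),
                 feature_names = colnames(train$X)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("Model %s-%s: %d trees, RMSE %.4g, target range [%.3g, %.3g]\n",
              x$spec$family, x$spec$target, x$spec$n_trees, x$rmse,
              x$target_range[1], x$target_range[2]))
  invisible(x)
}

#' Predict one subject's foveal function from its 21 structural samples
#'
#' The prediction is the unweighted mean of the forest's 21 row-level
#' predictions, with range half-width `1.96 * RMSE` from the model's
#' leave-one-subject-out evaluation.
#'
#' @param model a [train_final()] result.
#' @param samples data frame of exactly 21 samples (3 scans x 7
#'   eccentricities).
#' @return a `prediction` object.
#' @export
predict_subject <- function(model, samples) {
  stopifnot(inherits(model, "trained_model"))
  if (nrow(samples) != 21)
    stopf("expected 21 samples (3 scans x 7 eccentricities), got %d",
          nrow(samples))
  X <- .design_of(samples, model$spec)
  new_prediction(mean(rf_predict_cpp(model$forest, X)), 1.96 * model$rmse,
                 model$spec$target)
}
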