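# End-to-end pipeline: simulate -> (render/segment or fast-path) features ->
# fit and evaluate all models -> predict BCM -> treatment potential reports.

#' Pipeline configuration
#'
#' A run is reproducible from its persisted configuration plus seed: every
#' random stage derives its own sub-seed from `seed`.
#'
#' @param seed master seed.
#' @param n_ird,n_normal training cohort composition (defaults 26 + 3).
#' @param n_deletion,n_c203r BCM cohort sizes (defaults 8 + 8).
#' @param noise_fs_sd,noise_va_sd,onl_cos_corr training-cohort generator
#'   parameters (see [generate_training_cohort()]).
#' @param n_scans scans per subject.
#' @param mode `"render"` (default) renders, aligns, segments and
#'   re-extracts every B-scan (the full image path); `"fast"` builds samples
#'   directly from generator ground truth (see [samples_from_cohort()]),
#'   useful for replicate simulation studies.
#' @param thickness_noise_sd fast-path per-scan measurement noise (um).
#' @param render renderer settings for `mode = "render"`: a list with
#'   `lateral_extent` (deg), `n_ascans`, `target_per_15deg`, `axial_step`
#'   (um), `noise_sd`.
#' @param n_trees,min_leaf,features_per_split forest hyperparameters (see
#'   [model_spec()]).
#' @param nd_floor dB floor substituted for non-detectable FS.
#' @param outdir directory for CSV reports, or `NULL` for none.
#' @param cohort_cfg a [cohort_config()].
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1, n_ird = 26, n_normal = 3, n_deletion = 8,
                       n_c203r = 8, noise_fs_sd = 1.5, noise_va_sd = 0.08,
                       onl_cos_corr = 0.814, n_scans = 3,
                       mode = c("render", "fast"), thickness_noise_sd = 2,
                       render = list(lateral_extent = 3, n_ascans = 1024,
                                     target_per_15deg = 512, axial_step = 2,
                                     noise_sd = 0.02),
                       n_trees = 500, min_leaf = 2, features_per_split = NULL,
                       nd_floor = 0, outdir = NULL,
                       cohort_cfg = cohort_config()) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "run_config")
}

# Subject records via the full image path: render each scan, downsample,
# align, locate the foveola, segment, and extract the 7-eccentricity samples.
records_from_rendering <- function(cohort, cfg) {
  rs <- cfg$render
  lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    retina <- ground_truth_retina(row)
    samples <- do.call(rbind, lapply(seq_len(cfg$n_scans), function(s) {
      sseed <- derive_seed(cfg$seed, paste0(row$subject_id, "_", s))
      restore <- .Random.seed_guard(sseed)
      pit <- runif(1, -0.1, 0.1) # acquisition centring jitter
      restore()
      scan <- render_bscan(retina, lateral_extent = rs$lateral_extent,
                           n_ascans = rs$n_ascans,
                           axial_step = rs$axial_step,
                           noise_sd = rs$noise_sd, seed = sseed,
                           pit_center = pit)
      scan <- downsample_lrps(scan, rs$target_per_15deg)
      scan <- align_to_brm(scan)
      fov <- locate_foveola(scan)
      seg <- segment_layers(scan)
      extract_samples(scan, seg, fov,
                      scan_id = sprintf("%s_scan%d", row$subject_id, s))
    }))
    subject_record(row$subject_id, row$group, row$fs_db, row$va_decimal,
                   samples, n_scans = cfg$n_scans)
  })
}

# per-subject foveal ONL: one value per scan (0-eccentricity sample)
foveal_onl_per_scan <- function(record) {
  s <- record$samples[record$samples$eccentricity == 0, ]
  v <- s$onl
  if (anyNA(v)) {
    if (all(is.na(v))) return(NULL)
    v[is.na(v)] <- mean(v, na.rm = TRUE)
  }
  v
}

#' Leave-one-subject-out evaluation of the curve-fit predictor
#'
#' For each subject, the log curve is refit to the remaining subjects'
#' (mean foveal ONL, target) pairs and the held-out subject is predicted as
#' the mean of the curve at its three per-scan foveal ONLs.
#'
#' @param records list of [subject_record()]s.
#' @param target `"FS"` or `"VA"`.
#' @return object of class `model_evaluation` (method tag `"CF"`).
#' @export
cf_loso_evaluate <- function(records, target = c("FS", "VA")) {
  target <- match.arg(target)
  get_t <- function(r) if (target == "FS") r$fs_measured else r$va_measured
  keep <- vapply(records, function(r)
    !is.na(get_t(r)) && !is.null(foveal_onl_per_scan(r)), logical(1))
  records <- records[keep]
  if (length(records) < 4) stopf("need at least 4 usable subjects")
  onl_mean <- vapply(records, function(r) mean(foveal_onl_per_scan(r)),
                     numeric(1))
  y <- vapply(records, get_t, numeric(1))
  res <- lapply(seq_along(records), function(i) {
    fit <- fit_log_model(onl_mean[-i], y[-i], target)
    p <- suppressWarnings(predict_cf(fit, foveal_onl_per_scan(records[[i]])))
    data.frame(subject_id = records[[i]]$subject_id, measured = y[i],
               predicted = p$value)
  })
  per_subject <- do.call(rbind, res)
  structure(list(per_subject = per_subject,
                 rmse = rmse(per_subject$measured, per_subject$predicted),
                 n_folds = nrow(per_subject),
                 spec = list(family = "CF", target = target)),
            class = "model_evaluation")
}

#' Run the full analysis pipeline
#'
#' Simulates the training and BCM cohorts, builds subject records (fast
#' path or full render/segment path), evaluates the four forest models and
#' the two curve fits by leave-one-subject-out validation, trains final
#' models, predicts every BCM subject with all three methods, computes
#' treatment potentials, and compares methods per genotype group. When
#' `config$outdir` is set, all tables plus the configuration are persisted
#' as CSV/JSON.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `cohorts`, `records`, `evaluations`, `models`,
#'   `cf_fits`, `predictions`, `potentials` (data frame), `group_comparison`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[simulate] training cohort (%d IRD + %d normal)", cfg$n_ird,
      cfg$n_normal)
  training <- generate_training_cohort(cfg$n_ird, cfg$n_normal,
                                       cfg$noise_fs_sd, cfg$noise_va_sd,
                                       cfg$onl_cos_corr,
                                       seed = derive_seed(cfg$seed, "train"),
                                       config = cfg$cohort_cfg)
  bcm_del <- generate_bcm_cohort("deletion", cfg$n_deletion,
                                 seed = derive_seed(cfg$seed, "del"),
                                 config = cfg$cohort_cfg)
  bcm_c203r <- generate_bcm_cohort("C203R", cfg$n_c203r,
                                   seed = derive_seed(cfg$seed, "c203r"),
                                   config = cfg$cohort_cfg)

  say("[features] building subject records (%s path)", cfg$mode)
  build <- function(cohort, tag) {
    if (cfg$mode == "fast")
      samples_from_cohort(cohort, n_scans = cfg$n_scans,
                          thickness_noise_sd = cfg$thickness_noise_sd,
                          seed = derive_seed(cfg$seed, tag))
    else records_from_rendering(cohort, cfg)
  }
  rec_train <- build(training, "ftrain")
  rec_del <- build(bcm_del, "fdel")
  rec_c203r <- build(bcm_c203r, "fc203r")

  say("[evaluate] leave-one-subject-out (%d folds)", length(rec_train))
  specs <- list()
  for (fam in c("I", "II")) for (tg in c("FS", "VA"))
    specs[[paste0(fam, "-", tg)]] <-
      model_spec(fam, tg, n_trees = cfg$n_trees, min_leaf = cfg$min_leaf,
                 features_per_split = cfg$features_per_split,
                 seed = derive_seed(cfg$seed, paste0("rf", fam, tg)))
  evaluations <- lapply(specs, function(sp) loso_evaluate(rec_train, sp))
  evaluations[["CF-FS"]] <- cf_loso_evaluate(rec_train, "FS")
  evaluations[["CF-VA"]] <- cf_loso_evaluate(rec_train, "VA")

  say("[fit] final models")
  models <- lapply(names(specs), function(nm)
    train_final(rec_train, specs[[nm]], evaluations[[nm]]))
  names(models) <- names(specs)
  onl_mean <- vapply(rec_train, function(r) mean(foveal_onl_per_scan(r)),
                     numeric(1))
  cf_fits <- list(
    FS = fit_log_model(onl_mean, vapply(rec_train, `[[`, numeric(1),
                                        "fs_measured"), "FS"),
    VA = fit_log_model(onl_mean, vapply(rec_train, `[[`, numeric(1),
                                        "va_measured"), "VA"))
  # prediction half-widths use cross-validated RMSE for CF too
  cf_fits$FS$rmse <- evaluations[["CF-FS"]]$rmse
  cf_fits$VA$rmse <- evaluations[["CF-VA"]]$rmse

  say("[predict] BCM cohorts and treatment potential")
  bcm_records <- c(rec_del, rec_c203r)
  potentials <- list()
  predictions <- list()
  for (rec in bcm_records) {
    onl3 <- foveal_onl_per_scan(rec)
    for (tg in c("FS", "VA")) {
      preds <- list(
        I = predict_subject(models[[paste0("I-", tg)]], rec$samples),
        II = predict_subject(models[[paste0("II-", tg)]], rec$samples),
        CF = suppressWarnings(predict_cf(cf_fits[[tg]], onl3)))
      for (meth in names(preds)) {
        predictions[[paste(rec$subject_id, tg, meth, sep = "_")]] <-
          preds[[meth]]
        measured <- if (tg == "FS") rec$fs_measured else rec$va_measured
        tp <- suppressWarnings(
          treatment_potential(measured, preds[[meth]], tg,
                              subject_id = rec$subject_id, method = meth,
                              nd_floor = cfg$nd_floor))
        potentials[[length(potentials) + 1]] <- data.frame(
          subject_id = rec$subject_id, group = rec$group, target = tg,
          method = meth,
          measured = if (is.na(measured)) NA_real_ else measured,
          predicted = preds[[meth]]$value,
          half_width = preds[[meth]]$half_width, delta = tp$delta,
          lines_gained = tp$lines_gained %||% NA_integer_,
          snellen_predicted = tp$snellen_predicted %||% NA_character_)
      }
    }
  }
  potentials <- do.call(rbind, potentials)

  group_comparison <- compare_groups(potentials, n_perm = 2000,
                                     seed = derive_seed(cfg$seed, "kw"))

  out <- list(cohorts = list(training = training, deletion = bcm_del,
                             C203R = bcm_c203r),
              records = list(training = rec_train, deletion = rec_del,
                             C203R = rec_c203r),
              evaluations = evaluations, models = models, cf_fits = cf_fits,
              predictions = predictions, potentials = potentials,
              group_comparison = group_comparison, config = cfg)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(training, file.path(cfg$outdir, "cohort_training.csv"))
    write_cohort(bcm_del, file.path(cfg$outdir, "cohort_deletion.csv"))
    write_cohort(bcm_c203r, file.path(cfg$outdir, "cohort_C203R.csv"))
    ev <- do.call(rbind, lapply(names(evaluations), function(nm) {
      e <- evaluations[[nm]]
      data.frame(model = nm, per_subject_rmse = e$rmse, n_folds = e$n_folds)
    }))
    write.csv(ev, file.path(cfg$outdir, "evaluations.csv"),
              row.names = FALSE)
    for (nm in names(evaluations))
      write.csv(evaluations[[nm]]$per_subject,
                file.path(cfg$outdir, sprintf("loso_%s.csv", nm)),
                row.names = FALSE)
    write.csv(potentials, file.path(cfg$outdir, "potentials.csv"),
              row.names = FALSE)
    write.csv(group_comparison$summary,
              file.path(cfg$outdir, "group_summary.csv"), row.names = FALSE)
    write.csv(group_comparison$tests,
              file.path(cfg$outdir, "group_tests.csv"), row.names = FALSE)
    cfg_json <- unclass(cfg)
    cfg_json$cohort_cfg <- NULL
    jsonlite::write_json(cfg_json, file.path(cfg$outdir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  say("[done]")
  out
}
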