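# End-to-end pipeline: load or simulate a cohort, preprocess, screen
# artifacts, extract normalized spectral features, run group statistics,
# select features, and cross-validate the classifier.

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one validated list. The
#' defaults are the replication preset (`preset = "replication-2022"`): 14-channel
#' 10-20 montage, 250 Hz, 3-35 Hz zero-phase band-pass, 1-s epochs, 90 s
#' clean-duration gate, 3-30 Hz normalization, 5-11 Hz candidate bins,
#' 4 selected features, stratified 5-fold CV of L2 logistic regression at
#' C = 1 with a small C grid.
#'
#' @param montage Channel labels, in feature-column order.
#' @param target_fs Common sampling rate (Hz).
#' @param hp,lp Band-pass corners (Hz).
#' @param epoch_length_s Epoch length (s).
#' @param detector `"threshold"` (deterministic amplitude rule) or an
#'   `artifact_model` from [train_artifact_classifier()].
#' @param threshold_uv Amplitude threshold for the rule detector (uV).
#' @param peak_limit_uv,flat_limit_uv Bad-channel screening bounds (uV).
#' @param min_clean_s Clean-duration gate (s).
#' @param norm_range Normalization range (Hz, inclusive).
#' @param bands Band definition tibble.
#' @param candidate_bins Integer candidate feature bins (Hz).
#' @param k_features Features selected for classification.
#' @param cv_k CV folds.
#' @param cv_seed Fold shuffle seed.
#' @param C Inverse regularization strength used when `grid` is `NULL`.
#' @param grid Hyperparameter grid tibble or `NULL` to skip the search.
#' @param selection_mode `"full-cohort"` or `"nested"`.
#' @param var_equal Pooled-variance Student t instead of Welch.
#' @param preset Only `"replication-2022"`; any explicit argument overrides the
#'   preset field-by-field.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(montage = montage_1020_14(),
                            target_fs = 250, hp = 3, lp = 35,
                            epoch_length_s = 1,
                            detector = "threshold", threshold_uv = 100,
                            peak_limit_uv = 500, flat_limit_uv = 0.1,
                            min_clean_s = 90,
                            norm_range = c(3, 30),
                            bands = eeg_bands(),
                            candidate_bins = 5:11,
                            k_features = 4,
                            cv_k = 5, cv_seed = 0, C = 1,
                            grid = default_grid(),
                            selection_mode = c("full-cohort", "nested"),
                            var_equal = FALSE,
                            preset = "replication-2022") {
  selection_mode <- match.arg(selection_mode)
  if (!identical(preset, "replication-2022"))
    stop_config("preset", "unknown preset")
  if (length(montage) == 0) stop_config("montage", "must be non-empty")
  if (!(hp > 0 && hp < lp && lp < target_fs / 2))
    stop_config("hp/lp", "must satisfy 0 < hp < lp < target_fs/2")
  if (epoch_length_s <= 0) stop_config("epoch_length_s", "must be > 0")
  if (min_clean_s < 0) stop_config("min_clean_s", "must be >= 0")
  if (norm_range[1] >= norm_range[2])
    stop_config("norm_range", "must be increasing")
  if (k_features < 1) stop_config("k_features", "must be >= 1")
  if (cv_k < 2) stop_config("cv_k", "must be >= 2")
  if (C <= 0) stop_config("C", "must be > 0")
  structure(
    list(montage = montage, target_fs = target_fs, hp = hp, lp = lp,
         epoch_length_s = epoch_length_s, detector = detector,
         threshold_uv = threshold_uv, peak_limit_uv = peak_limit_uv,
         flat_limit_uv = flat_limit_uv, min_clean_s = min_clean_s,
         norm_range = norm_range, bands = bands,
         candidate_bins = candidate_bins, k_features = k_features,
         cv_k = cv_k, cv_seed = cv_seed, C = C, grid = grid,
         selection_mode = selection_mode, var_equal = var_equal,
         preset = preset),
    class = "pipeline_config"
  )
}

# Preprocess + artifact-screen + spectral stages for one recording.
# Returns NULL (with a log entry) when the subject fails a quality gate.
process_subject <- function(rec, config) {
  log_lines <- character()
  res <- tryCatch({
    pp <- preprocess_recording(
      rec, montage = config$montage, target_fs = config$target_fs,
      hp = config$hp, lp = config$lp,
      peak_limit_uv = config$peak_limit_uv,
      flat_limit_uv = config$flat_limit_uv)
    ep <- epoch(pp, config$epoch_length_s)
    feats <- extract_epoch_features(ep)
    mask <- if (inherits(config$detector, "artifact_model")) {
      classify_epochs(feats, model = config$detector,
                      epoch_length_s = config$epoch_length_s)
    } else {
      classify_epochs(feats, threshold_uv = config$threshold_uv,
                      epoch_length_s = config$epoch_length_s)
    }
    mask <- apply_clean_duration_gate(mask, config$min_clean_s)
    if (!attr(mask, "subject_valid")) {
      log_lines <- c(log_lines, sprintf(
        "%s: excluded, no channel with >= %g s clean",
        rec$subject_id, config$min_clean_s))
      NULL
    } else {
      psd <- average_psd(ep, mask) %>% normalize_psd(config$norm_range)
      excl <- pp$excluded_channels
      invalid <- mask$channels$channel[!mask$channels$is_valid]
      if (length(invalid) > 0)
        excl <- bind_rows(excl, tibble(channel = invalid,
                                       reason = "clean-duration"))
      list(psd = psd, mask = mask, excluded = excl,
           clean_s = mask$channels)
    }
  }, error = function(e) {
    log_lines <<- c(log_lines, sprintf("%s: excluded (%s)",
                                       rec$subject_id, conditionMessage(e)))
    NULL
  })
  list(result = res, log = log_lines)
}

#' Run the full pipeline on a cohort
#'
#' Executes, in fixed order: montage selection, resampling, zero-phase
#' band-pass, bad-channel screening, 1-s epoching, per-epoch artifact
#' classification, the clean-duration gate, periodogram averaging over
#' clean epochs, 3-30 Hz normalization, band powers and montage averaging,
#' the 5-11 Hz feature table (with column-mean imputation), per-feature and
#' band-level t-tests, top-k feature selection, and stratified k-fold CV.
#' Subjects failing a quality gate are excluded and counted.
#'
#' @param input An `eeg_cohort` from [generate_cohort()] / [read_cohort()],
#'   or a directory path readable by [read_cohort()], or a [cohort_spec()]
#'   (simulated on the fly with the default profiles).
#' @param config A [pipeline_config()].
#' @param artifacts [artifact_spec()] used only when `input` is a
#'   `cohort_spec`.
#' @return An `eeg_run_report`: list with `config`, `subjects` (per-subject
#'   log tibble), `excluded_subjects`, `psd` (normalized per-channel
#'   spectra), `montage_psd`, `band_powers`, `band_stats`, `feature_table`,
#'   `feature_stats`, `selected`, `cv` (an `eeg_cv`), and `log`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         artifacts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (inherits(input, "eeg_cohort")) input
  else if (inherits(input, "cohort_spec"))
    generate_cohort(spec = input, artifacts = artifacts)
  else if (is.character(input) && length(input) == 1) read_cohort(input)
  else abort("`input` must be an eeg_cohort, cohort_spec, or directory")

  log_lines <- character()
  per_subject <- vector("list", length(cohort$recordings))
  names(per_subject) <- names(cohort$recordings)
  for (id in names(cohort$recordings)) {
    pr <- process_subject(cohort$recordings[[id]], config)
    per_subject[id] <- list(pr$result)   # keep NULLs as exclusion markers
    log_lines <- c(log_lines, pr$log)
  }
  kept <- !vapply(per_subject, is.null, logical(1))
  excluded_subjects <- names(per_subject)[!kept]
  if (sum(kept) < 2)
    abort("fewer than 2 subjects survived the quality gates")
  per_subject <- per_subject[kept]

  subjects <- purrr::imap_dfr(per_subject, function(s, id) {
    tibble(subject_id = id,
           group = cohort$recordings[[id]]$group,
           n_valid_channels = sum(s$clean_s$is_valid),
           n_excluded_channels = nrow(s$excluded),
           mean_clean_s = mean(s$clean_s$clean_duration_s))
  })

  psd <- bind_rows(lapply(per_subject, `[[`, "psd"))
  montage_psd <- montage_average(psd)
  band_powers <- band_power(montage_psd, bands = config$bands,
                            available = c(config$hp, config$lp))
  band_stats <- band_comparison(band_powers, var_equal = config$var_equal)
  feature_table <- build_feature_table(psd, montage = config$montage,
                                       bins = config$candidate_bins) %>%
    impute_missing()
  feature_stats <- groupwise_ttest(feature_table,
                                   var_equal = config$var_equal)
  selected <- select_top_features(feature_stats, k = config$k_features,
                                  montage = config$montage)
  cv <- cross_validate(
    feature_table,
    features = if (config$selection_mode == "full-cohort")
      selected$feature else NULL,
    selection_mode = config$selection_mode,
    k_features = config$k_features, k = config$cv_k,
    seed = config$cv_seed, C = config$C, grid = config$grid,
    var_equal = config$var_equal, montage = config$montage)

  structure(
    list(config = config, subjects = subjects,
         excluded_subjects = excluded_subjects,
         psd = psd, montage_psd = montage_psd,
         band_powers = band_powers, band_stats = band_stats,
         feature_table = feature_table, feature_stats = feature_stats,
         selected = selected, cv = cv, log = log_lines),
    class = "eeg_run_report"
  )
}

#' @export
print.eeg_run_report <- function(x, ...) {
  cat(sprintf(
    "<eeg_run_report> %d subjects analysed (%d excluded)\n",
    nrow(x$subjects), length(x$excluded_subjects)))
  cat(sprintf("  feature table: %d x %d features\n",
              nrow(x$feature_table),
              length(feature_columns(x$feature_table))))
  cat(sprintf("  selected: %s\n", paste(x$selected$feature, collapse = ", ")))
  print(x$cv)
  invisible(x)
}

#' Write a run report's tables to a directory
#'
#' Feature table, per-feature statistics, selected features (JSON), CV
#' report (JSON), band statistics, per-subject log, and the configuration
#' echo (JSON) — everything needed to re-run and audit the analysis.
#'
#' @param report An `eeg_run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$feature_table,
                   file.path(dir, "feature_table.csv"), row.names = FALSE)
  utils::write.csv(report$feature_stats,
                   file.path(dir, "feature_stats.csv"), row.names = FALSE)
  utils::write.csv(report$band_stats,
                   file.path(dir, "band_stats.csv"), row.names = FALSE)
  utils::write.csv(report$subjects,
                   file.path(dir, "subjects.csv"), row.names = FALSE)
  jsonlite::write_json(report$selected, file.path(dir, "selected.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    c(glance(report$cv), list(folds = tidy(report$cv))),
    file.path(dir, "cv_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- report$config
  cfg$grid <- NULL
  cfg$bands <- NULL
  cfg$detector <- if (inherits(cfg$detector, "artifact_model"))
    "svm" else cfg$detector
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(report$log, sprintf("excluded subjects: %s",
                                   paste(report$excluded_subjects,
                                         collapse = ", "))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
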