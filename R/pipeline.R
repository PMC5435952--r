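#' Pipeline configuration
#'
#' One object holding every stage's parameters: the synthetic-cohort settings
#' (or an input directory of session CSVs), the filter band, epoching,
#' fuzzy-entropy parameters, cross-validation settings and the global seed.
#' Serializes losslessly to JSON (see [write_pipeline_config()]), so a run
#' can be reproduced from its manifest.
#'
#' @param synth A [synth_config()] used when `input_dir` is `NULL`.
#' @param input_dir Optional directory of session CSVs named
#'   `<subject>_<state>.csv` (wide format, see [read_eeg_csv()]); overrides
#'   the synthetic source.
#' @param input_fs Sampling rate of CSV inputs (default 1000).
#' @param filter A [filter_spec()].
#' @param epoch_seconds,overlap Epoching, as in [segment_epochs()].
#' @param artifact_threshold_uv Rejection threshold, as in
#'   [reject_artifacts()].
#' @param fuzzyen A [fuzzyen_params()].
#' @param n_folds,cost,gamma,per_subject Cross-validation settings, as in
#'   [crossval_svm()].
#' @param seed Global seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            input_fs = 1000, filter = filter_spec(),
                            epoch_seconds = 1, overlap = 0,
                            artifact_threshold_uv = 100,
                            fuzzyen = fuzzyen_params(), n_folds = 10,
                            cost = 1, gamma = NULL, per_subject = TRUE,
                            seed = 1) {
  stopifnot(inherits(synth, "synth_config"),
            inherits(filter, "filter_spec"),
            inherits(fuzzyen, "fuzzyen_params"))
  synth$seed <- as.integer(seed)
  structure(
    list(synth = synth, input_dir = input_dir, input_fs = input_fs,
         filter = filter, epoch_seconds = epoch_seconds, overlap = overlap,
         artifact_threshold_uv = artifact_threshold_uv, fuzzyen = fuzzyen,
         n_folds = n_folds, cost = cost, gamma = gamma,
         per_subject = per_subject, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Serialize / restore a pipeline configuration
#'
#' `write_pipeline_config()` writes the configuration as JSON;
#' `read_pipeline_config()` restores it, rejecting unknown keys so a stale
#' or mistyped manifest fails loudly rather than silently running with
#' defaults.
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON file path.
#' @return The path (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- lapply(unclass(cfg), function(v) if (is.object(v)) unclass(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    abort(paste0("unknown configuration key(s): ", paste(extra, collapse = ", ")))
  }
  check_sub <- function(part, ctor) {
    extra <- setdiff(names(part), names(formals(ctor)))
    if (length(extra)) {
      abort(paste0("unknown configuration key(s): ",
                   paste(extra, collapse = ", ")))
    }
    do.call(ctor, part)
  }
  pipeline_config(
    synth = check_sub(x$synth, synth_config),
    input_dir = x$input_dir,
    input_fs = x$input_fs %||% 1000,
    filter = check_sub(x$filter, filter_spec),
    epoch_seconds = x$epoch_seconds, overlap = x$overlap,
    artifact_threshold_uv = x$artifact_threshold_uv,
    fuzzyen = check_sub(x$fuzzyen, fuzzyen_params),
    n_folds = x$n_folds, cost = x$cost, gamma = x$gamma,
    per_subject = x$per_subject, seed = x$seed
  )
}

load_input_dir <- function(dir, fs) {
  files <- sort(list.files(dir, pattern = "\\.(csv|edf)$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no .csv or .edf files in %s", dir))
  purrr::map_dfr(files, function(f) {
    base <- sub("\\.(csv|edf)$", "", basename(f))
    parts <- strsplit(base, "_")[[1]]
    st <- parts[length(parts)]
    if (!st %in% c("normal", "fatigue")) {
      abort(sprintf("cannot infer state from file name '%s' (expected <subject>_<state>.<ext>)",
                    basename(f)))
    }
    sid <- paste(parts[-length(parts)], collapse = "_")
    if (grepl("\\.edf$", f)) read_edf(f, subject_id = sid, state = st)
    else read_eeg_csv(f, fs = fs, subject_id = sid, state = st)
  })
}

#' Run the full fatigue-detection pipeline
#'
#' Executes simulate (or load) -> band-pass -> notch -> epoch -> artifact
#' rejection -> fuzzy-entropy features -> cross-validated RBF-SVM, writing
#' all artifacts to `out_dir`:
#' \describe{
#'   \item{features.csv}{the feature table}
#'   \item{cv_report.json}{machine-readable accuracy report}
#'   \item{report.txt}{per-subject accuracy table}
#'   \item{fatigue_scores.csv}{continuous per-epoch fatigue levels from the
#'     Platt-calibrated model}
#'   \item{manifest.json}{config echo, seed, config hash, stage counts}
#' }
#' Runs are deterministic: the same configuration (including seed) produces
#' byte-identical features and reports.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `features`, `report` (the `cv_report`),
#'   `scores`, and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rec <- if (is.null(cfg$input_dir)) {
    inform("stage simulate: generating synthetic cohort")
    simulate_cohort(cfg$synth)
  } else {
    inform(sprintf("stage load: reading sessions from %s", cfg$input_dir))
    load_input_dir(cfg$input_dir, cfg$input_fs)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  filtered <- stage("filter", rec |> band_filter(cfg$filter) |>
                      notch_filter(cfg$filter))
  epochs <- stage("epoch", segment_epochs(filtered, cfg$epoch_seconds,
                                          cfg$overlap))
  kept <- stage("artifact", reject_artifacts(epochs,
                                             cfg$artifact_threshold_uv))
  n_rejected <- attr(kept, "n_rejected")
  inform(sprintf("stage epoch: %d epochs made, %d rejected",
                 nrow(epochs), n_rejected))
  features <- stage("features", extract_features(kept, cfg$fuzzyen))
  report <- stage("classify", crossval_svm(
    features, n_folds = cfg$n_folds, seed = cfg$seed, cost = cfg$cost,
    gamma = cfg$gamma, per_subject = cfg$per_subject))

  scorer <- stage("score", fit_fatigue_model(features, cost = cfg$cost,
                                             gamma = cfg$gamma))
  scores <- features |>
    dplyr::select("subject_id", "epoch_index", "label") |>
    dplyr::mutate(fatigue_score = fatigue_score(scorer, features))

  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(cfg, cfg_path)
  manifest <- list(
    package = "fuzzyeeg",
    version = as.character(utils::packageVersion("fuzzyeeg")),
    seed = cfg$seed,
    config_file = "config.json",
    config_hash = rlang::hash(readChar(cfg_path, file.size(cfg_path))),
    n_epochs_made = nrow(epochs),
    n_epochs_rejected = n_rejected,
    n_rows_classified = nrow(features)
  )

  write_features(features, file.path(out_dir, "features.csv"))
  writeLines(cv_report_json(report), file.path(out_dir, "cv_report.json"))
  writeLines(format(report), file.path(out_dir, "report.txt"))
  readr::write_csv(scores, file.path(out_dir, "fatigue_scores.csv"),
                   progress = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(features = features, report = report, scores = scores,
                 manifest = manifest, out_dir = out_dir))
}
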