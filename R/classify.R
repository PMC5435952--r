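## Stratified fold assignment: within each class, a seeded permutation is
## dealt round-robin into k folds, so fold class proportions match the data
## as closely as integer counts allow.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sig <- apply(X, 2, stats::sd)
  sig[sig == 0] <- 1
  list(center = mu, scale = sig)
}

standardize_apply <- function(X, sc) {
  scale(X, center = sc$center, scale = sc$scale)
}

svm_gamma <- function(X, gamma = NULL) {
  # inverse of (feature count x mean feature variance), computed on the
  # training matrix it will be applied to
  if (!is.null(gamma)) return(gamma)
  v <- mean(apply(X, 2, stats::var))
  if (v <= 0) v <- 1
  1 / (ncol(X) * v)
}

#' Train on one feature table, predict on another
#'
#' Fits an RBF-kernel support vector machine to the training table's
#' fuzzy-entropy features and evaluates accuracy on the test table. Feature
#' standardization (center, scale) is fit on the training data only and
#' applied to the test data, so no information leaks from test to train.
#'
#' @param train,test Feature tables (see [extract_features()]); `train` must
#'   contain both classes, `test` at least one row.
#' @param cost SVM soft-margin cost parameter C (default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses the inverse of
#'   (number of features x mean training-fold feature variance).
#' @return A list with `predictions` (integer labels for the test rows),
#'   `accuracy`, and the fitted `model`.
#' @export
fit_predict <- function(train, test, cost = 1, gamma = NULL) {
  fc <- feature_cols(train)
  if (length(fc) == 0) abort("no fuzzyen_* feature columns found")
  if (nrow(test) == 0) abort("empty test set")
  if (dplyr::n_distinct(train$label) < 2) {
    abort("training set contains a single class; cannot fit a classifier")
  }
  Xtr <- as.matrix(train[fc]); Xte <- as.matrix(test[fc])
  if (any(!is.finite(Xtr)) || any(!is.finite(Xte))) {
    abort("features must be finite")
  }
  sc <- standardize_fit(Xtr)
  Ztr <- standardize_apply(Xtr, sc)
  Zte <- standardize_apply(Xte, sc)
  fit <- e1071::svm(Ztr, factor(train$label, levels = c(0, 1)),
                    kernel = "radial", cost = cost,
                    gamma = svm_gamma(Ztr, gamma), scale = FALSE)
  pred <- as.integer(as.character(predict(fit, Zte)))
  list(predictions = pred,
       accuracy = mean(pred == test$label),
       model = fit, scaler = sc)
}

#' Stratified k-fold cross-validated SVM accuracy
#'
#' Evaluates the RBF-SVM fatigue classifier by stratified k-fold
#' cross-validation and assembles a per-subject accuracy report. By default
#' (`per_subject = TRUE`) folds are built and models trained within each
#' subject, mirroring a per-subject accuracy table; `per_subject = FALSE`
#' pools all subjects into subject-blind folds and attributes pooled
#' predictions back to subjects.
#'
#' Fold assignment is seeded and fully reproducible; feature standardization
#' is refit on every training fold.
#'
#' @param features A feature table from [extract_features()].
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param cost,gamma SVM hyperparameters, as in [fit_predict()].
#' @param per_subject Train and evaluate within each subject (default) or
#'   pooled across subjects.
#' @return A `cv_report` object: fold-level accuracies, per-subject mean
#'   accuracies, the cohort mean of per-subject means, and the cohort SD
#'   (dispersion across subjects, labelled as such). Use [tidy()] /
#'   [glance()] for tibble views and `print()` for the accuracy table.
#' @examples
#' \donttest{
#' feats <- simulate_cohort(synth_config(n_subjects = 2,
#'                                       session_seconds = 20)) |>
#'   segment_epochs() |>
#'   extract_features()
#' crossval_svm(feats, seed = 1)
#' }
#' @export
crossval_svm <- function(features, n_folds = 10, seed = 1, cost = 1,
                         gamma = NULL, per_subject = TRUE) {
  if (n_folds < 2) abort("`n_folds` must be at least 2")
  fc <- feature_cols(features)
  if (length(fc) == 0) abort("no fuzzyen_* feature columns found")

  run_folds <- function(tbl, rows_label) {
    counts <- table(factor(tbl$label, levels = c(0, 1)))
    if (any(counts == 0)) {
      return(NULL)  # caller logs the skip
    }
    if (min(counts) < n_folds) {
      abort(sprintf(
        "%s has %d samples in its smallest class but %d folds; use a smaller n_folds",
        rows_label, min(counts), n_folds))
    }
    fold_id <- stratified_folds(tbl$label, n_folds)
    purrr::map_dfr(seq_len(n_folds), function(f) {
      test_idx <- which(fold_id == f)
      res <- fit_predict(tbl[-test_idx, , drop = FALSE],
                         tbl[test_idx, , drop = FALSE],
                         cost = cost, gamma = gamma)
      tibble::tibble(fold = f, n_test = length(test_idx),
                     accuracy = res$accuracy,
                     test_rows = list(test_idx),
                     predictions = list(res$predictions))
    })
  }

  set.seed(seed)
  skipped <- character()
  if (per_subject) {
    folds <- features |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_split() |>
      purrr::map(function(tbl) {
        sid <- tbl$subject_id[1]
        out <- run_folds(tbl, paste("subject", sid))
        if (is.null(out)) {
          skipped <<- c(skipped, sid)
          inform(sprintf("subject %s skipped: a class is absent", sid))
          return(NULL)
        }
        dplyr::mutate(out, subject_id = sid, .before = 1)
      }) |>
      purrr::compact() |>
      dplyr::bind_rows()
    subjects <- folds |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                       n_epochs = sum(.data$n_test), .groups = "drop")
  } else {
    folds <- run_folds(features, "pooled data")
    if (is.null(folds)) abort("pooled data contains a single class")
    # attribute pooled predictions back to subjects
    per_row <- folds |>
      tidyr::unnest(c("test_rows", "predictions")) |>
      dplyr::mutate(subject_id = features$subject_id[.data$test_rows],
                    correct = .data$predictions ==
                      features$label[.data$test_rows])
    subjects <- per_row |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(mean_accuracy = mean(.data$correct),
                       n_epochs = dplyr::n(), .groups = "drop")
    folds <- dplyr::mutate(folds, subject_id = "pooled", .before = 1)
  }
  folds <- dplyr::select(folds, -"test_rows", -"predictions")

  if (nrow(subjects) == 0) abort("no subject had both classes present")
  structure(
    list(
      folds = folds,
      subjects = subjects,
      cohort_mean = mean(subjects$mean_accuracy),
      cohort_sd = if (nrow(subjects) > 1) stats::sd(subjects$mean_accuracy) else 0,
      dispersion = "sd",
      skipped = skipped,
      config = list(n_folds = n_folds, seed = seed, cost = cost,
                    gamma = gamma, per_subject = per_subject)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Render a cross-validation report as an accuracy table
#'
#' One row per subject plus a closing `MEAN +/- SD` row — the conventional
#' per-subject accuracy table layout.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A character vector of table lines.
#' @export
format.cv_report <- function(x, ...) {
  lines <- c(sprintf("%-16s %s", "No. of subject", "Accuracy"),
             sprintf("%-16s %.2f", x$subjects$subject_id,
                     x$subjects$mean_accuracy),
             sprintf("%-16s %.2f +/- %.3f", "MEAN +/- SD",
                     x$cohort_mean, x$cohort_sd))
  lines
}

#' @export
tidy.cv_report <- function(x, ...) {
  x$subjects
}

#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_folds = x$config$n_folds,
    cohort_mean_accuracy = x$cohort_mean,
    cohort_sd_accuracy = x$cohort_sd,
    n_skipped = length(x$skipped)
  )
}

#' JSON twin of the accuracy report
#'
#' @param x A `cv_report`.
#' @return A JSON string with per-subject accuracies, the cohort summary and
#'   the configuration echo.
#' @export
cv_report_json <- function(x) {
  stopifnot(inherits(x, "cv_report"))
  jsonlite::toJSON(
    list(subjects = x$subjects,
         cohort_mean = x$cohort_mean,
         cohort_sd = x$cohort_sd,
         dispersion = x$dispersion,
         skipped = x$skipped,
         config = x$config[!vapply(x$config, is.null, TRUE)]),
    auto_unbox = TRUE, digits = NA)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-subject cross-validated accuracy
#'
#' Fold-level accuracies (points) and subject means (bars) with the cohort
#' mean as a dashed reference line.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$subject_id,
                               y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_jitter(
      data = object$folds[object$folds$subject_id %in%
                            object$subjects$subject_id, ],
      ggplot2::aes(y = .data$accuracy), width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::geom_hline(yintercept = object$cohort_mean, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "subject", y = "10-fold CV accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Fit a fatigue scoring model
#'
#' Trains an RBF-SVM with Platt-scaled probability outputs on a feature
#' table, for converting new epochs' features into a continuous fatigue
#' level in \[0, 1\].
#'
#' @inheritParams fit_predict
#' @param features Training feature table containing both classes.
#' @return A `fatigue_model` object.
#' @export
fit_fatigue_model <- function(features, cost = 1, gamma = NULL) {
  fc <- feature_cols(features)
  if (dplyr::n_distinct(features$label) < 2) {
    abort("training set contains a single class; cannot fit a classifier")
  }
  X <- as.matrix(features[fc])
  sc <- standardize_fit(X)
  Z <- standardize_apply(X, sc)
  fit <- e1071::svm(Z, factor(features$label, levels = c(0, 1)),
                    kernel = "radial", cost = cost,
                    gamma = svm_gamma(Z, gamma), scale = FALSE,
                    probability = TRUE)
  structure(list(model = fit, scaler = sc, features = fc),
            class = "fatigue_model")
}

#' Continuous fatigue score
#'
#' Maps epochs' fuzzy-entropy features through the trained classifier's
#' Platt-calibrated probability of the fatigue class: a monotone transform
#' of the SVM margin into \[0, 1\], with 0.5 at the decision boundary.
#'
#' @param model A `fatigue_model` from [fit_fatigue_model()].
#' @param features A feature table (labels not required).
#' @return A numeric vector of scores in \[0, 1\], one per row.
#' @export
fatigue_score <- function(model, features) {
  if (!inherits(model, "fatigue_model")) {
    abort("`model` must be a fatigue_model (see fit_fatigue_model())")
  }
  X <- as.matrix(features[model$features])
  if (any(!is.finite(X))) abort("features must be finite")
  Z <- standardize_apply(X, model$scaler)
  pr <- predict(model$model, Z, probability = TRUE)
  unname(attr(pr, "probabilities")[, "1"])
}
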