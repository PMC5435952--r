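test_that("perfectly separated clusters give accuracy 1 in every fold", {
  feats <- separable_features(n_per_class = 100)
  rep <- crossval_svm(feats, n_folds = 10, seed = 1)
  expect_true(all(rep$folds$accuracy == 1))
  expect_equal(rep$cohort_mean, 1)
  expect_equal(rep$cohort_sd, 0)
  expect_equal(sum(rep$folds$n_test), 200)
})

test_that("fit_predict honors its contracts", {
  feats <- separable_features(n_per_class = 30)
  res <- fit_predict(feats, feats)
  expect_equal(res$accuracy, 1)
  expect_equal(res$predictions, feats$label)

  single <- feats[feats$label == 0, ]
  expect_error(fit_predict(single, feats), "single class")
  expect_error(fit_predict(feats, feats[0, ]), "empty test")
})

test_that("standardization is fit on the training data only (no leakage)", {
  feats <- separable_features(n_per_class = 30)
  test <- separable_features(n_per_class = 10, seed = 2)
  res1 <- fit_predict(feats, test)
  shifted <- dplyr::mutate(test, fuzzyen_FP1 = fuzzyen_FP1 + 100)
  res2 <- fit_predict(feats, shifted)
  expect_identical(res1$scaler, res2$scaler)
})

test_that("label-permuted features classify at chance", {
  set.seed(42)
  base <- separable_features(n_per_class = 100, gap = 10)
  accs <- vapply(1:30, function(i) {
    null <- dplyr::mutate(base, label = sample(label))
    crossval_svm(null, n_folds = 10, seed = i)$cohort_mean
  }, 0)
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("fold assignment and the whole report are reproducible under a seed", {
  feats <- small_cohort_features()
  r1 <- crossval_svm(feats, seed = 7)
  r2 <- crossval_svm(feats, seed = 7)
  expect_identical(r1, r2)
  r3 <- crossval_svm(feats, seed = 8)
  expect_false(identical(r1$folds$accuracy, r3$folds$accuracy) &&
                 identical(r1, r3))
})

test_that("subjects with a missing class are skipped; too few samples is an error", {
  feats <- dplyr::bind_rows(
    separable_features(n_per_class = 20, subject_id = "S01"),
    dplyr::filter(separable_features(n_per_class = 20, subject_id = "S02"),
                  label == 0)
  )
  expect_message(rep <- crossval_svm(feats, n_folds = 10, seed = 1),
                 "skipped")
  expect_equal(rep$subjects$subject_id, "S01")
  expect_equal(rep$skipped, "S02")

  tiny <- separable_features(n_per_class = 5)
  expect_error(crossval_svm(tiny, n_folds = 10), "smaller n_folds")
  expect_error(crossval_svm(separable_features(10), n_folds = 1), "at least 2")
})

test_that("pooled mode attributes subject-blind fold predictions back to subjects", {
  feats <- dplyr::bind_rows(
    separable_features(n_per_class = 30, subject_id = "S01", seed = 1),
    separable_features(n_per_class = 30, subject_id = "S02", seed = 2)
  )
  rep <- crossval_svm(feats, n_folds = 10, seed = 3, per_subject = FALSE)
  expect_setequal(rep$subjects$subject_id, c("S01", "S02"))
  expect_equal(sum(rep$subjects$n_epochs), nrow(feats))
  expect_equal(rep$cohort_mean, 1)
})

test_that("the report renders one row per subject plus a MEAN +/- SD row", {
  feats <- dplyr::bind_rows(lapply(1:3, function(i) {
    separable_features(n_per_class = 15, subject_id = sprintf("S%02d", i),
                       seed = i)
  }))
  rep <- crossval_svm(feats, n_folds = 10, seed = 1)
  lines <- format(rep)
  expect_length(lines, 1 + 3 + 1)
  expect_match(lines[length(lines)], "MEAN \\+/- SD")

  one <- crossval_svm(separable_features(20), n_folds = 10, seed = 1)
  expect_length(format(one), 3)
  expect_equal(one$cohort_sd, 0)

  js <- jsonlite::fromJSON(cv_report_json(rep))
  expect_equal(js$cohort_mean, rep$cohort_mean)
  expect_equal(nrow(js$subjects), 3)
})

test_that("tidy, glance and autoplot views are consistent with the report", {
  feats <- small_cohort_features()
  rep <- crossval_svm(feats, seed = 2)
  td <- tidy(rep)
  expect_equal(td$mean_accuracy, rep$subjects$mean_accuracy)
  gl <- glance(rep)
  expect_equal(gl$cohort_mean_accuracy, mean(td$mean_accuracy))
  expect_equal(gl$n_subjects, 2L)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})

test_that("fatigue scores are calibrated probabilities in [0, 1]", {
  feats <- separable_features(n_per_class = 100, gap = 10)
  model <- fit_fatigue_model(feats)
  sc <- fatigue_score(model, feats)
  expect_true(all(sc >= 0 & sc <= 1))
  # deep inside each class
  expect_gt(mean(sc[feats$label == 1]), 0.9)
  expect_lt(mean(sc[feats$label == 0]), 0.1)
  # at the midpoint of two symmetric clusters the score sits near 0.5
  mid <- tibble::tibble(subject_id = "S01", epoch_index = 1L,
                        fuzzyen_FP1 = 5, fuzzyen_FP2 = 5, label = NA)
  expect_lt(abs(fatigue_score(model, mid) - 0.5), 0.15)
  expect_error(fatigue_score(list(), feats), "fatigue_model")
  expect_error(fit_fatigue_model(feats[feats$label == 1, ]), "single class")
})

test_that("cohort accuracy rises with the synthetic state separation", {
  accs <- sapply(c(1.02, 2, 4), function(ratio) {
    runs <- vapply(1:2, function(s) {
      cfg <- synth_config(n_subjects = 2, session_seconds = 16,
                          snr_normal = 4, snr_fatigue = 4 / ratio,
                          seed = 100 + s)
      feats <- suppressMessages(
        simulate_cohort(cfg) |>
          segment_epochs() |>
          extract_features())
      crossval_svm(feats, seed = s)$cohort_mean
    }, 0)
    median(runs)
  })
  expect_true(all(diff(accs) >= 0))
  expect_lt(accs[1], 0.85)
  expect_gt(accs[3], 0.9)
})
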