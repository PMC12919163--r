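# Printed metric rows used across these tests: triplets of (precision,
# sensitivity, specificity) with the accuracy / F1 / kappa values they imply.
reference_rows <- data.frame(
  precision = c(50.00, 45.45, 33.33, 50.00, 25.00, 50.00, 62.50, 31.03,
                57.14, 46.15, 14.29, 35.00),
  sensitivity = c(14.29, 71.43, 12.50, 22.22, 14.29, 28.57, 33.33, 60.00,
                  25.00, 46.15, 7.14, 58.33),
  specificity = c(95.83, 81.82, 91.30, 92.31, 87.50, 90.70, 93.48, 57.45,
                  93.62, 85.71, 87.76, 77.59))

test_that("confusion tallies agree with a brute-force count", {
  cm <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 2L, fn = 0L, fp = 0L, tn = 2L))

  cm0 <- confusion(c(1, 1, 0), c(0, 0, 0))
  expect_equal(cm0$tp + cm0$fp, 0L)

  set.seed(21)
  truth <- rbinom(1000, 1, 0.3); pred <- rbinom(1000, 1, 0.5)
  cm <- confusion(truth, pred)
  # brute-force loop oracle
  tp <- fn <- fp <- tn <- 0
  for (i in 1:1000) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
  }
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = tp, fn = fn, fp = fp, tn = tn),
               ignore_attr = TRUE)

  expect_error(confusion(c(1, 0), c(1, 0, 1)), "equal length")
  expect_equal(confusion(c("stimulus", "non_stimulus"),
                         c("stimulus", "stimulus"))$fp, 1L)
})

test_that("metric arithmetic reproduces printed reference rows", {
  r1 <- compute_metrics(confusion_matrix(tp = 1, fn = 6, fp = 1, tn = 23))
  expect_equal(flashvep:::round_half_up(r1$accuracy, 2), 77.42)
  expect_equal(flashvep:::round_half_up(r1$cohen_kappa, 2), 13.55)
  expect_equal(flashvep:::round_half_up(r1$f1, 2), 22.22)

  r2 <- compute_metrics(confusion_matrix(tp = 5, fn = 2, fp = 6, tn = 27))
  expect_equal(flashvep:::round_half_up(r2$accuracy, 2), 80.00)
  expect_equal(flashvep:::round_half_up(r2$precision, 2), 45.45)
  expect_equal(flashvep:::round_half_up(r2$sensitivity, 2), 71.43)
  expect_equal(flashvep:::round_half_up(r2$f1, 2), 55.56)
  expect_equal(flashvep:::round_half_up(r2$specificity, 2), 81.82)
  expect_equal(flashvep:::round_half_up(r2$cohen_kappa, 2), 43.46)

  perfect <- compute_metrics(confusion_matrix(tp = 3, fn = 0, fp = 0,
                                              tn = 9))
  for (k in c("accuracy", "precision", "sensitivity", "specificity", "f1",
              "cohen_kappa"))
    expect_equal(perfect[[k]], 100)
})

test_that("undefined metrics surface as NA, never 0", {
  all_neg <- compute_metrics(confusion_matrix(tp = 0, fn = 5, fp = 0,
                                              tn = 20))
  expect_true(is.na(all_neg$precision))
  expect_true(is.na(all_neg$f1))
  expect_false(is.na(all_neg$specificity))

  # constant predictions on a single-class truth: p_e = 1
  degenerate <- compute_metrics(confusion_matrix(tp = 7, fn = 0, fp = 0,
                                                 tn = 0))
  expect_true(is.na(degenerate$cohen_kappa))
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(33)
  for (i in 1:25) {
    cm <- confusion_matrix(tp = rpois(1, 5) + 1, fn = rpois(1, 5),
                           fp = rpois(1, 5), tn = rpois(1, 20) + 1)
    r <- compute_metrics(cm)
    if (!is.na(r$f1))
      expect_equal(r$f1,
                   2 * r$precision * r$sensitivity /
                     (r$precision + r$sensitivity),
                   tolerance = 1e-12)
    expect_equal(r$accuracy,
                 100 * (cm$tp + cm$tn) / (cm$tp + cm$fn + cm$fp + cm$tn),
                 tolerance = 1e-12)
  }
})

test_that("kappa is 100 exactly for error-free two-class predictions", {
  set.seed(8)
  for (i in 1:10) {
    cm <- confusion_matrix(tp = rpois(1, 4) + 1, fn = 0, fp = 0,
                           tn = rpois(1, 10) + 1)
    expect_equal(compute_metrics(cm)$cohen_kappa, 100)
  }
  # independence construct: prediction ignores truth, both marginals mixed
  cm0 <- confusion_matrix(tp = 2, fn = 2, fp = 8, tn = 8)
  expect_equal(compute_metrics(cm0)$cohen_kappa, 0, tolerance = 1e-12)
})

test_that("minimal confusion matrices are recovered from metric triplets", {
  cm <- infer_confusion_from_metrics(100, 100, 100)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 0L, fp = 0L, tn = 1L))

  cm1 <- infer_confusion_from_metrics(50.00, 14.29, 95.83)
  expect_equal(unlist(cm1[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 6L, fp = 1L, tn = 23L))
  expect_equal(flashvep:::round_half_up(
    compute_metrics(cm1)$accuracy, 2), 77.42)

  cm11 <- infer_confusion_from_metrics(14.29, 7.14, 87.76)
  expect_equal(unlist(cm11[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 13L, fp = 6L, tn = 43L))
  expect_equal(flashvep:::round_half_up(
    compute_metrics(cm11)$cohen_kappa, 2), -6.21)

  expect_error(infer_confusion_from_metrics(33.33, 100, 100, max_total = 5),
               "no integer confusion matrix")
})

test_that("metric triplets round-trip through reconstruction", {
  for (i in seq_len(nrow(reference_rows))) {
    row <- reference_rows[i, ]
    cm <- infer_confusion_from_metrics(row$precision, row$sensitivity,
                                       row$specificity)
    r <- compute_metrics(cm)
    expect_equal(flashvep:::round_half_up(r$precision, 2), row$precision)
    expect_equal(flashvep:::round_half_up(r$sensitivity, 2),
                 row$sensitivity)
    expect_equal(flashvep:::round_half_up(r$specificity, 2),
                 row$specificity)
  }
})

test_that("reports serialize to JSON and CSV", {
  r <- compute_metrics(confusion_matrix(tp = 5, fn = 2, fp = 6, tn = 27))
  js <- tempfile(fileext = ".json")
  write_metrics_json(r, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$accuracy, r$accuracy, tolerance = 1e-12)
  expect_equal(back$confusion$tp, 5)

  cs <- tempfile(fileext = ".csv")
  write_metrics_csv(r, cs)
  df <- utils::read.csv(cs)
  expect_equal(names(df), c("accuracy", "precision", "sensitivity", "f1",
                            "specificity", "cohen_kappa"))
  expect_equal(df$cohen_kappa, 43.46)
})

test_that("balanced accuracy averages sensitivity and specificity", {
  cm <- confusion_matrix(tp = 5, fn = 5, fp = 10, tn = 30)
  expect_equal(balanced_accuracy(cm), (0.5 + 0.75) / 2)
})
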