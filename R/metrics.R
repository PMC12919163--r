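#' Binary confusion matrix for stimulus detection
#'
#' The stimulus segment is the positive class throughout.
#'
#' @param tp,fn,fp,tn Nonnegative integer counts.
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("confusion matrix must contain at least one observation",
         call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("stimulus", "non_stimulus"),
                              predicted = c("stimulus", "non_stimulus")))
  print(m)
  invisible(x)
}

#' Tally a confusion matrix from label vectors
#'
#' @param truth,predicted Equal-length binary vectors; either 0/1 (1 =
#'   stimulus), logicals, or the labels `"stimulus"` / `"non_stimulus"`.
#' @return A [confusion_matrix()].
#' @export
confusion <- function(truth, predicted) {
  to01 <- function(x, name) {
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      bad <- !x %in% c("stimulus", "non_stimulus")
      if (any(bad)) stop("`", name, "` has labels other than stimulus/",
                         "non_stimulus", call. = FALSE)
      as.integer(x == "stimulus")
    } else {
      x <- as.integer(as.logical(x) | x == 1)
      x
    }
  }
  t01 <- to01(truth, "truth"); p01 <- to01(predicted, "predicted")
  if (length(t01) != length(p01))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (!length(t01)) stop("empty label vectors", call. = FALSE)
  confusion_matrix(tp = sum(t01 == 1 & p01 == 1),
                   fn = sum(t01 == 1 & p01 == 0),
                   fp = sum(t01 == 0 & p01 == 1),
                   tn = sum(t01 == 0 & p01 == 0))
}

#' Evaluation metrics under class imbalance
#'
#' Computes the six summary metrics on the percent scale: accuracy, precision,
#' sensitivity (TPR), specificity (TNR), F1 and Cohen's kappa (also x100, so
#' perfect agreement is 100 and chance is 0). Kappa is
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` taken from the
#' row/column marginals; it is the preferred summary here because non-stimulus
#' segments heavily outnumber stimulus segments. A metric whose denominator is
#' zero (e.g. precision of a predictor that never says stimulus, or kappa when
#' `p_e = 1`) is reported as `NA` ("not available"), never as 0. Values are
#' kept unrounded internally; printing rounds half-up to 2 decimals.
#'
#' @param cm A [confusion_matrix()].
#' @return A list of class `metrics_report` with elements `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `f1`, `cohen_kappa` (percent)
#'   and `confusion`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- (tp + tn) / total
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  kappa <- if (abs(1 - pe) > 1e-15) (acc - pe) / (1 - pe) else NA_real_
  structure(list(accuracy = 100 * acc, precision = 100 * prec,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 f1 = 100 * f1, cohen_kappa = 100 * kappa,
                 confusion = cm),
            class = "metrics_report")
}

metric_columns <- c("accuracy", "precision", "sensitivity", "f1",
                    "specificity", "cohen_kappa")

#' @export
print.metrics_report <- function(x, ...) {
  vals <- vapply(metric_columns, function(k) {
    if (is.na(x[[k]])) NA_real_ else round_half_up(x[[k]], 2)
  }, numeric(1))
  df <- as.data.frame(as.list(vals))
  names(df) <- c("Accuracy", "Precision", "Sensitivity", "F1",
                 "Specificity", "CohenKappa")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a metrics report
#'
#' `write_metrics_json` stores unrounded values plus the confusion counts;
#' `write_metrics_csv` writes a single row in the conventional reporting
#' column order (accuracy, precision, sensitivity, F1, specificity, kappa),
#' rounded half-up to 2 decimals.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- report[metric_columns]
  out$confusion <- report$confusion[c("tp", "fn", "fp", "tn")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  df <- as.data.frame(lapply(report[metric_columns],
                             function(v) round_half_up(v, 2)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Balanced accuracy of a confusion matrix
#'
#' Mean of sensitivity and specificity, on the 0-1 scale; the summary of
#' choice when one class dominates.
#'
#' @param cm A [confusion_matrix()].
#' @return A fraction in `[0, 1]` (or `NA` if a class is absent).
#' @export
balanced_accuracy <- function(cm) {
  rep_ <- compute_metrics(cm)
  (rep_$sensitivity + rep_$specificity) / 200
}

#' Reconstruct the minimal confusion matrix from printed metrics
#'
#' Given precision, sensitivity and specificity in percent (as printed, i.e.
#' rounded half-up to 2 decimals), exhaustively searches integer confusion
#' matrices with total count at most `max_total` and returns the
#' smallest-total matrix whose three ratios reproduce the inputs after
#' rounding. Ties at the same total are broken lexicographically by
#' `(tp, fp, fn, tn)`. This is the validation tool used to recover the
#' integer counts behind published metric tables.
#'
#' @param precision_pct,sensitivity_pct,specificity_pct Percent values in
#'   `[0, 100]`.
#' @param max_total Largest total count to consider (`>= 4`).
#' @return A [confusion_matrix()].
#' @export
infer_confusion_from_metrics <- function(precision_pct, sensitivity_pct,
                                         specificity_pct, max_total = 200) {
  for (v in c(precision_pct, sensitivity_pct, specificity_pct))
    if (v < 0 || v > 100) stop("metric inputs must be in [0, 100]",
                               call. = FALSE)
  if (max_total < 4) stop("max_total must be >= 4", call. = FALSE)
  rounds_to <- function(num, den, target)
    den > 0 & abs(round_half_up(100 * num / den, 2) - target) < 1e-9

  grid <- expand.grid(a = 0:max_total, b = 0:max_total)
  grid <- grid[grid$a + grid$b <= max_total, ]
  sens_pairs <- grid[rounds_to(grid$a, grid$a + grid$b, sensitivity_pct), ]
  names(sens_pairs) <- c("tp", "fn")
  prec_pairs <- grid[rounds_to(grid$a, grid$a + grid$b, precision_pct), ]
  names(prec_pairs) <- c("tp", "fp")
  spec_pairs <- grid[rounds_to(grid$a, grid$a + grid$b, specificity_pct), ]
  names(spec_pairs) <- c("tn", "fp")

  cand <- merge(sens_pairs, prec_pairs, by = "tp")
  cand <- merge(cand, spec_pairs, by = "fp")
  cand$total <- cand$tp + cand$fn + cand$fp + cand$tn
  cand <- cand[cand$total <= max_total & cand$total >= 1, ]
  if (!nrow(cand))
    stop("no integer confusion matrix with total <= ", max_total,
         " reproduces these metrics", call. = FALSE)
  cand <- cand[order(cand$total, cand$tp, cand$fp, cand$fn, cand$tn), ]
  confusion_matrix(tp = cand$tp[1], fn = cand$fn[1], fp = cand$fp[1],
                   tn = cand$tn[1])
}
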