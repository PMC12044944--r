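#' Confusion counts for a binary classification
#'
#' Tallies true/false positives and negatives. Labels may be given as 0/1,
#' logicals, or factors/characters together with the `positive` level.
#'
#' @param truth Observed labels.
#' @param estimate Predicted labels, same length and coding as `truth`.
#' @param positive Label treated as the positive class when `truth` is not
#'   already 0/1 or logical. Default `"active"`, falling back to `1`.
#' @return A one-row tibble of class `confusion_counts` with columns
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(truth, estimate, positive = "active") {
  assert_that(length(truth) == length(estimate),
              "`truth` and `estimate` must have the same length",
              class = "stackscreen_input_error")
  assert_that(length(truth) > 0, "empty evaluation: no observations",
              class = "stackscreen_input_error")
  t01 <- as_binary(truth, positive)
  e01 <- as_binary(estimate, positive)
  out <- tibble(
    tp = sum(t01 == 1 & e01 == 1),
    tn = sum(t01 == 0 & e01 == 0),
    fp = sum(t01 == 0 & e01 == 1),
    fn = sum(t01 == 1 & e01 == 0)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

as_binary <- function(x, positive) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    assert_that(all(x %in% c(0, 1)), "numeric labels must be 0/1",
                class = "stackscreen_input_error")
    return(as.integer(x))
  }
  x <- as.character(x)
  lev <- unique(x)
  assert_that(length(lev) <= 2, "labels must be binary",
              class = "stackscreen_input_error")
  pos <- if (positive %in% lev || length(lev) < 2) positive else lev[2]
  as.integer(x == pos)
}

#' Threshold-based classification metrics from confusion counts
#'
#' Computes sensitivity (SN), specificity (SP), accuracy (ACC), balanced
#' accuracy (BACC = (SN + SP) / 2) and the Matthews correlation coefficient
#' (MCC). When a metric's denominator vanishes (e.g. SP with no observed
#' negatives) the value is `NA` and flagged in the `degenerate` column;
#' a vanishing MCC denominator yields the conventional value 0, also flagged.
#'
#' @param counts A `confusion_counts` row (or anything with tp/tn/fp/fn
#'   columns or fields).
#' @return A one-row tibble of class `metrics_report` with columns
#'   `acc`, `bacc`, `sn`, `sp`, `mcc`, the four counts, `n`, and `degenerate`
#'   (comma-separated names of degenerate metrics, `""` if none).
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  n <- tp + tn + fp + fn
  assert_that(n > 0, "empty evaluation: no observations",
              class = "stackscreen_input_error")
  degenerate <- character(0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- c(degenerate, "sn"); NA_real_ }
  sp <- if (tn + fp > 0) tn / (tn + fp) else { degenerate <- c(degenerate, "sp"); NA_real_ }
  acc <- (tp + tn) / n
  bacc <- (sn + sp) / 2
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) {
    (tp * tn - fp * fn) / mcc_den
  } else {
    degenerate <- c(degenerate, "mcc")
    0
  }
  out <- tibble(
    acc = acc, bacc = bacc, sn = sn, sp = sp, mcc = mcc,
    tp = tp, tn = tn, fp = fp, fn = fn, n = n,
    degenerate = paste(degenerate, collapse = ",")
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Rank-based ROC AUC
#'
#' Area under the receiver-operating curve computed from the Mann-Whitney
#' statistic with midrank handling of tied scores: the probability that a
#' randomly chosen positive outscores a randomly chosen negative, counting
#' ties as 1/2.
#'
#' @param truth Observed labels (0/1, logical, or factor with `positive`).
#' @param scores Numeric scores; higher means more positive.
#' @param positive Positive label for non-numeric `truth`.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
#' @export
auc_score <- function(truth, scores, positive = "active") {
  assert_that(length(truth) == length(scores),
              "`truth` and `scores` must have the same length",
              class = "stackscreen_input_error")
  y <- as_binary(truth, positive)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  assert_that(n_pos > 0 && n_neg > 0,
              "AUC undefined: both classes must be present",
              class = "stackscreen_undefined_metric")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full evaluation report from labels and scores
#'
#' Convenience wrapper combining [confusion()], [compute_metrics()] and
#' [auc_score()] at a probability threshold.
#'
#' @inheritParams auc_score
#' @param threshold Probability cutoff applied to `scores`.
#' @return A `metrics_report` tibble with an `auc` column.
#' @export
classification_report <- function(truth, scores, threshold = 0.5,
                                  positive = "active") {
  y <- as_binary(truth, positive)
  pred <- as.integer(scores >= threshold)
  rep <- compute_metrics(confusion(y, pred))
  rep$auc <- tryCatch(auc_score(y, scores),
                      stackscreen_undefined_metric = function(e) NA_real_)
  rep
}

#' Stratified k-fold assignment
#'
#' @param y Labels.
#' @param folds Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(y, folds = 10, seed = 1) {
  y <- as.character(y)
  assert_that(folds >= 2, "need at least 2 folds",
              class = "stackscreen_fold_error")
  assert_that(folds <= length(y), "more folds than observations",
              class = "stackscreen_fold_error")
  id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      id[idx] <- rep_len(sample(folds), length(idx))
    }
  })
  id
}

#' Cross-validated evaluation of an arbitrary fit/predict pipeline
#'
#' Runs stratified k-fold cross-validation, scoring each observation with the
#' fold model that excluded it, and reports metrics on the pooled out-of-fold
#' predictions (per-fold confusion counts are retained alongside).
#'
#' @param x Feature matrix or data frame.
#' @param y Binary labels aligned with rows of `x`.
#' @param fit `function(x, y)` returning a fitted model.
#' @param predict_prob `function(model, x)` returning positive-class
#'   probabilities.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param threshold Probability cutoff for label metrics.
#' @return A list of class `cv_result`: `pooled` (a `metrics_report` with
#'   AUC), `per_fold` (tibble of per-fold counts), `oof` (tibble of row id,
#'   fold, truth, score).
#' @export
cross_validate <- function(x, y, fit, predict_prob, folds = 10, seed = 1,
                           threshold = 0.5) {
  x <- as.matrix(x)
  y01 <- as_binary(y, "active")
  assert_that(min(table(y01)) >= 1 && length(unique(y01)) == 2,
              "both classes must be present", class = "stackscreen_fold_error")
  fold_id <- stratified_folds(y01, folds = folds, seed = seed)
  oof <- rep(NA_real_, length(y01))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    model <- fit(x[tr, , drop = FALSE], y01[tr])
    oof[!tr] <- predict_prob(model, x[!tr, , drop = FALSE])
  }
  per_fold <- purrr::map_dfr(sort(unique(fold_id)), function(k) {
    sel <- fold_id == k
    cc <- confusion(y01[sel], as.integer(oof[sel] >= threshold))
    dplyr::bind_cols(tibble(fold = k), cc)
  })
  pooled <- classification_report(y01, oof, threshold = threshold)
  structure(
    list(pooled = pooled, per_fold = per_fold,
         oof = tibble(row = seq_along(y01), fold = fold_id,
                      truth = y01, score = oof)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated evaluation (", max(x$oof$fold), " folds, pooled)\n", sep = "")
  print(x$pooled, ...)
  invisible(x)
}
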