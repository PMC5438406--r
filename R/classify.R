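#' Repeated random-subsampling cross-validation design
#'
#' In every repeat a fraction of the cohort (default 5 percent, at least
#' one subject, size `ceiling(n * test_fraction)`) is drawn uniformly
#' without replacement as test set and the rest trains the classifier.
#' Pooling the test predictions of many repeats (default 500) yields an
#' overall performance estimate that is robust to any single random split.
#'
#' @param n_repeats Number of random splits (default 500).
#' @param test_fraction Test proportion per repeat, in (0, 0.5)
#'   (default 0.05).
#' @param seed Integer master seed; all splits derive from it.
#' @param stratified Draw test sets preserving class proportions
#'   (default `FALSE`: plain uniform draws).
#' @return An object of class `cv_design`.
#' @export
cv_design <- function(n_repeats = 500L, test_fraction = 0.05, seed = 1L,
                      stratified = FALSE) {
  stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 0.5)
  structure(list(n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "cv_design")
}

#' Draw the train/test splits of a cross-validation design
#'
#' Draws `n_repeats` test sets of size `ceiling(n * test_fraction)`
#' reproducibly from the design seed.  When labels are supplied, any repeat
#' whose training rows would contain a single class is redrawn once; if
#' still degenerate it is flagged for skipping.
#'
#' @param n Cohort size (>= 4).
#' @param design A [cv_design()].
#' @param labels Optional 0/1 labels enabling the degenerate-split guard
#'   (and stratification if the design asks for it).
#' @return A list with `test` (list of test index vectors), `skip`
#'   (logical per repeat) and `test_size`.
#' @export
draw_splits <- function(n, design, labels = NULL) {
  stopifnot(inherits(design, "cv_design"), n >= 4)
  m <- ceiling(n * design$test_fraction)
  if (m >= n) stop("test size ", m, " not smaller than cohort size ", n)
  set.seed(seed_stream(design$seed, "splits"))
  draw_one <- function() {
    if (design$stratified && !is.null(labels)) {
      pos <- which(labels == 1L)
      neg <- which(labels == 0L)
      m_pos <- min(length(pos), max(0L, round(m * length(pos) / n)))
      m_neg <- m - m_pos
      if (m_neg > length(neg)) {
        m_neg <- length(neg)
        m_pos <- m - m_neg
      }
      sort(c(if (m_pos > 0) sample(pos, m_pos),
             if (m_neg > 0) sample(neg, m_neg)))
    } else {
      sort(sample.int(n, m))
    }
  }
  test <- replicate(design$n_repeats, draw_one(), simplify = FALSE)
  skip <- logical(design$n_repeats)
  if (!is.null(labels)) {
    single_class <- function(te) {
      tr <- labels[-te]
      all(tr == tr[1])
    }
    for (r in seq_along(test)) {
      if (single_class(test[[r]])) {
        test[[r]] <- draw_one()          # one redraw from the same stream
        if (single_class(test[[r]])) skip[r] <- TRUE
      }
    }
  }
  list(test = test, skip = skip, test_size = m)
}

#' Fit a calibrated linear SVM on one split and predict the test rows
#'
#' Fits min-max scaling on the training rows, trains a linear-kernel SVM
#' (L1 hinge loss, regularisation `C`), calibrates a Platt sigmoid on
#' decision values from 3-fold internal cross-validation of the training
#' split, and returns the calibrated probability of the positive
#' (low-outcome) class for each test row.
#'
#' @param train_x,test_x Numeric matrices of descriptor columns (raw,
#'   unscaled; scaling is fitted internally on `train_x` only).
#' @param train_y 0/1 labels of the training rows (both classes required).
#' @param C SVM regularisation constant (default 1).
#' @param calibrate Apply Platt calibration (default `TRUE`; otherwise raw
#'   decision values are returned as `prob`).
#' @return List with `prob` (calibrated positive-class probabilities) and
#'   `decision` (raw decision values) for the test rows.
#' @export
fit_predict_one <- function(train_x, train_y, test_x, C = 1,
                            calibrate = TRUE) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as.integer(train_y)
  if (all(train_y == train_y[1]))
    stop("training split contains a single class")
  res <- cpp_fit_predict(train_x, train_y, test_x, C, calibrate,
                         1000L, 1e-3)
  list(prob = res$prob, decision = res$decision)
}

#' Pooled ROC curve and AUC
#'
#' Pools test predictions (typically from all cross-validation repeats)
#' into one set and computes the ROC step function over all distinct
#' thresholds and the AUC by trapezoidal integration, which with the
#' rank-average tie convention equals the Mann-Whitney statistic: the
#' probability that a random positive outranks a random negative.
#'
#' @param prob Predicted positive-class probabilities (or any monotone
#'   score).
#' @param label True 0/1 labels (both classes required).
#' @return An object of class `roc_result` with `thresholds`, `fpr`,
#'   `tpr` and `auc`.
#' @export
pooled_roc <- function(prob, label) {
  label <- as.integer(label)
  if (length(prob) != length(label)) stop("length mismatch")
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("pooled predictions contain a single class")
  ord <- order(prob, decreasing = TRUE)
  p <- prob[ord]
  y <- label[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)   # last index of each threshold
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, p[last]), fpr = fpr, tpr = tpr,
                 auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Pooled ROC: AUC %.3f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds) - 1L))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = "black", lwd = 2, ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "False positive rate", ylab = "True positive rate",
         col = col, lwd = lwd, ...)
    abline(0, 1, lty = 3, col = "grey")
  } else {
    lines(x$fpr, x$tpr, type = "s", col = col, lwd = lwd, ...)
  }
  invisible(x)
}

# internal: extract the descriptor matrix and outcome labels from a cohort
# table
cohort_xy <- function(table, descriptors = NULL, outcome = NULL) {
  if (is.null(outcome)) outcome <- attr(table, "outcome")
  if (is.null(outcome)) stop("specify `outcome` (cognitive or motor)")
  outcome <- match.arg(outcome, c("cognitive", "motor"))
  ycol <- paste0("outcome_", outcome)
  if (!ycol %in% names(table)) stop("table lacks column ", ycol)
  if (is.null(descriptors))
    descriptors <- intersect(descriptor_names(), names(table))
  x <- as.matrix(as.data.frame(table)[descriptors])
  y <- as.integer(table[[ycol]])
  keep <- !is.na(y) & stats::complete.cases(x)
  list(x = x[keep, , drop = FALSE], y = y[keep], outcome = outcome,
       subject_id = as.character(table$subject_id)[keep])
}

#' Evaluate one descriptor subset under repeated random subsampling
#'
#' Restricts the cohort table to the given descriptor subset, then for
#' every repeat of the design fits the calibrated linear SVM on the
#' training split and predicts the test split; all test predictions are
#' pooled into one ROC/AUC.  Per-repeat AUCs are additionally reported for
#' repeats whose test set contains both classes.
#'
#' @param table A `cohort_table` (from [build_arm()] or
#'   [simulate_cohort()]).
#' @param subset Character vector of descriptor names, or a logical/0-1
#'   mask over [descriptor_names()].
#' @param design A [cv_design()].
#' @param outcome `"cognitive"` or `"motor"`; defaults to the table's
#'   `outcome` attribute.
#' @param C SVM regularisation (default 1).
#' @param calibrate Platt calibration (default `TRUE`).
#' @param splits Optional precomputed [draw_splits()] result (used by
#'   [run_search()] to share splits across subsets).
#' @return An object of class `subset_result`: the subset, pooled
#'   [pooled_roc()] result, per-repeat AUCs, prediction records and design
#'   metadata.
#' @export
evaluate_subset <- function(table, subset, design, outcome = NULL, C = 1,
                            calibrate = TRUE, splits = NULL) {
  subset <- as_subset_names(subset)
  if (length(subset) == 0L) stop("empty descriptor subset")
  xy <- cohort_xy(table, intersect(descriptor_names(), names(table)),
                  outcome)
  missing_d <- setdiff(subset, colnames(xy$x))
  if (length(missing_d))
    stop("descriptor(s) not in table: ", paste(missing_d, collapse = ", "))
  n <- nrow(xy$x)
  if (is.null(splits)) splits <- draw_splits(n, design, xy$y)
  test_sets <- splits$test[!splits$skip]
  res <- cpp_eval_repeats(xy$x[, subset, drop = FALSE], xy$y, test_sets,
                          C, calibrate, 200L, 0.01)
  if (length(res$prob) == 0L) stop("all repeats were skipped")
  roc <- pooled_roc(res$prob, res$label)
  per_repeat <- vapply(split(seq_along(res$prob), res$repeat_index),
                       function(i) {
                         y <- res$label[i]
                         if (length(unique(y)) < 2L) return(NA_real_)
                         cpp_auc(res$prob[i], y)
                       }, numeric(1))
  records <- data.frame(subject_id = xy$subject_id[res$row],
                        repeat_index = res$repeat_index,
                        calibrated_probability = res$prob,
                        true_label = res$label,
                        stringsAsFactors = FALSE)
  structure(list(subset = subset, auc = roc$auc, roc = roc,
                 per_repeat_auc = per_repeat, records = records,
                 n = n, design = design, outcome = xy$outcome,
                 n_skipped = sum(splits$skip) + res$n_skipped),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat("Descriptor subset: ", paste(x$subset, collapse = ", "), "\n", sep = "")
  cat(sprintf("  outcome %s, n = %d, %d repeats (%d skipped)\n",
              x$outcome, x$n, x$design$n_repeats, x$n_skipped))
  cat(sprintf("  pooled AUC %.3f", x$auc))
  ok <- !is.na(x$per_repeat_auc)
  if (any(ok))
    cat(sprintf("; per-repeat AUC median %.3f (defined in %d repeats)",
                median(x$per_repeat_auc[ok]), sum(ok)))
  cat("\n")
  invisible(x)
}

#' @export
plot.subset_result <- function(x, ...) {
  plot(x$roc, main = sprintf("Pooled ROC, AUC %.3f", x$auc), ...)
  invisible(x)
}

# normalise a subset given as names, logical mask or 0/1 vector
as_subset_names <- function(subset, names = descriptor_names()) {
  if (is.character(subset)) return(subset)
  if (is.logical(subset) || all(subset %in% c(0, 1))) {
    if (length(subset) != length(names))
      stop("mask length must be ", length(names))
    return(names[as.logical(subset)])
  }
  stop("subset must be descriptor names or a mask")
}
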