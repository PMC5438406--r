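#' Enumerate all non-empty descriptor subsets
#'
#' All `2^n - 1` non-empty inclusion masks over `n` descriptors in
#' deterministic binary-counter order: row `m` has flag `j` set when bit
#' `j - 1` of `m` is set.  For the canonical 14 descriptors this yields
#' 16383 subsets.
#'
#' @param n_descriptors Number of descriptors (1 to 20).
#' @param names Optional column names (default [descriptor_names()] when
#'   `n_descriptors` is 14).
#' @return A logical matrix with `2^n - 1` rows.
#' @export
enumerate_subsets <- function(n_descriptors, names = NULL) {
  n <- as.integer(n_descriptors)
  if (n < 1L || n > 20L) stop("n_descriptors must be in 1..20")
  m <- seq_len(2L^n - 1L)
  masks <- vapply(seq_len(n), function(j) bitwAnd(m, bitwShiftL(1L, j - 1L)) > 0L,
                  logical(length(m)))
  masks <- matrix(masks, ncol = n)
  if (is.null(names) && n == 14L) names <- descriptor_names()
  if (!is.null(names)) colnames(masks) <- names
  masks
}

#' The seven predefined descriptor subsets
#'
#' The predefined comparison sets: all image descriptors, the volume
#' descriptors (eight relative tissue volumes plus brain volume), and the
#' cortical morphology measures (ISA, MC, GI, MT) -- each with and without
#' GA at birth -- plus GA alone.
#'
#' @return A named list of seven logical masks over [descriptor_names()].
#' @export
predefined_subsets <- function() {
  dn <- descriptor_names()
  mask <- function(keep) setNames(dn %in% keep, dn)
  volumes <- c("CB", "mWM", "BGT", "vCSF", "uWM", "BS", "cGM", "eCSF", "BV")
  morpho <- c("ISA", "MC", "GI", "MT")
  list(
    image = mask(c(volumes, morpho)),
    image_ga = mask(c("GA", volumes, morpho)),
    volumes = mask(volumes),
    volumes_ga = mask(c("GA", volumes)),
    morphology = mask(morpho),
    morphology_ga = mask(c("GA", morpho)),
    ga_only = mask("GA")
  )
}

#' Exhaustive descriptor-subset search
#'
#' Evaluates every non-empty subset of the table's descriptors with the
#' calibrated linear SVM under one shared list of random splits (the same
#' splits for every subset, so the ranking is free of split-sampling
#' noise), ranks subsets by pooled AUC (ties broken by mask binary value),
#' counts how often each descriptor appears among the top `k` subsets, and
#' additionally evaluates the seven predefined subsets on the same splits.
#'
#' @param table A `cohort_table`.
#' @param design A [cv_design()]; 500 repeats is the reference setting,
#'   smaller values give a reduced-cost search.
#' @param outcome `"cognitive"` or `"motor"` (default: table attribute).
#' @param k Number of top subsets reported (default 10).
#' @param C SVM regularisation (default 1).
#' @param calibrate Platt calibration (default `TRUE`).
#' @param descriptors Descriptor columns to search over (default: all
#'   canonical descriptors present in the table).
#' @return An object of class `search_report` with the ranked table, the
#'   presence counts, the predefined-subset results and design metadata.
#' @export
run_search <- function(table, design, outcome = NULL, k = 10L, C = 1,
                       calibrate = TRUE, descriptors = NULL) {
  if (is.null(descriptors))
    descriptors <- intersect(descriptor_names(), names(table))
  xy <- cohort_xy(table, descriptors, outcome)
  d <- length(descriptors)
  masks <- enumerate_subsets(d, names = descriptors)
  splits <- draw_splits(nrow(xy$x), design, xy$y)
  test_sets <- splits$test[!splits$skip]
  aucs <- cpp_search_aucs(xy$x, xy$y, test_sets,
                          matrix(as.integer(masks), ncol = d), C, calibrate,
                          200L, 0.01)
  mask_value <- as.numeric(seq_len(nrow(masks)))   # binary-counter value
  ord <- order(-aucs, mask_value)
  ranked <- data.frame(rank = seq_along(ord), auc = aucs[ord],
                       masks[ord, , drop = FALSE])
  names(ranked)[-(1:2)] <- descriptors
  k <- min(k, nrow(ranked))
  presence <- colSums(ranked[seq_len(k), descriptors, drop = FALSE])
  predefined <- lapply(predefined_subsets(), function(msk) {
    keep <- names(msk)[msk]
    if (!all(keep %in% descriptors)) return(NULL)
    evaluate_subset(table, keep, design, outcome = xy$outcome, C = C,
                    calibrate = calibrate, splits = splits)
  })
  predefined <- predefined[!vapply(predefined, is.null, logical(1))]
  structure(list(ranked = ranked, presence = presence, k = k,
                 predefined = predefined, descriptors = descriptors,
                 design = design, outcome = xy$outcome, n = nrow(xy$x),
                 n_subsets = nrow(masks),
                 n_skipped_splits = sum(splits$skip)),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat(sprintf("Exhaustive subset search: %d subsets of %d descriptors, %s outcome, n = %d\n",
              x$n_subsets, length(x$descriptors), x$outcome, x$n))
  cat(sprintf("  %d repeats of %.0f%% random test splits\n",
              x$design$n_repeats, 100 * x$design$test_fraction))
  cat(sprintf("Top %d subsets by pooled AUC:\n", x$k))
  top <- x$ranked[seq_len(x$k), ]
  marks <- apply(top[x$descriptors], 1,
                 function(r) paste(x$descriptors[as.logical(r)], collapse = " "))
  for (i in seq_len(x$k))
    cat(sprintf("  %5.3f  %s\n", top$auc[i], marks[i]))
  cat("Presence in top", x$k, "subsets:\n ")
  cat(sprintf(" %s=%d", names(x$presence), x$presence), "\n")
  invisible(x)
}

#' @export
summary.search_report <- function(object, ...) {
  pre <- vapply(object$predefined, function(p) p$auc, numeric(1))
  cat(sprintf("Best full-search AUC: %.3f\n", object$ranked$auc[1]))
  cat("Predefined subsets:\n")
  for (nm in names(pre)) cat(sprintf("  %-14s %.3f\n", nm, pre[nm]))
  invisible(list(best_auc = object$ranked$auc[1], predefined = pre,
                 presence = object$presence))
}

#' Plot the predefined-subset ROC curves of a search report
#'
#' Multi-curve pooled ROC plot: the best full-search subset alongside the
#' seven predefined subsets.
#'
#' @param x A `search_report`.
#' @param ... Passed to [plot.roc_result()].
#' @export
plot.search_report <- function(x, ...) {
  cols <- grDevices::hcl.colors(length(x$predefined) + 1, "Dark 2")
  labels <- character(0)
  first <- TRUE
  i <- 1
  for (nm in names(x$predefined)) {
    plot(x$predefined[[nm]]$roc, add = !first, col = cols[i], ...)
    labels <- c(labels, sprintf("%s (%.2f)", nm, x$predefined[[nm]]$auc))
    first <- FALSE
    i <- i + 1
  }
  legend("bottomright", legend = labels, col = cols[seq_along(labels)],
         lwd = 2, cex = 0.7, bty = "n")
  invisible(x)
}

#' Write a search report to CSV files
#'
#' Writes `ranked.csv` (pooled AUC plus the 0/1 descriptor flags for every
#' subset, ranked), `presence_counts.csv` (descriptor presence in the top-k
#' subsets), and one `roc_<name>.csv` (fpr, tpr, threshold) per predefined
#' subset.  Output is deterministic given the design seed.
#'
#' @param report A `search_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_search_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ranked <- report$ranked
  for (d in report$descriptors) ranked[[d]] <- as.integer(ranked[[d]])
  write.csv(ranked, file.path(dir, "ranked.csv"), row.names = FALSE)
  write.csv(data.frame(descriptor = names(report$presence),
                       count = as.integer(report$presence)),
            file.path(dir, "presence_counts.csv"), row.names = FALSE)
  for (nm in names(report$predefined)) {
    roc <- report$predefined[[nm]]$roc
    write.csv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                         tpr = roc$tpr),
              file.path(dir, paste0("roc_", nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
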