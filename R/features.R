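#' Binary low-outcome label
#'
#' Low outcome is a Bayley-III composite score strictly below 85 (one
#' standard deviation below the population mean of 100); a score of 85 or
#' higher is favourable.
#'
#' @param score Bayley composite score(s).
#' @param threshold Cut-off (default 85).
#' @return Integer 0/1 vector; `NA` scores give `NA` (such subjects are
#'   excluded upstream, never labelled).
#' @export
label_low_outcome <- function(score, threshold = 85) {
  as.integer(score < threshold)
}

#' Assemble a cohort feature table for one experimental arm
#'
#' Joins per-subject metadata with per-(subject, timepoint) image
#' descriptors into a modelling table for one of the three arms: the
#' 30-week scan, the 40-week scan, or the serial change (`"delta"`, the
#' 40-week minus 30-week difference of the 13 image descriptors, with GA at
#' birth passed through unchanged).  Subjects lacking a required scan or
#' the designated outcome score are dropped with a message.
#'
#' @param records Data frame of subject metadata as returned by
#'   [read_subject_table()].
#' @param descriptors Data frame with columns `subject_id`, `timepoint`
#'   (`"30wk"` or `"40wk"`) and the 13 image descriptor columns
#'   (`setdiff(descriptor_names(), "GA")`).
#' @param arm One of `"30wk"`, `"40wk"`, `"delta"`.
#' @param outcome Which outcome defines the class label: `"cognitive"` or
#'   `"motor"`.
#' @param threshold Low-outcome cut-off (default 85).
#' @return A `cohort_table` sorted by `subject_id` (see
#'   [simulate_cohort()] for the column layout).
#' @export
build_arm <- function(records, descriptors,
                      arm = c("30wk", "40wk", "delta"),
                      outcome = c("cognitive", "motor"), threshold = 85) {
  arm <- match.arg(arm)
  outcome <- match.arg(outcome)
  img <- setdiff(descriptor_names(), "GA")
  need <- c("subject_id", "timepoint", img)
  missing_cols <- setdiff(need, names(descriptors))
  if (length(missing_cols))
    stop("descriptor table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  score_col <- paste0(outcome, "_score")
  if (!score_col %in% names(records))
    stop("records lack column ", score_col)

  grab <- function(tp) {
    d <- descriptors[descriptors$timepoint == tp, c("subject_id", img)]
    if (anyDuplicated(d$subject_id))
      stop("duplicate (subject, timepoint) rows at ", tp)
    d
  }
  if (arm == "delta") {
    d30 <- grab("30wk")
    d40 <- grab("40wk")
    ids <- intersect(d30$subject_id, d40$subject_id)
    d30 <- d30[match(ids, d30$subject_id), ]
    d40 <- d40[match(ids, d40$subject_id), ]
    feat <- data.frame(subject_id = ids,
                       as.data.frame(d40[img] - d30[img]),
                       check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    feat <- grab(arm)
  }

  m <- merge(feat, records, by = "subject_id")
  # subjects in the records that lack the required scan(s) never reach m
  dropped <- sum(!records$subject_id %in% m$subject_id)
  keep <- !is.na(m[[score_col]]) & !is.na(m$ga_birth)
  dropped <- dropped + sum(!keep)
  if (dropped > 0)
    message(dropped, " subject(s) dropped (missing scan, GA or ",
            outcome, " score)")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no subjects remain for arm ", arm)

  out <- data.frame(subject_id = m$subject_id, GA = m$ga_birth,
                    m[img], check.names = FALSE, stringsAsFactors = FALSE)
  out$cognitive_score <- if ("cognitive_score" %in% names(m))
    m$cognitive_score else NA_real_
  out$motor_score <- if ("motor_score" %in% names(m))
    m$motor_score else NA_real_
  out$outcome_cognitive <- label_low_outcome(out$cognitive_score, threshold)
  out$outcome_motor <- label_low_outcome(out$motor_score, threshold)
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "arm") <- arm
  attr(out, "outcome") <- outcome
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Fit min-max scaling parameters on a training subset
#'
#' Per-descriptor minimum and maximum computed over the training rows only;
#' no information flows from other rows.  Constant training columns are
#' flagged and mapped to 0 by [apply_minmax()].
#'
#' @param x Numeric matrix or data frame of descriptor columns.
#' @param train_index Row indices of the training subset.
#' @return An object of class `scaling_params`.
#' @export
fit_minmax <- function(x, train_index) {
  x <- as.matrix(x)
  if (length(train_index) == 0L) stop("empty training index")
  tr <- x[train_index, , drop = FALSE]
  mins <- apply(tr, 2, min)
  maxs <- apply(tr, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs <= mins),
            class = "scaling_params")
}

#' Apply min-max scaling
#'
#' Maps `x` to `(x - min) / (max - min)` using parameters estimated on a
#' training subset.  Values outside the training range are deliberately not
#' clipped (they map outside \[0, 1\]); constant training columns map to 0.
#'
#' @param params A [fit_minmax()] result.
#' @param rows Numeric matrix or data frame with the same columns.
#' @return A numeric matrix of scaled values.
#' @export
apply_minmax <- function(params, rows) {
  stopifnot(inherits(params, "scaling_params"))
  x <- as.matrix(rows)
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  out <- sweep(out, 2, ifelse(params$constant, 1, rng), "/")
  out[, params$constant] <- 0
  out
}
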