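#' Specification of a simulated two-class cohort
#'
#' Describes a cohort of subjects with the 14 canonical descriptors drawn
#' from class-conditional Gaussians.  The positive class ("low outcome")
#' has per-descriptor mean shifts `delta` in standardised units; Bayley
#' composite scores are then generated so that `score < 85` reproduces the
#' drawn class labels exactly, which makes the printed prevalence counts of
#' a target cohort exactly reproducible.
#'
#' @param n Number of subjects.
#' @param prevalence Proportion of the positive (low-outcome) class; the
#'   realised count is `round(n * prevalence)`.
#' @param n_positive Exact positive count (overrides `prevalence`).
#' @param delta Standardised class-mean shift: either a single number
#'   applied to no descriptor unless named, or a named vector over
#'   [descriptor_names()] (unnamed descriptors get 0).
#' @param noise_sd Within-class standard deviation of the image descriptors
#'   (default 1).
#' @param correlation Optional 13x13 correlation matrix for the image
#'   descriptors (default identity).
#' @param ga_mean,ga_sd,ga_range Gestational-age-at-birth distribution:
#'   truncated normal, defaults 26.5 +/- 1.0 weeks on \[24, 28\].
#' @param score_sd Scale of the score offsets around the 85-point
#'   threshold (default 10).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence = NULL, n_positive = NULL,
                        delta = numeric(0), noise_sd = 1,
                        correlation = NULL, ga_mean = 26.5, ga_sd = 1,
                        ga_range = c(24, 28), score_sd = 10, seed = 1L) {
  if (is.null(n_positive)) {
    if (is.null(prevalence)) stop("give `prevalence` or `n_positive`")
    n_positive <- round(n * prevalence)
  }
  stopifnot(n_positive >= 0, n_positive <= n)
  dn <- descriptor_names()
  dvec <- setNames(numeric(length(dn)), dn)
  if (length(delta)) {
    if (is.null(names(delta)))
      stop("`delta` must be named with descriptor names")
    bad <- setdiff(names(delta), dn)
    if (length(bad)) stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
    dvec[names(delta)] <- delta
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!all(dim(correlation) == c(13L, 13L)))
      stop("`correlation` must be 13x13 (image descriptors)")
  }
  structure(list(n = as.integer(n), n_positive = as.integer(n_positive),
                 delta = dvec, noise_sd = noise_sd,
                 correlation = correlation, ga_mean = ga_mean,
                 ga_sd = ga_sd, ga_range = ga_range, score_sd = score_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated-normal draws by inverse-CDF (deterministic given the RNG state)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate a cohort table
#'
#' Draws class labels (exact positive count), then descriptors from
#' class-conditional Gaussians with the specified shifts and correlations,
#' then Bayley composite scores consistent with the labels: positives get
#' `85 - |offset|`, negatives `85 + |offset|`, so labelling at the < 85
#' threshold recovers the drawn labels with zero mismatches.  GA at birth is
#' drawn from the truncated normal (its class shift, if any, is applied to
#' the location before truncation).  The non-designated outcome's scores
#' are drawn from the population distribution N(100, 15) independently of
#' the labels.
#'
#' @param spec A [cohort_spec()].
#' @param outcome Which outcome the labels drive: `"motor"` or
#'   `"cognitive"`.
#' @param arm Arm tag stored on the table (`"30wk"`, `"40wk"` or
#'   `"delta"`); descriptive metadata only.
#' @return A `cohort_table`: a data frame with `subject_id`, the 14
#'   descriptor columns, `cognitive_score`, `motor_score`,
#'   `outcome_cognitive` and `outcome_motor`, with attributes `arm` and
#'   `outcome`.
#' @export
simulate_cohort <- function(spec, outcome = c("motor", "cognitive"),
                            arm = "40wk") {
  stopifnot(inherits(spec, "cohort_spec"))
  outcome <- match.arg(outcome)
  set.seed(seed_stream(spec$seed, "cohort"))
  n <- spec$n
  label <- integer(n)
  label[sample.int(n, spec$n_positive)] <- 1L

  dn <- descriptor_names()
  img <- setdiff(dn, "GA")
  Z <- matrix(rnorm(n * 13L), n, 13L)
  if (!is.null(spec$correlation))
    Z <- Z %*% chol(spec$correlation)
  shift <- matrix(spec$delta[img], n, 13L, byrow = TRUE) * label
  Ximg <- (Z + shift) * spec$noise_sd
  colnames(Ximg) <- img
  ga <- rtruncnorm(n, spec$ga_mean + spec$ga_sd * spec$delta[["GA"]] * label,
                   spec$ga_sd, spec$ga_range[1], spec$ga_range[2])

  offset <- pmax(abs(rnorm(n, 0, spec$score_sd)), 1e-6)
  score <- ifelse(label == 1L, 85 - offset, 85 + offset)
  other <- rnorm(n, 100, 15)
  cognitive <- if (outcome == "cognitive") score else other
  motor <- if (outcome == "motor") score else other

  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)), GA = ga,
                    Ximg, check.names = FALSE, stringsAsFactors = FALSE)
  out$cognitive_score <- cognitive
  out$motor_score <- motor
  out$outcome_cognitive <- label_low_outcome(cognitive)
  out$outcome_motor <- label_low_outcome(motor)
  attr(out, "arm") <- arm
  attr(out, "outcome") <- outcome
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Theoretical AUC of a single Gaussian descriptor
#'
#' For two Gaussian classes with standardised mean difference `delta` and
#' standard deviations `sd0`, `sd1`, the AUC of the descriptor itself is
#' `pnorm(delta / sqrt(sd0^2 + sd1^2))`.
#'
#' @param delta Standardised mean difference between classes.
#' @param sd0,sd1 Class standard deviations (default 1).
#' @return AUC in \[0, 1\].
#' @export
theoretical_auc <- function(delta, sd0 = 1, sd1 = 1) {
  if (sd0 <= 0 || sd1 <= 0) stop("standard deviations must be positive")
  pnorm(delta / sqrt(sd0^2 + sd1^2))
}
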