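# brute-force Mann-Whitney statistic: independent oracle for pooled AUC
mann_whitney <- function(prob, label) {
  pos <- prob[label == 1]
  neg <- prob[label == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("cv_design and draw_splits give valid reproducible partitions", {
  des <- cv_design(n_repeats = 20, seed = 4)
  sp <- draw_splits(66, des)
  expect_equal(sp$test_size, ceiling(66 * 0.05))  # = 4
  expect_length(sp$test, 20L)
  for (te in sp$test) {
    expect_length(te, 4L)
    expect_true(all(te %in% 1:66))
    expect_false(anyDuplicated(te) > 0)
    # train and test partition the index set
    expect_setequal(c(te, setdiff(1:66, te)), 1:66)
  }
  expect_identical(draw_splits(66, des), sp)       # same seed, same splits
  expect_false(identical(draw_splits(66, cv_design(20, seed = 5)), sp))
})

test_that("degenerate single-class training splits are redrawn then skipped", {
  # 1 positive among 8: any test set containing the positive leaves a
  # single-class training split
  labels <- c(1L, rep(0L, 7))
  des <- cv_design(n_repeats = 200, test_fraction = 0.25, seed = 2)
  sp <- draw_splits(8, des, labels)
  # the stored test sets are the final (post-redraw) ones, so a repeat is
  # skipped exactly when its final test set absorbs the lone positive
  has_pos <- vapply(sp$test, function(te) 1L %in% te, logical(1))
  expect_identical(sp$skip, has_pos)
  # a single draw hits the positive with p = 2/8; one redraw squares that,
  # so far fewer than p * n_repeats = 50 repeats end up skipped
  expect_gt(sum(sp$skip), 0L)
  expect_lt(sum(sp$skip), 50L)
})

test_that("stratified splits preserve the class balance", {
  labels <- rep(c(1L, 0L), c(25, 75))
  des <- cv_design(n_repeats = 50, test_fraction = 0.2, seed = 9,
                   stratified = TRUE)
  sp <- draw_splits(100, des, labels)
  for (te in sp$test) expect_equal(sum(labels[te]), 5L)
})

test_that("fit_predict_one separates a separable toy problem", {
  train_x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  train_y <- rep(c(0L, 1L), each = 10)
  test_x <- matrix(c(0.05, 0.95, 0.1, 0.9), ncol = 1)
  r <- fit_predict_one(train_x, train_y, test_x)
  expect_true(all(r$prob >= 0 & r$prob <= 1))
  expect_true(min(r$prob[c(2, 4)]) > max(r$prob[c(1, 3)]))
  expect_error(fit_predict_one(train_x, rep(1L, 20), test_x),
               "single class")
})

test_that("label flip complements the prediction ranking", {
  set.seed(31)
  train_x <- matrix(rnorm(80), ncol = 2)
  train_y <- as.integer(train_x[, 1] + 0.3 * rnorm(40) > 0)
  if (all(train_y == train_y[1])) train_y[1] <- 1L - train_y[1]
  test_x <- matrix(rnorm(30), ncol = 2)
  a <- fit_predict_one(train_x, train_y, test_x)
  b <- fit_predict_one(train_x, 1L - train_y, test_x)
  expect_equal(order(a$prob), rev(order(b$prob)))
})

test_that("duplicating training rows with C halved leaves decisions unchanged", {
  # duplicating every row doubles the hinge-loss sum, so halving C restores
  # the exact same objective: the fitted decision function must coincide
  set.seed(13)
  train_x <- matrix(rnorm(60), ncol = 2)
  train_y <- as.integer(train_x[, 1] > 0)
  if (all(train_y == train_y[1])) train_y[1] <- 1L - train_y[1]
  test_x <- matrix(rnorm(40), ncol = 2)
  a <- fit_predict_one(train_x, train_y, test_x, calibrate = FALSE)
  b <- fit_predict_one(rbind(train_x, train_x), c(train_y, train_y), test_x,
                       C = 0.5, calibrate = FALSE)
  expect_equal(a$decision, b$decision, tolerance = 1e-8)
  expect_equal(order(a$decision), order(b$decision))
})

test_that("the linear SVM agrees with an independent implementation", {
  set.seed(21)
  n <- 120
  x <- matrix(rnorm(2 * n), ncol = 2)
  y <- as.integer(x[, 1] + 0.5 * rnorm(n) > 0)
  tr <- 1:90
  te <- 91:120
  mine <- fit_predict_one(x[tr, ], y[tr], x[te, ], calibrate = FALSE)
  xs <- apply_minmax(fit_minmax(x, tr), x)       # same scaling for both
  ref <- e1071::svm(xs[tr, ], factor(y[tr]), kernel = "linear", cost = 1,
                    scale = FALSE)
  dec <- attr(predict(ref, xs[te, ], decision.values = TRUE),
              "decision.values")[, 1]
  if (cor(dec, mine$decision) < 0) dec <- -dec   # sign is class-order bound
  expect_gt(cor(rank(dec), rank(mine$decision)), 0.98)
  expect_equal(pooled_roc(mine$decision, y[te])$auc,
               pooled_roc(dec, y[te])$auc, tolerance = 0.02)
})

test_that("pooled_roc matches hand values, the tie convention and pROC", {
  r <- pooled_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1)
  expect_equal(tail(r$tpr, 1), 1)

  expect_equal(pooled_roc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  set.seed(2)
  p <- round(runif(300), 2)              # rounding forces ties
  y <- rbinom(300, 1, 0.3)
  expect_equal(pooled_roc(p, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  expect_error(pooled_roc(p, rep(1, 300)), "single class")
})

test_that("AUC flips exactly under label complement", {
  set.seed(3)
  p <- runif(50)
  y <- rbinom(50, 1, 0.4)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  expect_equal(pooled_roc(p, y)$auc, 1 - pooled_roc(p, 1 - y)$auc)
})

test_that("evaluate_subset pools predictions and is deterministic", {
  tab <- simulate_cohort(cohort_spec(n = 120, prevalence = 0.25,
                                     delta = c(GI = 1.5), seed = 6),
                         outcome = "motor")
  des <- cv_design(n_repeats = 30, seed = 6)
  r1 <- evaluate_subset(tab, "GI", des)
  r2 <- evaluate_subset(tab, "GI", des)
  expect_identical(r1, r2)
  expect_s3_class(r1, "subset_result")
  expect_gt(r1$auc, 0.6)                        # strong signal is recovered
  expect_equal(r1$auc, r1$roc$auc)
  # records: only test-set appearances, correct labels
  expect_true(all(r1$records$repeat_index %in% 1:30))
  expect_equal(nrow(r1$records), 30 * ceiling(120 * 0.05))
  lab <- setNames(tab$outcome_motor, tab$subject_id)
  expect_equal(r1$records$true_label,
               unname(lab[r1$records$subject_id]))
  expect_error(evaluate_subset(tab, character(0), des), "empty")
  expect_error(evaluate_subset(tab, "XX", des), "XX")
})

test_that("label permutation yields an AUC distribution centred at 0.5", {
  tab <- simulate_cohort(cohort_spec(n = 200, prevalence = 0.25,
                                     delta = c(GI = 1.5), seed = 10),
                         outcome = "motor")
  des <- cv_design(n_repeats = 40, seed = 10)
  r <- evaluate_subset(tab, "GI", des)
  set.seed(99)
  perm <- replicate(50, pooled_roc(r$records$calibrated_probability,
                                   sample(r$records$true_label))$auc)
  se <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm) - 0.5), 2 * se + 1e-8)
})

test_that("adding a pure-noise descriptor barely changes pooled AUC", {
  tab <- simulate_cohort(cohort_spec(n = 2000, prevalence = 0.25,
                                     delta = c(GI = 1.19), seed = 14),
                         outcome = "motor")
  des <- cv_design(n_repeats = 30, seed = 14)
  a1 <- evaluate_subset(tab, "GI", des)$auc
  a2 <- evaluate_subset(tab, c("GI", "ISA"), des)$auc
  expect_lt(abs(a1 - a2), 0.05)
})

test_that("pooled AUC equals the Mann-Whitney statistic", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    p <- round(runif(n), sample(1:3, 1))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    expect_equal(pooled_roc(p, y)$auc, mann_whitney(p, y))
  }
})
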