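test_that("phantom_spec computes a field of view that fits the anatomy", {
  ps <- phantom_spec()
  expect_s3_class(ps, "phantom_spec")
  # structures span 52 mm in x/y and 68 mm in z
  expect_true(all(ps$fov * ps$spacing >= c(52, 52, 68)))
  expect_error(phantom_spec(fov = 20), "field of view")
  ps2 <- phantom_spec(spacing = c(0.34, 0.34, 2))
  expect_true(all(ps2$fov * c(0.34, 0.34, 2) >= c(52, 52, 68)))
})

test_that("the phantom contains all eight classes with exact truth at a=0", {
  ph <- make_phantom(phantom_spec(spacing = c(1, 1, 1)))
  expect_s3_class(ph, "brain_phantom")
  expect_setequal(setdiff(unique(as.vector(ph$volume$grid)), 0L), 1:8)
  expect_true(ph$truth$exact)
  expect_equal(sum(ph$truth$relative), 1)
  expect_equal(ph$truth$ISA, 4 * pi * 400)
  expect_equal(ph$truth$GI, 1)
  expect_equal(ph$truth$MC, 1 / 20)
  expect_equal(ph$truth$MT, 3)
  expect_false(make_phantom(phantom_spec(spacing = c(1, 1, 1),
                                         fold_amplitude = 1))$truth$exact)
  expect_output(print(ph), "phantom")
})

test_that("coarse voxel counts approach the closed-form volumes", {
  ph <- make_phantom(phantom_spec(spacing = c(1, 1, 1)))
  tv <- tissue_volumes(ph$volume)
  err <- tv$relative[names(ph$truth$relative)] / ph$truth$relative - 1
  # 1 mm voxels: lattice error scales with surface/volume ratio; the
  # smallest structure (brain stem, r = 2.5 mm) dominates
  expect_lt(max(abs(err)), 0.10)
  expect_equal(tv$icv, ph$truth$icv, tolerance = 0.01)
})

test_that("anisotropic clinical spacing preserves volume accuracy", {
  ph <- make_phantom(phantom_spec(spacing = c(0.34, 0.34, 2)))
  tv <- tissue_volumes(ph$volume)
  err <- tv$relative[names(ph$truth$relative)] / ph$truth$relative - 1
  expect_lt(max(abs(err)), 0.10)
})

test_that("the parametric surface oracle matches closed forms at a=0", {
  tru <- phantom_surface_truth(0)
  expect_equal(tru$area, 4 * pi * 400, tolerance = 1e-4)
  expect_equal(tru$gi, 1, tolerance = 1e-3)
  expect_equal(tru$volume, 4 / 3 * pi * 8000, tolerance = 1e-4)
  # folding strictly increases area and GI
  tru2 <- phantom_surface_truth(2)
  expect_gt(tru2$area, tru$area)
  expect_gt(tru2$gi, tru$gi)
})

test_that("cohort simulation hits the requested positive count exactly", {
  tab <- simulate_cohort(cohort_spec(n = 153, prevalence = 0.24, seed = 3),
                         outcome = "cognitive")
  expect_equal(sum(tab$outcome_cognitive), round(153 * 0.24))
  expect_equal(nrow(tab), 153L)
  tab2 <- simulate_cohort(cohort_spec(n = 66, n_positive = 9, seed = 3),
                          outcome = "motor")
  expect_equal(sum(tab2$outcome_motor), 9L)
  # scores are consistent with the labels at the 85 threshold
  expect_equal(tab2$outcome_motor, as.integer(tab2$motor_score < 85))
})

test_that("cohort descriptors realise the requested effect size", {
  spec <- cohort_spec(n = 4000, prevalence = 0.5, delta = c(GI = 1.19),
                      seed = 5)
  tab <- simulate_cohort(spec, outcome = "motor")
  d_emp <- mean(tab$GI[tab$outcome_motor == 1]) -
    mean(tab$GI[tab$outcome_motor == 0])
  expect_equal(d_emp, 1.19, tolerance = 0.1)
  # unshifted descriptors stay centred
  expect_equal(mean(tab$ISA), 0, tolerance = 0.1)
  # GA respects the truncation range
  expect_true(all(tab$GA >= 24 & tab$GA <= 28))
})

test_that("cohort simulation is reproducible and seed-sensitive", {
  s <- cohort_spec(n = 50, prevalence = 0.2, seed = 11)
  expect_identical(simulate_cohort(s), simulate_cohort(s))
  s2 <- cohort_spec(n = 50, prevalence = 0.2, seed = 12)
  expect_false(identical(simulate_cohort(s), simulate_cohort(s2)))
})

test_that("requested descriptor correlations are realised", {
  C <- diag(13)
  C[1, 2] <- C[2, 1] <- 0.7        # CB with mWM (image-descriptor order)
  spec <- cohort_spec(n = 5000, prevalence = 0.2, correlation = C, seed = 2)
  tab <- simulate_cohort(spec)
  expect_equal(cor(tab$CB, tab$mWM), 0.7, tolerance = 0.05)
  expect_equal(cor(tab$CB, tab$BGT), 0, tolerance = 0.05)
})

test_that("theoretical_auc matches the normal closed form", {
  expect_equal(theoretical_auc(0), 0.5)
  expect_equal(theoretical_auc(1.19), pnorm(1.19 / sqrt(2)))
  expect_gt(theoretical_auc(2), theoretical_auc(1))
  expect_error(theoretical_auc(1, sd0 = 0))
})

test_that("component seed streams are decorrelated", {
  expect_false(neopredict:::seed_stream(1L, "cohort") ==
                 neopredict:::seed_stream(1L, "splits"))
  expect_identical(neopredict:::seed_stream(7L, "cohort"),
                   neopredict:::seed_stream(7L, "cohort"))
})
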