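test_that("descriptor_names gives the 14 canonical descriptors in order", {
  dn <- descriptor_names()
  expect_length(dn, 14L)
  expect_equal(dn[1], "GA")
  expect_equal(dn[14], "BV")
  expect_equal(dn, c("GA", "CB", "mWM", "BGT", "vCSF", "uWM", "BS", "cGM",
                     "eCSF", "ISA", "MC", "GI", "MT", "BV"))
})

test_that("tissue_volumes counts voxels exactly with anisotropic spacing", {
  g <- array(0L, c(4, 4, 4))
  g[1:2, 1, 1] <- 1L      # 2 voxels uWM
  g[3, 1, 1] <- 3L        # 1 voxel cGM
  g[4, 4, 4] <- 8L        # 1 voxel BS
  v <- label_volume(g, c(0.34, 0.34, 2))
  tv <- tissue_volumes(v)
  voxvol <- 0.34 * 0.34 * 2
  expect_equal(tv$absolute[["uWM"]], 2 * voxvol)
  expect_equal(tv$absolute[["cGM"]], 1 * voxvol)
  expect_equal(tv$absolute[["BS"]], 1 * voxvol)
  expect_equal(tv$icv, 4 * voxvol)
  expect_equal(sum(tv$relative), 1)
  expect_equal(unname(tv$relative[c("mWM", "BGT", "vCSF", "eCSF", "CB")]),
               rep(0, 5))
  expect_error(tissue_volumes(label_volume(array(0L, c(3, 3, 3)), rep(1, 3))))
})

test_that("largest_component and fill_holes behave as set operations", {
  m <- array(FALSE, c(7, 7, 7))
  m[2:4, 2:4, 2:4] <- TRUE          # 27-voxel block
  m[6, 6, 6] <- TRUE                # separate single voxel
  lc <- neopredict:::largest_component(m)
  expect_equal(sum(lc), 27L)
  expect_false(lc[6, 6, 6])

  hollow <- array(FALSE, c(7, 7, 7))
  hollow[2:6, 2:6, 2:6] <- TRUE
  hollow[4, 4, 4] <- FALSE          # internal cavity
  filled <- neopredict:::fill_holes(hollow)
  expect_true(filled[4, 4, 4])
  expect_equal(sum(filled), 125L)
  # open notch touching the border must not be filled
  notch <- hollow
  notch[4, 4, 4] <- TRUE
  notch[4, 4, 1:3] <- FALSE
  expect_equal(neopredict:::fill_holes(notch), notch)
})

test_that("resample_isotropic preserves labels and physical extent", {
  g <- array(sample(0:8, 8 * 8 * 4, replace = TRUE), c(8, 8, 4))
  rs <- neopredict:::resample_isotropic(g, c(0.5, 0.5, 0.5), 0.5)
  expect_identical(rs$grid, g)              # already isotropic: unchanged

  rs2 <- neopredict:::resample_isotropic(g, c(0.5, 0.5, 2), 0.5)
  expect_equal(dim(rs2$grid), c(8L, 8L, 16L))
  expect_true(all(rs2$grid %in% g))         # nearest neighbour: no new labels
  # in-plane content is untouched, each slice is replicated along z
  expect_identical(rs2$grid[, , 1], g[, , 1])
  expect_identical(rs2$grid[, , 16], g[, , 4])
})

test_that("interior mask closes the ventricle walls", {
  # uWM shell around a vCSF core: the interior mask must include both
  g <- array(0L, c(11, 11, 11))
  g[3:9, 3:9, 3:9] <- 1L
  g[5:7, 5:7, 5:7] <- 4L
  mask <- neopredict:::interior_mask(g)
  expect_equal(sum(mask), 7L^3)
  # with the ventricle mislabelled background the cavity is still filled
  g2 <- g
  g2[5:7, 5:7, 5:7] <- 0L
  expect_equal(sum(neopredict:::interior_mask(g2)), 7L^3)
})

test_that("median thickness of concentric spheres equals the gap", {
  n <- 44L
  x <- (seq_len(n) - 1) * 0.5 - 10.7
  R <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  inner <- neopredict:::extract_isosurface(1 / (1 + exp((R - 6) / 0.5)),
                                           rep(0.5, 3))
  outer_s <- neopredict:::extract_isosurface(1 / (1 + exp((R - 9) / 0.5)),
                                             rep(0.5, 3))
  expect_equal(median_cortical_thickness(inner, outer_s), 3,
               tolerance = 0.05)
  expect_equal(median_cortical_thickness(inner, outer_s, symmetric = TRUE),
               3, tolerance = 0.05)
})

test_that("gyrification index of a convex surface is 1", {
  n <- 40L
  x <- (seq_len(n) - 1) * 0.5 - 9.75
  R <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  s <- neopredict:::extract_isosurface(1 / (1 + exp((R - 8) / 0.5)),
                                       rep(0.5, 3))
  expect_equal(gyrification_index(s), 1, tolerance = 0.01)
})

test_that("signed global mean curvature recovers 1/r with correct scaling", {
  mk <- function(r) {
    n <- 44L
    x <- (seq_len(n) - 1) * 0.5 - 10.7
    R <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
    neopredict:::extract_isosurface(1 / (1 + exp((R - r) / 0.5)), rep(0.5, 3))
  }
  mc6 <- global_mean_curvature(mk(6))
  mc9 <- global_mean_curvature(mk(9))
  expect_equal(mc6, 1 / 6, tolerance = 0.05)
  expect_equal(mc9, 1 / 9, tolerance = 0.05)
  expect_gt(mc6, mc9)        # curvature decreases with radius
})

test_that("extract_inner_surface requires cortical grey matter", {
  g <- array(0L, c(6, 6, 6))
  g[2:5, 2:5, 2:5] <- 1L
  v <- label_volume(g, rep(0.5, 3))
  expect_error(extract_inner_surface(v), "cortical grey")
})
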