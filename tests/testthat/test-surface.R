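# unit tetrahedron with outward winding: exact area and volume oracles
tetra <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  list(v = v, f = f)
}

test_that("triangle_surface validates closedness and orientation", {
  tf <- tetra()
  s <- triangle_surface(tf$v, tf$f)
  expect_s3_class(s, "triangle_surface")
  expect_true(is_watertight(s))
  expect_equal(surface_area(s), 3 / 2 + sqrt(3) / 2)
  expect_equal(enclosed_volume(s), 1 / 6)

  # inward winding is rejected
  expect_error(triangle_surface(tf$v, tf$f[, c(1, 3, 2)]), "orientation")
  # open surface (one face missing) is rejected
  expect_error(triangle_surface(tf$v, tf$f[1:3, , drop = FALSE]))
})

test_that("clean_surface drops degenerate faces and orphan vertices", {
  tf <- tetra()
  v <- rbind(tf$v, c(9, 9, 9))                 # unreferenced vertex
  f <- rbind(tf$f, c(1, 1, 2))                 # degenerate face
  s <- triangle_surface(v, f)
  expect_equal(nrow(s$vertices), 4L)
  expect_equal(nrow(s$faces), 4L)
})

test_that("convex hull is exact on a cube and accurate on sphere clouds", {
  cc <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_area(cc), 6)

  set.seed(42)
  p <- matrix(rnorm(3 * 2000), ncol = 3)
  p <- 5 * p / sqrt(rowSums(p^2))
  expect_equal(convex_hull_area(p), 4 * pi * 25, tolerance = 0.02)

  # interior points never change the hull
  withr <- rbind(p, matrix(runif(300, -1, 1), ncol = 3))
  expect_equal(convex_hull_area(withr), convex_hull_area(p))
})

test_that("support-sampled hull matches the full hull on large clouds", {
  set.seed(7)
  p <- matrix(rnorm(3 * 20000), ncol = 3)
  p <- 10 * p / sqrt(rowSums(p^2))
  a_sampled <- convex_hull_area(p)                       # n > max_candidates
  a_full <- convex_hull_area(p, max_candidates = 30000L)
  expect_equal(a_sampled, a_full, tolerance = 0.005)
  expect_equal(a_sampled, 4 * pi * 100, tolerance = 0.005)
})

test_that("iso-surface of a smooth spherical field recovers the sphere", {
  n <- 40L
  x <- (seq_len(n) - 1) * 0.5 - 9.75
  R <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  fld <- 1 / (1 + exp((R - 8) / 0.5))
  s <- neopredict:::extract_isosurface(fld, c(0.5, 0.5, 0.5))
  expect_true(is_watertight(s))
  expect_equal(surface_area(s), 4 * pi * 64, tolerance = 0.005)
  expect_equal(enclosed_volume(s), 4 / 3 * pi * 512, tolerance = 0.005)
})

test_that("smoothing preserves topology and only slightly shrinks a sphere", {
  n <- 40L
  x <- (seq_len(n) - 1) * 0.5 - 9.75
  R <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  fld <- 1 / (1 + exp((R - 8) / 0.5))
  s <- neopredict:::extract_isosurface(fld, c(0.5, 0.5, 0.5))
  sm <- smooth_surface(s, iterations = 10, lambda = 0.5)
  expect_true(is_watertight(sm))
  v0 <- enclosed_volume(s)
  v1 <- enclosed_volume(sm)
  expect_lt(v1, v0)                      # Laplacian smoothing shrinks
  expect_gt(v1, 0.98 * v0)               # but only slightly at this scale
})

test_that("PLY export writes a consistent ASCII mesh", {
  tf <- tetra()
  s <- triangle_surface(tf$v, tf$f)
  f <- tempfile(fileext = ".ply")
  on.exit(unlink(f))
  write_surface_ply(s, f)
  lines <- readLines(f)
  expect_equal(lines[1], "ply")
  expect_true(any(grepl("element vertex 4", lines)))
  expect_true(any(grepl("element face 4", lines)))
  expect_equal(length(lines), 9 + 4 + 4)
})
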