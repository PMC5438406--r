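#' Specification of a geometric brain phantom
#'
#' The phantom emulates an 8-class neonatal tissue segmentation with
#' analytically known morphometry: a deep-grey core (BGT, radius 6 mm), a
#' ventricular shell (vCSF, 6-8 mm), unmyelinated white matter (8 mm to the
#' inner cortical radius) with an embedded myelinated-WM sphere (radius
#' 3 mm at offset (0,0,14)), a cortical ribbon of constant radial thickness
#' (default 3 mm), an extracerebral CSF shell out to 26 mm, and separate
#' cerebellum (radius 6 at (0,0,-36)) and brain-stem (radius 2.5 at
#' (0,0,-28.5)) spheres.  The inner cortical radius is
#' `20 + a * sin(k * theta) * sin(k * phi)` in spherical coordinates, so
#' `fold_amplitude = 0` gives concentric spheres with closed-form
#' descriptors, and increasing `a` produces controlled folding.
#'
#' @param spacing Voxel spacing in mm (default isotropic 0.5); the
#'   anisotropic clinical geometry can be emulated with
#'   `c(0.34, 0.34, 2)`.
#' @param fov Field of view in voxels (default computed to fit all
#'   structures with a 1-voxel margin).
#' @param fold_amplitude Radial fold amplitude `a` in mm (default 0).
#' @param fold_frequency Angular fold frequency `k` (integer, default 6).
#' @param cortical_thickness Radial thickness of the cortical ribbon in mm
#'   (default 3).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = c(0.5, 0.5, 0.5), fov = NULL,
                         fold_amplitude = 0, fold_frequency = 6L,
                         cortical_thickness = 3) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  stopifnot(all(spacing > 0), fold_amplitude >= 0, cortical_thickness > 0)
  radii <- list(bgt = 6, vcsf = 8, uwm_inner = 8, cortex_inner = 20,
                ecsf_outer = 26, mwm_r = 3, mwm_centre = c(0, 0, 14),
                cb_r = 6, cb_centre = c(0, 0, -36),
                bs_r = 2.5, bs_centre = c(0, 0, -28.5))
  # physical bounding box of all structures, relative to the brain centre
  rmax_xy <- radii$ecsf_outer
  z_lo <- radii$cb_centre[3] - radii$cb_r
  z_hi <- radii$ecsf_outer
  extent <- c(2 * rmax_xy, 2 * rmax_xy, z_hi - z_lo)
  if (is.null(fov)) {
    fov <- ceiling(extent / spacing) + 2L
  } else {
    fov <- rep(as.integer(fov), length.out = 3)
    if (any(fov * spacing < extent))
      stop("structures do not fit in the field of view: need at least ",
           paste(ceiling(extent / spacing), collapse = " x "), " voxels")
  }
  structure(list(spacing = spacing, fov = fov,
                 fold_amplitude = fold_amplitude,
                 fold_frequency = as.integer(fold_frequency),
                 cortical_thickness = cortical_thickness, radii = radii),
            class = "phantom_spec")
}

#' Voxelize a geometric brain phantom
#'
#' Rasterises the structures of a [phantom_spec()] onto the voxel grid
#' (later structures overwrite earlier ones, so every voxel carries exactly
#' one label) and returns the label volume together with the analytic
#' descriptor expectations.  For the unfolded phantom the expectations are
#' closed-form: ISA `4*pi*20^2`, GI 1, global mean curvature `1/20`, median
#' thickness equal to the ribbon thickness, and class volumes from
#' sphere/shell formulas.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `brain_phantom` with elements `volume`
#'   (a [label_volume()]) and `truth` (named list of expected descriptor
#'   values; exact for `fold_amplitude = 0`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- spec$radii
  d <- spec$fov
  sp <- spec$spacing
  # place the brain centre so that the structure bounding box is centred,
  # then shift by a fixed irrational sub-voxel phase per axis: exactly
  # lattice-centred (or half-centred) spheres are the degenerate worst
  # cases of voxel counting, so the phantom is rasterised in generic
  # position instead
  z_lo <- r$cb_centre[3] - r$cb_r
  z_hi <- r$ecsf_outer
  phase <- c(1 / pi, exp(-1), sqrt(2) - 1)
  centre <- c((d[1] - 1) * sp[1] / 2,
              (d[2] - 1) * sp[2] / 2,
              (d[3] - 1) * sp[3] / 2 - (z_hi + z_lo) / 2) + phase * sp
  a <- spec$fold_amplitude
  k <- spec$fold_frequency
  th <- spec$cortical_thickness
  # analytic label at physical coordinates relative to the brain centre;
  # the structure painting order makes every point carry exactly one label
  label_at <- function(X, Y, Z) {
    rad <- sqrt(X^2 + Y^2 + Z^2)
    if (a > 0) {
      theta <- acos(pmin(1, pmax(-1, Z / pmax(rad, 1e-12))))
      phi <- atan2(Y, X)
      r_in <- r$cortex_inner + a * sin(k * theta) * sin(k * phi)
    } else {
      r_in <- r$cortex_inner
    }
    g <- integer(length(rad))
    g[rad < r$ecsf_outer] <- 5L                    # eCSF
    g[rad < r_in + th] <- 3L                       # cGM ribbon
    g[rad < r_in] <- 1L                            # uWM
    g[rad < r$vcsf] <- 4L                          # vCSF
    g[rad < r$bgt] <- 7L                           # BGT
    paint <- function(g, off, radius, code) {
      g[(X - off[1])^2 + (Y - off[2])^2 + (Z - off[3])^2 < radius^2] <- code
      g
    }
    g <- paint(g, r$mwm_centre, r$mwm_r, 2L)       # mWM inside uWM
    g <- paint(g, r$cb_centre, r$cb_r, 6L)         # cerebellum
    g <- paint(g, r$bs_centre, r$bs_r, 8L)         # brain stem
    g
  }

  x <- (seq_len(d[1]) - 1) * sp[1] - centre[1]
  y <- (seq_len(d[2]) - 1) * sp[2] - centre[2]
  z <- (seq_len(d[3]) - 1) * sp[3] - centre[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  g <- array(label_at(X, Y, Z), d)
  vol <- label_volume(g, sp)

  ball <- function(rr) 4 / 3 * pi * rr^3
  absolute <- c(
    uWM = ball(r$cortex_inner) - ball(r$vcsf) - ball(r$mwm_r),
    mWM = ball(r$mwm_r),
    cGM = ball(r$cortex_inner + th) - ball(r$cortex_inner),
    vCSF = ball(r$vcsf) - ball(r$bgt),
    eCSF = ball(r$ecsf_outer) - ball(r$cortex_inner + th),
    CB = ball(r$cb_r),
    BGT = ball(r$bgt),
    BS = ball(r$bs_r)
  )
  icv <- sum(absolute)
  truth <- list(
    absolute = absolute[tissue_classes()$abbrev],
    relative = absolute[tissue_classes()$abbrev] / icv,
    icv = icv,
    ISA = 4 * pi * r$cortex_inner^2,
    GI = 1,
    MC = 1 / r$cortex_inner,
    MT = th,
    exact = a == 0
  )
  structure(list(volume = vol, truth = truth, spec = spec),
            class = "brain_phantom")
}

#' @export
print.brain_phantom <- function(x, ...) {
  cat("Geometric brain phantom (fold amplitude",
      x$spec$fold_amplitude, "mm)\n")
  print(x$volume)
  invisible(x)
}

#' Reference surface quantities of the folded phantom from its
#' parametrisation
#'
#' Meshes the analytic inner cortical surface
#' `r(theta, phi) = 20 + a * sin(k theta) * sin(k phi)` directly on a dense
#' parameter grid -- independently of any voxel processing -- and returns
#' its area, convex-hull area, gyrification index and enclosed volume (the
#' latter by spherical quadrature of `r^3/3 sin(theta)`).  Serves as the
#' high-resolution oracle for the voxel pipeline.
#'
#' @param fold_amplitude,fold_frequency Fold parameters `a` (mm) and `k`.
#' @param radius Base radius in mm (default 20).
#' @param n Parameter-grid resolution (default 600, i.e. mean triangle edge
#'   around 0.1 mm at the equator).
#' @return List with `area`, `hull_area`, `gi` and `volume`.
#' @export
phantom_surface_truth <- function(fold_amplitude, fold_frequency = 6L,
                                  radius = 20, n = 600L) {
  a <- fold_amplitude
  k <- fold_frequency
  theta <- seq(0, pi, length.out = n + 1)
  phi <- seq(-pi, pi, length.out = 2 * n + 1)[-1]
  rfun <- function(t, p) radius + a * sin(k * t) * sin(k * p)
  TT <- matrix(theta, n + 1, 2 * n)
  PP <- matrix(phi, n + 1, 2 * n, byrow = TRUE)
  R <- rfun(TT, PP)
  Xm <- R * sin(TT) * cos(PP)
  Ym <- R * sin(TT) * sin(PP)
  Zm <- R * cos(TT)
  nt <- n + 1
  idx <- function(i, j) (j - 1L) * nt + i          # column-major, phi wraps
  V <- cbind(as.vector(Xm), as.vector(Ym), as.vector(Zm))
  i <- rep(seq_len(n), times = 2 * n)
  j <- rep(seq_len(2 * n), each = n)
  jn <- ifelse(j == 2 * n, 1L, j + 1L)
  f1 <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, jn))
  f2 <- cbind(idx(i, j), idx(i + 1, jn), idx(i, jn))
  F <- rbind(f1, f2)
  tri_area <- function(V, F) {
    aa <- V[F[, 2], ] - V[F[, 1], ]
    bb <- V[F[, 3], ] - V[F[, 1], ]
    cx <- aa[, 2] * bb[, 3] - aa[, 3] * bb[, 2]
    cy <- aa[, 3] * bb[, 1] - aa[, 1] * bb[, 3]
    cz <- aa[, 1] * bb[, 2] - aa[, 2] * bb[, 1]
    sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
  }
  area <- tri_area(V, F)
  hull <- convex_hull_area(V, max_candidates = 6000L)
  # enclosed volume by midpoint quadrature over (theta, phi)
  tm <- (theta[-1] + theta[-(n + 1)]) / 2
  pm <- seq(-pi, pi, length.out = 2 * n + 1)
  pm <- (pm[-1] + pm[-(2 * n + 1)]) / 2
  Rq <- outer(tm, pm, rfun)
  vol <- sum(Rq^3 / 3 * sin(tm)) * (pi / n) * (2 * pi / (2 * n))
  list(area = area, hull_area = hull, gi = area / hull, volume = vol)
}
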