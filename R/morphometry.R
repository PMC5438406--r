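#' Canonical descriptor names
#'
#' The 14 descriptors in their fixed canonical order: gestational age at
#' birth (GA, weeks), the eight relative tissue volumes (CB, mWM, BGT, vCSF,
#' uWM, BS, cGM, eCSF; fractions of intracranial volume), inner cortical
#' surface area (ISA, mm^2), global mean curvature (MC, 1/mm), gyrification
#' index (GI, dimensionless), median cortical thickness (MT, mm) and brain
#' volume (BV, mm^3, the total intracranial volume).
#'
#' @return Character vector of length 14.
#' @export
descriptor_names <- function() {
  c("GA", "CB", "mWM", "BGT", "vCSF", "uWM", "BS", "cGM", "eCSF",
    "ISA", "MC", "GI", "MT", "BV")
}

#' Absolute and relative tissue volumes
#'
#' Counts voxels of each of the eight tissue classes on the native grid and
#' converts to mm^3 using the voxel volume.  The total intracranial volume
#' is the sum over the eight classes; relative volumes are
#' absolute / intracranial.
#'
#' @param vol A [label_volume()].
#' @return A list with `absolute` (named mm^3 per class), `relative`
#'   (named fractions summing to 1) and `icv` (mm^3).
#' @export
tissue_volumes <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  counts <- tabulate(vol$grid, nbins = 8L)
  if (sum(counts) == 0L)
    stop("label volume contains no non-background voxels")
  voxvol <- prod(vol$spacing)
  absolute <- counts * voxvol
  names(absolute) <- tissue_classes()$abbrev
  icv <- sum(absolute)
  list(absolute = absolute, relative = absolute / icv, icv = icv)
}

# classes forming the cerebral interior: uWM, mWM, BGT, vCSF.  Ventricles
# and deep grey are included so that the inner cortical surface does not get
# punctured at the ventricle walls; cerebellum and brain stem are excluded.
interior_classes <- function() c(1L, 2L, 7L, 4L)

# binary interior mask: union of interior classes, largest 6-connected
# component, internal cavities filled
interior_mask <- function(grid, classes = interior_classes()) {
  mask <- array(grid %in% classes, dim(grid))
  if (!any(mask)) stop("empty interior mask: no cerebral interior classes")
  mask <- largest_component(mask)
  fill_holes(mask)
}

largest_component <- function(mask) {
  lab <- cpp_label_components(mask, dim(mask))
  sizes <- tabulate(lab)
  array(lab == which.max(sizes), dim(mask))
}

# fill any background cavity that does not touch the volume border
fill_holes <- function(mask) {
  lab <- cpp_label_components(!mask, dim(mask))
  lab <- array(lab, dim(mask))
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

# nearest-neighbour resampling of a label grid to an isotropic target
# spacing; returns list(grid, spacing)
resample_isotropic <- function(grid, spacing, target = 0.5) {
  if (max(abs(spacing - target)) < 1e-9)
    return(list(grid = grid, spacing = rep(target, 3)))
  d <- dim(grid)
  idx <- lapply(1:3, function(ax) {
    n_new <- max(2L, round(d[ax] * spacing[ax] / target))
    pos <- ((seq_len(n_new)) - 0.5) * target
    pmin(d[ax], pmax(1L, ceiling(pos / spacing[ax])))
  })
  list(grid = grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       spacing = rep(target, 3))
}

# mask (logical array) -> iso-surface of the Gaussian-smoothed indicator at
# level 0.5.  Smoothing the binary indicator before extraction suppresses
# the voxel staircase that would otherwise bias mesh-based area and
# curvature; sigma is in voxels of the (resampled) grid.
mask_surface <- function(mask, spacing, sigma_vox = 1) {
  field <- cpp_gaussian_smooth(array(as.numeric(mask), dim(mask)),
                               dim(mask), rep(sigma_vox, 3))
  surf <- extract_isosurface(field, spacing, level = 0.5)
  if (!is_watertight(surf))
    stop("extracted surface is not watertight after cleaning")
  surf
}

#' Extract the inner cortical surface
#'
#' The inner cortical surface is the closed boundary of the cerebral
#' interior: the largest connected component of
#' unmyelinated + myelinated white matter, basal ganglia/thalami and
#' ventricular CSF, with internal cavities filled.  The label grid is first
#' resampled (nearest neighbour) to an isotropic grid, the binary indicator
#' is smoothed with a small Gaussian, and the level-0.5 iso-surface is
#' extracted as a watertight triangle mesh in mm coordinates.
#'
#' @param vol A [label_volume()].
#' @param resolution Isotropic working resolution in mm (default 0.5).
#' @param sigma Gaussian pre-smoothing of the binary mask, in voxels of the
#'   resampled grid (default 1).
#' @return A [triangle_surface()].
#' @export
extract_inner_surface <- function(vol, resolution = 0.5, sigma = 1) {
  stopifnot(inherits(vol, "label_volume"))
  if (!any(vol$grid == 3L))
    stop("volume contains no cortical grey matter (class 3)")
  rs <- resample_isotropic(vol$grid, vol$spacing, resolution)
  mask <- interior_mask(rs$grid)
  mask_surface(mask, rs$spacing, sigma)
}

#' Extract the outer cortical surface
#'
#' Boundary of the cerebral interior united with cortical grey matter
#' (the pial-side boundary of the cortical ribbon), extracted the same way
#' as [extract_inner_surface()].
#'
#' @inheritParams extract_inner_surface
#' @return A [triangle_surface()].
#' @export
extract_outer_surface <- function(vol, resolution = 0.5, sigma = 1) {
  stopifnot(inherits(vol, "label_volume"))
  rs <- resample_isotropic(vol$grid, vol$spacing, resolution)
  mask <- interior_mask(rs$grid, classes = c(interior_classes(), 3L))
  mask_surface(mask, rs$spacing, sigma)
}

#' Gyrification index
#'
#' Ratio of the surface area to the area of the convex hull of the
#' surface's vertices.  A convex surface has GI of 1 up to mesh
#' discretisation error; folding increases the numerator while leaving the
#' hull nearly unchanged.
#'
#' @param surf A [triangle_surface()] (the inner cortical surface).
#' @param max_candidates Passed to [convex_hull_area()].
#' @return Dimensionless ratio >= 1 - epsilon_mesh.
#' @export
gyrification_index <- function(surf, max_candidates = 6000L) {
  surface_area(surf) / convex_hull_area(surf, max_candidates)
}

#' Global mean curvature
#'
#' Area-weighted average of the signed discrete mean curvature over the
#' vertices of the surface, in 1/mm (positive where the surface is locally
#' convex).  The discrete operator is the cotangent Laplacian (mean
#' curvature normal) with barycentric vertex areas and sign taken against
#' the outward vertex normal; the surface is Laplacian-smoothed first
#' because discrete curvature is noise-dominated on voxelized meshes, and
#' the signed average lets residual mesh noise cancel instead of
#' accumulating.  For a sphere of radius r the value is 1/r.
#'
#' @param surf A [triangle_surface()].
#' @param smooth_iterations Laplacian smoothing passes applied before
#'   curvature estimation (default 10; 0 disables).
#' @param lambda Smoothing step size (default 0.5).
#' @return Global mean curvature in 1/mm.
#' @export
global_mean_curvature <- function(surf, smooth_iterations = 10L,
                                  lambda = 0.5) {
  if (smooth_iterations > 0)
    surf <- smooth_surface(surf, smooth_iterations, lambda)
  mc <- cpp_mean_curvature(surf$vertices, surf$faces)
  sum(mc$H * mc$area) / sum(mc$area)
}

#' Median cortical thickness
#'
#' For every vertex of the inner surface, the Euclidean distance to the
#' nearest vertex of the outer surface; returns the median over inner
#' vertices.  With `symmetric = TRUE` the median of the reverse distances
#' is averaged in.
#'
#' @param inner,outer [triangle_surface()] objects (inner and outer
#'   cortical boundaries).
#' @param symmetric Average the two one-sided medians (default `FALSE`).
#' @return Median thickness in mm.
#' @export
median_cortical_thickness <- function(inner, outer, symmetric = FALSE) {
  if (nrow(inner$vertices) == 0L || nrow(outer$vertices) == 0L)
    stop("empty surface")
  d_io <- RANN::nn2(outer$vertices, inner$vertices, k = 1)$nn.dists[, 1]
  if (!symmetric) return(median(d_io))
  d_oi <- RANN::nn2(inner$vertices, outer$vertices, k = 1)$nn.dists[, 1]
  (median(d_io) + median(d_oi)) / 2
}

#' Compute the full 14-descriptor vector for one label volume
#'
#' Assembles gestational age at birth, the eight relative tissue volumes,
#' the four cortical morphology measures and the total intracranial volume
#' into a single named row.  Volumes are counted on the native grid;
#' surface-based measures use the isotropically resampled grid.
#' Deterministic for fixed input.
#'
#' @param vol A [label_volume()].
#' @param ga_birth Gestational age at birth in weeks.
#' @param resolution,sigma Passed to the surface extraction steps.
#' @return A one-row data frame with the 14 columns of
#'   [descriptor_names()]; the absolute tissue volumes are attached as
#'   attribute `"absolute_volumes"`.
#' @export
compute_descriptors <- function(vol, ga_birth, resolution = 0.5, sigma = 1) {
  tv <- tissue_volumes(vol)
  inner <- extract_inner_surface(vol, resolution, sigma)
  outer <- extract_outer_surface(vol, resolution, sigma)
  out <- data.frame(
    GA = ga_birth,
    CB = tv$relative[["CB"]], mWM = tv$relative[["mWM"]],
    BGT = tv$relative[["BGT"]], vCSF = tv$relative[["vCSF"]],
    uWM = tv$relative[["uWM"]], BS = tv$relative[["BS"]],
    cGM = tv$relative[["cGM"]], eCSF = tv$relative[["eCSF"]],
    ISA = surface_area(inner),
    MC = global_mean_curvature(inner),
    GI = gyrification_index(inner),
    MT = median_cortical_thickness(inner, outer),
    BV = tv$icv
  )
  attr(out, "absolute_volumes") <- tv$absolute
  out
}
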