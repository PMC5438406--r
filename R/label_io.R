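#' Canonical 8-class neonatal tissue code scheme
#'
#' The eight tissue classes of the neonatal segmentation protocol, with the
#' integer codes used throughout the package (0 is background):
#' 1 uWM (unmyelinated white matter), 2 mWM (myelinated white matter),
#' 3 cGM (cortical grey matter), 4 vCSF (ventricular CSF), 5 eCSF
#' (extracerebral CSF), 6 CB (cerebellum), 7 BGT (basal ganglia and
#' thalami), 8 BS (brain stem).  Upstream segmenters using different codes
#' can be accommodated with the `remap` argument of [read_label_volume()].
#'
#' @return A data frame with columns `code`, `abbrev` and `name`.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  data.frame(
    code = 1:8,
    abbrev = c("uWM", "mWM", "cGM", "vCSF", "eCSF", "CB", "BGT", "BS"),
    name = c("unmyelinated white matter", "myelinated white matter",
             "cortical grey matter", "ventricular CSF",
             "extracerebral CSF", "cerebellum",
             "basal ganglia and thalami", "brain stem"),
    stringsAsFactors = FALSE
  )
}

#' Construct a tissue label volume
#'
#' A label volume is a 3-D integer grid of tissue codes in `{0..8}` together
#' with the physical voxel spacing in mm.  Voxel indices are 1-based in R;
#' all geometry downstream is computed in physical mm, with world axes
#' aligned to voxel axes (an affine, when supplied, is carried along as
#' metadata).
#'
#' @param grid 3-D array of integer labels in `{0..8}`.
#' @param spacing Numeric vector of three positive voxel edge lengths (mm).
#'   Anisotropy is permitted (clinical neonatal acquisitions are e.g.
#'   0.34 x 0.34 x 2.0 mm).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing, affine = NULL) {
  if (length(dim(grid)) == 4L && dim(grid)[4] == 1L)
    grid <- array(grid, dim(grid)[1:3])
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array")
  if (any(abs(grid - round(grid)) > 1e-8))
    stop("label volume contains non-integer voxel values")
  grid <- array(as.integer(round(grid)), dim(grid))
  bad <- setdiff(sort(unique(as.vector(grid))), 0:8)
  if (length(bad))
    stop("labels outside the 8-class scheme {0..8}: ",
         paste(bad, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths in mm")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  }
  structure(list(grid = grid, spacing = spacing, affine = affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Tissue label volume:", paste(dim(x$grid), collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  tab <- tabulate(x$grid + 1L, nbins = 9L)
  lab <- c("bg", tissue_classes()$abbrev)
  present <- tab > 0
  cat("Voxels per class:",
      paste(sprintf("%s=%d", lab[present], tab[present]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a tissue label volume from NIfTI
#'
#' Reads a 3-D (or singleton-4th-dimension) NIfTI image of integer tissue
#' labels; voxel spacing is taken from the header.  Labels outside the
#' canonical `{0..8}` scheme are an error unless a remapping table is
#' supplied.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param remap Optional named integer vector mapping foreign codes to
#'   canonical codes, e.g. `c("10" = 1, "20" = 3)`; unmapped canonical codes
#'   pass through.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, remap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D label image, got ", length(dim(arr)), " dimensions")
  if (any(abs(arr - round(arr)) > 1e-6))
    stop("image contains non-integer voxel values; not a label volume")
  arr <- round(arr)
  if (!is.null(remap)) {
    from <- as.integer(names(remap))
    to <- as.integer(remap)
    out <- arr
    for (i in seq_along(from)) out[arr == from[i]] <- to[i]
    arr <- out
  }
  spacing <- RNifti::pixdim(img)[1:3]
  label_volume(arr, spacing)
}

#' Write a tissue label volume to NIfTI
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a subject metadata table
#'
#' Reads a CSV of per-subject metadata.  Mandatory columns are
#' `subject_id` and `ga_birth` (gestational age at birth, weeks); optional
#' columns are `pma_scan_30`, `pma_scan_40` (postmenstrual age at each scan,
#' weeks), `cognitive_score` and `motor_score` (Bayley-III composites).
#' Empty cells become `NA` -- an absent score or scan is represented as
#' missing, never as zero.
#'
#' @param path Path to a delimited text file with a header row.
#' @return A data frame, one row per subject, sorted by `subject_id`.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA", "na"))
  required <- c("subject_id", "ga_birth")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  for (col in c("ga_birth", "pma_scan_30", "pma_scan_40",
                "cognitive_score", "motor_score"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  out_of_range <- !is.na(df$ga_birth) &
    (df$ga_birth < 20 | df$ga_birth > 32)
  if (any(out_of_range))
    warning(sum(out_of_range), " subject(s) with ga_birth outside the ",
            "plausible 20-32 week range")
  df[order(df$subject_id), , drop = FALSE]
}
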