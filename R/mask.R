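#' Binary segmentation mask with physical voxel spacing
#'
#' Container for a 3D binary voxel array together with its voxel spacing in
#' millimetres.  Axis 1 is superior-inferior (the slice direction), axis 2
#' anterior-posterior, axis 3 left-right; [read_mask()] normalizes NIfTI
#' input into this convention.
#'
#' @param voxels 3D array with values in \{0, 1\}.
#' @param spacing_mm numeric triple of strictly positive voxel spacings in
#'   mm, ordered (slice, row, column) = (SI, AP, LR).
#' @return An object of class `segmentation_mask`: a list with elements
#'   `voxels` (integer 3D array) and `spacing_mm`.
#' @export
segmentation_mask <- function(voxels, spacing_mm) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  v <- as.integer(voxels)
  if (anyNA(v) || !all(v == 0L | v == 1L))
    stop("mask voxels must be binary (0/1)", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive values", call. = FALSE)
  structure(
    list(voxels = array(v, dim(voxels)), spacing_mm = spacing_mm),
    class = "segmentation_mask"
  )
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf(
    "<segmentation_mask> %s voxels @ %s mm, %d foreground\n",
    paste(dim(x$voxels), collapse = "x"),
    paste(signif(x$spacing_mm, 4), collapse = "x"),
    sum(x$voxels)
  ))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$voxels)

# Physical coordinates (mm) of the centers of all foreground voxels,
# one row per voxel, columns (SI, AP, LR).  Voxel (i,j,k) is centered at
# ((i,j,k) - 0.5) * spacing.
voxel_coords_mm <- function(mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  sweep(idx - 0.5, 2L, mask$spacing_mm, `*`)
}

stop_if_not_mask <- function(mask) {
  if (!inherits(mask, "segmentation_mask"))
    stop("expected a `segmentation_mask` object", call. = FALSE)
  invisible(mask)
}

warn_if_anisotropic <- function(spacing_mm) {
  inplane <- spacing_mm[c(.AXIS_AP, .AXIS_LR)]
  if (abs(diff(inplane)) > 0.1 * mean(inplane))
    warning(sprintf(
      "in-plane spacing is anisotropic beyond 10%% (%.4g x %.4g mm); the mm-to-pixel radius conversion is ambiguous",
      inplane[1], inplane[2]), call. = FALSE)
  invisible(NULL)
}

#' Read a segmentation mask from a NIfTI file
#'
#' Reads a NIfTI image, reorients it to a canonical anatomical frame using
#' the header's qform/sform, permutes it into the package's (SI, AP, LR)
#' axis order and binarizes it at 0.5 (with a warning when the input was not
#' already binary).  Files carrying no orientation information (both
#' transform codes zero) are rejected rather than guessed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [segmentation_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code == 0L && hdr$qform_code == 0L)
    stop(sprintf("'%s' carries no orientation (qform and sform codes are both 0); cannot normalize axes", path), call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  vals <- arr != 0 & arr != 1
  if (any(vals)) {
    warning(sprintf("'%s' is not binary; thresholding at 0.5", path),
            call. = FALSE)
    arr <- (arr > 0.5) * 1L
  }
  # RAS axes are (LR, PA, IS); permute to internal (SI, AP, LR)
  vox <- aperm(arr, c(3L, 2L, 1L))
  spacing <- sp[c(3L, 2L, 1L)]
  warn_if_anisotropic(spacing)
  segmentation_mask(vox, spacing)
}

#' Write a segmentation mask to a NIfTI file
#'
#' Writes the mask as an unsigned 8-bit NIfTI volume with an RAS sform built
#' from the voxel spacing, so that [read_mask()] round-trips voxels and
#' spacing.
#'
#' @param mask a [segmentation_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stop_if_not_mask(mask)
  arr <- aperm(mask$voxels, c(3L, 2L, 1L))  # back to (LR, AP, SI) = RAS ijk
  sp <- mask$spacing_mm[c(3L, 2L, 1L)]
  img <- RNifti::asNifti(arr, reference = list(
    pixdim = c(-1, sp, 0, 0, 0, 0),
    sform_code = 2L,
    srow_x = c(sp[1], 0, 0, 0),
    srow_y = c(0, sp[2], 0, 0),
    srow_z = c(0, 0, sp[3], 0)
  ))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Resample a binary mask to a target voxel spacing
#'
#' Nearest-neighbour resampling on the voxel-center grid.  Nearest-neighbour
#' interpolation is the only label-preserving choice for binary masks; for
#' large structures it preserves foreground physical volume to within a few
#' percent.
#'
#' @param mask a [segmentation_mask()].
#' @param target_spacing_mm numeric triple of target spacings in mm.
#' @return A [segmentation_mask()] at the target spacing.  When the target
#'   equals the source spacing the voxel array is returned unchanged.
#' @export
resample_mask <- function(mask, target_spacing_mm) {
  stop_if_not_mask(mask)
  target <- as.numeric(target_spacing_mm)
  if (length(target) != 3L || any(target <= 0))
    stop("`target_spacing_mm` must be three strictly positive values",
         call. = FALSE)
  if (isTRUE(all.equal(target, mask$spacing_mm, tolerance = 1e-12)))
    return(segmentation_mask(mask$voxels, target))
  d_old <- dim(mask$voxels)
  extent <- d_old * mask$spacing_mm
  d_new <- pmax(1L, as.integer(round(extent / target)))
  if (any(d_new < 1L)) stop("resampling produced a zero-size grid", call. = FALSE)
  idx <- lapply(1:3, function(a) {
    x <- (seq_len(d_new[a]) - 0.5) * target[a]          # new voxel centers, mm
    i <- floor(x / mask$spacing_mm[a]) + 1L              # containing old voxel
    pmin.int(pmax.int(i, 1L), d_old[a])
  })
  segmentation_mask(mask$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
                    target)
}
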