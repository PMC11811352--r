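#' Angle between two unit tangent vectors
#'
#' The arccosine of the dot product, in degrees, with the dot product
#' clamped to `[-1, 1]` against rounding.
#'
#' @param tp,tq unit 3D vectors (norm within 1e-6 of 1).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
tangent_angle <- function(tp, tq) {
  if (abs(sqrt(sum(tp^2)) - 1) > 1e-6 || abs(sqrt(sum(tq^2)) - 1) > 1e-6)
    stop("tangent vectors must be unit norm (within 1e-6)", call. = FALSE)
  acos(min(1, max(-1, sum(tp * tq)))) * 180 / pi
}

# trimmed sample range: the 5th through 95th of n samples (1-based,
# inclusive), dropping the curve tails that are distorted by incomplete
# vertebral coverage at the volume borders
trim_range <- function(n) {
  lo <- ceiling(0.05 * n)
  hi <- floor(0.95 * n)
  lo:hi
}

#' Build the pairwise tangent-angle map of a sampled curve
#'
#' For samples restricted to the trimmed range (the 5th-95th points of 100,
#' i.e. 91 indices), entry (i, j) is the angle in degrees between tangent i
#' and tangent j.  The map is symmetric with a zero diagonal, and all
#' entries lie in `[0, 180]`.
#'
#' @param samples a `curve_samples` object.
#' @return An object of class `angle_map`: `raw` (matrix, degrees),
#'   `smoothed` (`NULL` until [smooth_angle_map()]), `index_range` (the
#'   sample indices covered).
#' @export
build_angle_map <- function(samples) {
  if (!inherits(samples, "curve_samples")) stop("expected `curve_samples`", call. = FALSE)
  idx <- trim_range(nrow(samples$tangents))
  tg <- samples$tangents[idx, , drop = FALSE]
  g <- tcrossprod(tg)
  g[g > 1] <- 1; g[g < -1] <- -1
  m <- acos(g) * 180 / pi
  m[lower.tri(m)] <- t(m)[lower.tri(m)]  # enforce exact symmetry
  diag(m) <- 0
  structure(list(raw = m, smoothed = NULL, index_range = idx),
            class = "angle_map")
}

#' @export
print.angle_map <- function(x, ...) {
  cat(sprintf("<angle_map> %d x %d (samples %d..%d), max raw %.2f deg%s\n",
              nrow(x$raw), ncol(x$raw), min(x$index_range), max(x$index_range),
              max(x$raw),
              if (is.null(x$smoothed)) "" else
                sprintf(", max smoothed %.2f deg", max(x$smoothed))))
  invisible(x)
}

# 1D reflect-boundary Gaussian smoothing operator as an m x m row-stochastic
# matrix; applied on both sides it performs the separable 2D convolution.
gaussian_reflect_operator <- function(m, sigma) {
  radius <- ceiling(4 * sigma)
  g <- dnorm(-radius:radius, sd = sigma)
  g <- g / sum(g)
  reflect <- function(j) {
    while (j < 1L || j > m) {
      if (j < 1L) j <- 1L - j
      if (j > m) j <- 2L * m + 1L - j
    }
    j
  }
  S <- matrix(0, m, m)
  for (i in seq_len(m))
    for (o in -radius:radius) {
      j <- reflect(i + o)
      S[i, j] <- S[i, j] + g[o + radius + 1L]
    }
  S
}

#' Gaussian smoothing of an angle map
#'
#' Separable 2D Gaussian convolution of the raw map with reflect boundary
#' handling and the kernel truncated at 4 sigma.  Because the kernel
#' weights are a convex combination, the smoothed maximum never exceeds the
#' raw maximum and a constant map is left unchanged.
#'
#' @param map an [build_angle_map()] result.
#' @param sigma Gaussian standard deviation in map-index units (default 2).
#' @return The `angle_map` with its `smoothed` field filled in.
#' @export
smooth_angle_map <- function(map, sigma = 2) {
  if (!inherits(map, "angle_map")) stop("expected an `angle_map`", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  S <- gaussian_reflect_operator(nrow(map$raw), sigma)
  sm <- S %*% map$raw %*% t(S)
  # convexity guarantees smoothed values within the raw range; clamp the
  # ~1e-15 float dust from kernel rows not summing to exactly one
  map$smoothed <- pmin(pmax(sm, min(map$raw)), max(map$raw))
  map
}

#' Predicted 3D Cobb angle of a sampled curve
#'
#' Builds the pairwise tangent-angle map over the trimmed sample range,
#' smooths it with a Gaussian kernel, and returns the maximum of the
#' smoothed map -- the 3D Cobb statistic -- together with the sample-index
#' pair attaining it.
#'
#' @param samples a `curve_samples` object.
#' @param sigma Gaussian sigma in map-index units (default 2).
#' @return An object of class `cobb_result` with `pred_3d_ca` (degrees),
#'   `map_2d_ca` (`NA` here; filled by the pipeline), `argmax_pair`
#'   (sample indices) and the `angle_map`.
#' @export
pred_3d_ca <- function(samples, sigma = 2) {
  map <- smooth_angle_map(build_angle_map(samples), sigma)
  am <- which(map$smoothed == max(map$smoothed), arr.ind = TRUE)[1, ]
  cobb_result(
    pred_3d_ca = max(map$smoothed),
    map_2d_ca = NA_real_,
    argmax_pair = sort(map$index_range[am]),
    angle_map = map
  )
}

#' Coronal-projection 2D Cobb angle of a sampled curve
#'
#' Projects the tangent vectors onto the coronal plane (dropping the
#' anterior-posterior component), renormalizes them, excludes samples whose
#' projected tangent is nearly perpendicular to the plane (projected norm
#' below 1e-3), and returns the maximal pairwise angle over the trimmed
#' range, unsmoothed.
#'
#' @param samples a `curve_samples` object.
#' @return Angle in degrees.  Errors when more than half of the trimmed
#'   samples are excluded (curve mostly sagittal).
#' @export
map_2d_ca <- function(samples) {
  if (!inherits(samples, "curve_samples")) stop("expected `curve_samples`", call. = FALSE)
  idx <- trim_range(nrow(samples$tangents))
  tg <- samples$tangents[idx, c(.AXIS_SI, .AXIS_LR), drop = FALSE]
  nrm <- sqrt(rowSums(tg^2))
  keep <- nrm >= 1e-3
  if (mean(!keep) > 0.5)
    stop("more than 50% of projected tangents are near-perpendicular to the coronal plane; the curve is mostly sagittal",
         call. = FALSE)
  tg <- tg[keep, , drop = FALSE] / nrm[keep]
  g <- tcrossprod(tg)
  g[g > 1] <- 1; g[g < -1] <- -1
  max(acos(g) * 180 / pi)
}

#' Cobb measurement result
#'
#' @param pred_3d_ca 3D Cobb statistic, degrees.
#' @param map_2d_ca coronal-projection statistic, degrees (may be `NA`).
#' @param argmax_pair sample-index pair attaining `pred_3d_ca`.
#' @param angle_map optional `angle_map` the statistic was read from.
#' @return An object of class `cobb_result`.
#' @export
cobb_result <- function(pred_3d_ca, map_2d_ca = NA_real_, argmax_pair = NULL,
                        angle_map = NULL) {
  if (pred_3d_ca < 0 || pred_3d_ca > 180 ||
      (!is.na(map_2d_ca) && (map_2d_ca < 0 || map_2d_ca > 180)))
    stop("Cobb angles must lie in [0, 180] degrees", call. = FALSE)
  structure(list(pred_3d_ca = pred_3d_ca, map_2d_ca = map_2d_ca,
                 argmax_pair = argmax_pair, angle_map = angle_map),
            class = "cobb_result")
}

#' @export
print.cobb_result <- function(x, ...) {
  cat(sprintf("<cobb_result> PRED-3D-CA %.1f deg, MAP-2D-CA %s deg (argmax samples %s)\n",
              x$pred_3d_ca,
              if (is.na(x$map_2d_ca)) "NA" else sprintf("%.1f", x$map_2d_ca),
              paste(x$argmax_pair, collapse = "-")))
  invisible(x)
}
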