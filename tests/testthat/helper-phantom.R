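# Shared phantom settings for the test suite.  Tests run the generator on a
# 1.8 x 0.7 x 0.7 mm grid (a 2x downsampling of the package's clinical
# working grid) to keep volumes small; the geometry in mm is unchanged.
test_spacing <- c(1.8, 0.7, 0.7)

make_test_phantom <- function(cobb_angle_deg, seed = 1, ...) {
  rasterize_phantom(phantom_spec(cobb_angle_deg = cobb_angle_deg,
                                 spacing_mm = test_spacing, seed = seed, ...))
}

test_config <- function(...) {
  pipeline_config(target_spacing_mm = test_spacing, ...)
}

# brute-force maximal pairwise tangent angle (degrees) of a polyline,
# restricted to chords whose midpoint arclength lies in the central 90%
brute_force_max_angle <- function(points, restrict_central = TRUE) {
  ch <- diff(points)
  len <- sqrt(rowSums(ch^2))
  ch <- ch / len
  if (restrict_central) {
    s <- c(0, cumsum(len))
    smid <- (s[-1] + s[-length(s)]) / 2
    keep <- smid >= 0.05 * max(s) & smid <= 0.95 * max(s)
    ch <- ch[keep, , drop = FALSE]
  }
  g <- tcrossprod(ch)
  g[g > 1] <- 1; g[g < -1] <- -1
  max(acos(g)) * 180 / pi
}

# analytic straight-arc-straight curve samples (100 points), bypassing the
# voxel pipeline: the phantom centerline sampled at uniform arclength
analytic_arc_samples <- function(cobb_angle_deg, plane = "coronal",
                                 oblique_tilt_deg = 20, n = 100) {
  spec <- phantom_spec(cobb_angle_deg = cobb_angle_deg, plane = plane,
                       oblique_tilt_deg = oblique_tilt_deg,
                       spacing_mm = test_spacing)
  cl <- make_centerline(spec, n_points = 2001)
  idx <- round(seq(1, nrow(cl$points), length.out = n))
  curve_samples(cl$points[idx, ], cl$tangents[idx, ])
}
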