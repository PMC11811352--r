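#' Specification of a synthetic scoliotic spine phantom
#'
#' Describes a synthetic spine whose centerline is a straight-arc-straight
#' space curve with a known total turning (Cobb) angle.  Vertebral bodies
#' are ellipsoidal blobs strung along the centerline; thin transverse and
#' spinous bars emulate the bony processes that spoke-kernel filtering is
#' designed to remove.  The straight caps each cover 20% of the arclength,
#' so the arc -- and with it the full turning angle -- lies strictly inside
#' the central 90% of the curve and survives the 5th-95th sample trim used
#' by the Cobb statistics.
#'
#' @param cobb_angle_deg total turning angle of the central arc, degrees,
#'   in `[0, 120)`.
#' @param n_vertebrae number of vertebral bodies (>= 2).
#' @param body_radius_mm in-plane radius of each body blob, mm.
#' @param body_height_mm extent of each body along the centerline, mm.
#' @param gap_mm inter-body gap along the centerline, mm (> 0).
#' @param process_thickness_mm square cross-section side of the process
#'   bars, mm; must be smaller than `body_radius_mm`.  Zero disables the
#'   bars entirely (bodies only).
#' @param process_length_mm how far each bar protrudes beyond the body
#'   surface, mm.
#' @param spacing_mm voxel spacing triple (SI, AP, LR), mm.
#' @param plane `"coronal"` keeps the curve in the coronal plane;
#'   `"oblique"` tilts its lateral direction out of that plane by
#'   `oblique_tilt_deg`.
#' @param oblique_tilt_deg tilt of the curve plane about the SI axis,
#'   degrees (used only when `plane = "oblique"`).
#' @param seed integer seed controlling the small random lateral jitter of
#'   body centers; identical spec + seed gives a bit-identical mask.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cobb_angle_deg = 40,
                         n_vertebrae = 12,
                         body_radius_mm = 15,
                         body_height_mm = 22,
                         gap_mm = 6,
                         process_thickness_mm = 4,
                         process_length_mm = 25,
                         spacing_mm = c(0.90, 0.35, 0.35),
                         plane = c("coronal", "oblique"),
                         oblique_tilt_deg = 20,
                         seed = 0) {
  plane <- match.arg(plane)
  if (!is.finite(cobb_angle_deg) || cobb_angle_deg < 0 || cobb_angle_deg >= 120)
    stop("`cobb_angle_deg` must lie in [0, 120): the straight-arc-straight construction assumes the arc turns by less than 120 degrees",
         call. = FALSE)
  if (n_vertebrae < 2) stop("`n_vertebrae` must be >= 2", call. = FALSE)
  if (body_radius_mm <= process_thickness_mm)
    stop("`body_radius_mm` must exceed `process_thickness_mm`", call. = FALSE)
  if (gap_mm <= 0)
    stop(sprintf("`gap_mm` (%.3g) is too small relative to `body_height_mm` (%.3g): bodies would overlap",
                 gap_mm, body_height_mm), call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive values", call. = FALSE)
  structure(list(
    cobb_angle_deg = cobb_angle_deg, n_vertebrae = as.integer(n_vertebrae),
    body_radius_mm = body_radius_mm, body_height_mm = body_height_mm,
    gap_mm = gap_mm, process_thickness_mm = process_thickness_mm,
    process_length_mm = process_length_mm, spacing_mm = spacing_mm,
    plane = plane, oblique_tilt_deg = oblique_tilt_deg,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Arclength of the phantom centerline and the cap/arc breakpoints.  The
# straight caps take 15% of arclength each.  Two pressures set this value.
# The arc should be as long as possible: real scoliotic spines have no
# curvature discontinuities, and the sharper the synthetic curvature jump
# at a cap join, the more any smooth-curve measurement rings around it.
# But each cap must also hold at least two vertebral bodies beyond the
# trimmed tail, because a single body is wider than it is tall and its
# voxel cloud alone cannot pin down the end direction of a fitted curve --
# only body-to-body progression can.  With the default twelve bodies at
# 28 mm pitch, 15% (~50 mm, just under two bodies) is the workable middle.
centerline_geometry <- function(spec) {
  L <- spec$n_vertebrae * (spec$body_height_mm + spec$gap_mm)
  list(L = L, s1 = 0.15 * L, s2 = 0.85 * L)
}

# Evaluate the centerline at arclengths s (vector).  The tangent direction
# angle phi(s), measured from the SI axis within the curve plane, is
#   -theta/2            on the first cap,
#   linear in s         on the arc (constant curvature),
#   +theta/2            on the last cap,
# so the maximal pairwise tangent angle equals theta and is attained between
# the two caps.  Positions integrate cos/sin(phi) in closed form, giving
# exactly collinear points on the caps.
eval_centerline <- function(spec, s) {
  g <- centerline_geometry(spec)
  theta <- spec$cobb_angle_deg * pi / 180
  phi0 <- -theta / 2
  kappa <- if (theta > 0) theta / (g$s2 - g$s1) else 0

  u <- w <- phi <- numeric(length(s))
  # in-plane coordinates: u along SI, w lateral
  u1 <- g$s1 * cos(phi0); w1 <- g$s1 * sin(phi0)
  if (theta > 0) {
    u2 <- u1 + (sin(phi0 + kappa * (g$s2 - g$s1)) - sin(phi0)) / kappa
    w2 <- w1 - (cos(phi0 + kappa * (g$s2 - g$s1)) - cos(phi0)) / kappa
  } else {
    u2 <- u1 + (g$s2 - g$s1); w2 <- w1
  }
  cap1 <- s <= g$s1
  arc  <- s > g$s1 & s < g$s2
  cap2 <- s >= g$s2
  phi[cap1] <- phi0
  phi[arc]  <- phi0 + kappa * (s[arc] - g$s1)
  phi[cap2] <- phi0 + theta
  u[cap1] <- s[cap1] * cos(phi0)
  w[cap1] <- s[cap1] * sin(phi0)
  if (theta > 0) {
    u[arc] <- u1 + (sin(phi[arc]) - sin(phi0)) / kappa
    w[arc] <- w1 - (cos(phi[arc]) - cos(phi0)) / kappa
  } else {
    u[arc] <- u1 + (s[arc] - g$s1)
    w[arc] <- w1
  }
  u[cap2] <- u2 + (s[cap2] - g$s2) * cos(phi0 + theta)
  w[cap2] <- w2 + (s[cap2] - g$s2) * sin(phi0 + theta)

  # embed: lateral direction in (AP, LR) set by the plane choice
  alpha <- if (spec$plane == "oblique") spec$oblique_tilt_deg * pi / 180 else 0
  e_lat <- c(0, sin(alpha), cos(alpha))
  pts <- cbind(u, w * e_lat[2], w * e_lat[3])
  tans <- cbind(cos(phi), sin(phi) * e_lat[2], sin(phi) * e_lat[3])
  colnames(pts) <- colnames(tans) <- c("si", "ap", "lr")
  list(points = pts, tangents = tans, s = s)
}

#' Analytic phantom centerline
#'
#' Returns a dense polyline sampling of the straight-arc-straight phantom
#' centerline together with its analytic tangents and the true maximal
#' pairwise tangent angle over the central 90% of arclength (which equals
#' `cobb_angle_deg` by construction).
#'
#' @param spec a [phantom_spec()].
#' @param n_points number of polyline samples (>= 500).
#' @return A list with `points` (n x 3, mm), `tangents` (n x 3, unit),
#'   `s` (arclength, mm) and `true_max_angle_deg`.
#' @export
make_centerline <- function(spec, n_points = 1001) {
  if (!inherits(spec, "phantom_spec")) stop("expected a `phantom_spec`", call. = FALSE)
  n_points <- max(as.integer(n_points), 500L)
  g <- centerline_geometry(spec)
  out <- eval_centerline(spec, seq(0, g$L, length.out = n_points))
  out$true_max_angle_deg <- spec$cobb_angle_deg
  out
}

#' Rasterize a spine phantom into a binary mask
#'
#' Places `n_vertebrae` ellipsoidal body blobs at equal arclength spacing
#' along the centerline (oriented along the local tangent, with a small
#' seeded lateral jitter), attaches two transverse bars and one spinous bar
#' of square cross-section to each body, and voxelizes everything onto a
#' grid at `spacing_mm`.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_output` with elements `mask`
#'   (a [segmentation_mask()]), `centerline_points` (dense polyline, mm, in
#'   the mask's coordinate frame), `tangents`, `true_max_angle_deg`,
#'   `body_centers_mm` and `spec`.
#' @export
rasterize_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a `phantom_spec`", call. = FALSE)
  g <- centerline_geometry(spec)
  n <- spec$n_vertebrae
  h <- spec$body_height_mm; r <- spec$body_radius_mm
  th <- spec$process_thickness_mm; len <- spec$process_length_mm

  s_centers <- (seq_len(n) - 0.5) * g$L / n
  cl <- eval_centerline(spec, s_centers)
  centers <- cl$points
  tangents <- cl$tangents

  # consecutive bodies must not overlap: centers are body_height + gap apart
  # along the arc; reject if the straight-line distance drops below the
  # body extent
  dmin <- min(sqrt(rowSums((centers[-1, , drop = FALSE] -
                            centers[-n, , drop = FALSE])^2)))
  if (dmin < h)
    stop(sprintf("bodies overlap: center spacing %.2f mm < body_height_mm = %.2f (gap_mm = %.2f too small)",
                 dmin, h, spec$gap_mm), call. = FALSE)

  # Seeded per-body lateral jitter.  The sd is kept at 0.1 mm so that the
  # real turning angle of the jittered body chain stays negligible
  # (~atan(2 * 0.1 / 28) < 0.5 deg) against the declared analytic angle:
  # larger jitter would put genuine curvature into a nominally straight
  # phantom and the declared truth would no longer describe the mask.
  set.seed(spec$seed)
  jitter <- matrix(rnorm(2L * n, sd = 0.1), ncol = 2)  # AP, LR, mm
  centers[, 2] <- centers[, 2] + jitter[, 1]
  centers[, 3] <- centers[, 3] + jitter[, 2]

  # grid: translate so geometry starts at a small margin from the origin
  margin <- 4
  half <- max(h / 2, r) + (if (th > 0) r + len else 0)
  lo <- apply(centers, 2, min) - half - margin
  hi <- apply(centers, 2, max) + half + margin
  centers <- sweep(centers, 2L, lo)
  dense <- eval_centerline(spec, seq(0, g$L, length.out = 1001))
  dense_pts <- sweep(dense$points, 2L, lo)

  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing_mm)))
  vox <- array(0L, dims)
  sp <- spec$spacing_mm
  # voxel indices along `axis` whose centers fall within [c - hw, c + hw]
  ax_range <- function(center, halfwidth, axis) {
    i0 <- max(1L, as.integer(ceiling((center - halfwidth) / sp[axis] + 0.5)))
    i1 <- min(dims[axis], as.integer(floor((center + halfwidth) / sp[axis] + 0.5)))
    if (i0 > i1) integer(0) else i0:i1
  }

  box_half <- sqrt((h / 2)^2 + r^2) + max(sp)  # bounding radius of a tilted ellipsoid
  for (b in seq_len(n)) {
    ctr <- centers[b, ]; tg <- tangents[b, ]
    ir <- ax_range(ctr[1], box_half, 1L)
    jr <- ax_range(ctr[2], box_half, 2L)
    kr <- ax_range(ctr[3], box_half, 3L)
    xi <- (ir - 0.5) * sp[1] - ctr[1]
    xj <- (jr - 0.5) * sp[2] - ctr[2]
    xk <- (kr - 0.5) * sp[3] - ctr[3]
    # local ellipsoid test: (along/h2)^2 + (perp/r)^2 <= 1
    d1 <- rep(xi, times = length(jr) * length(kr))
    d2 <- rep(rep(xj, each = length(ir)), times = length(kr))
    d3 <- rep(xk, each = length(ir) * length(jr))
    along <- d1 * tg[1] + d2 * tg[2] + d3 * tg[3]
    perp2 <- d1^2 + d2^2 + d3^2 - along^2
    inside <- (along / (h / 2))^2 + perp2 / r^2 <= 1
    sub <- array(vox[ir, jr, kr], c(length(ir), length(jr), length(kr)))
    sub[inside] <- 1L
    vox[ir, jr, kr] <- sub

    if (th > 0 && len > 0) {
      reach <- r + len
      # two transverse bars (+/- LR) and one spinous bar (posterior, -AP)
      bars <- list(
        list(jr = ax_range(ctr[2], th / 2, 2L), kr = ax_range(ctr[3] + reach / 2, reach / 2, 3L)),
        list(jr = ax_range(ctr[2], th / 2, 2L), kr = ax_range(ctr[3] - reach / 2, reach / 2, 3L)),
        list(jr = ax_range(ctr[2] - reach / 2, reach / 2, 2L), kr = ax_range(ctr[3], th / 2, 3L))
      )
      ir_b <- ax_range(ctr[1], th / 2, 1L)
      for (bar in bars)
        if (length(ir_b) && length(bar$jr) && length(bar$kr))
          vox[ir_b, bar$jr, bar$kr] <- 1L
    }
  }

  structure(list(
    mask = segmentation_mask(vox, sp),
    centerline_points = dense_pts,
    tangents = dense$tangents,
    s = dense$s,
    true_max_angle_deg = spec$cobb_angle_deg,
    body_centers_mm = centers,
    spec = spec
  ), class = "phantom_output")
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> %d vertebrae, true max tangent angle %.1f deg\n",
              x$spec$n_vertebrae, x$true_max_angle_deg))
  print(x$mask)
  invisible(x)
}

#' Write a phantom mask and its ground-truth sidecar
#'
#' Writes the phantom's mask as NIfTI and a JSON sidecar holding the
#' centerline polyline, the analytic maximal tangent angle and the
#' generating parameters.
#'
#' @param phantom a `phantom_output` from [rasterize_phantom()].
#' @param path output NIfTI path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Invisibly, the sidecar path.
#' @export
write_phantom <- function(phantom, path) {
  write_mask(phantom$mask, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    true_max_angle_deg = phantom$true_max_angle_deg,
    centerline_points_mm = phantom$centerline_points,
    spec = unclass(phantom$spec)
  ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
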