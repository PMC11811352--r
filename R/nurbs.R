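#' NURBS curve container
#'
#' A clamped NURBS curve of degree `degree` with `n` control points, a knot
#' vector of length `n + degree + 1` whose first and last `degree + 1`
#' entries are pinned at 0 and 1, and positive weights.  With unit weights
#' (the fitting default) the curve is an ordinary B-spline; the rational
#' form is kept in the data model so that weights regressed elsewhere can be
#' evaluated with the same machinery.
#'
#' @param ctrlpts n x 3 matrix of control points, mm.
#' @param knots nondecreasing knot vector of length `n + degree + 1`,
#'   clamped at 0 and 1, interior knots strictly inside (0, 1).
#' @param degree spline degree (default 3, cubic).
#' @param weights n positive weights (default all 1).
#' @return An object of class `nurbs_curve`.
#' @export
nurbs_curve <- function(ctrlpts, knots, degree = 3,
                        weights = rep(1, nrow(ctrlpts))) {
  ctrlpts <- as.matrix(ctrlpts)
  if (ncol(ctrlpts) != 3L) stop("`ctrlpts` must be an n x 3 matrix", call. = FALSE)
  n <- nrow(ctrlpts)
  degree <- as.integer(degree)
  if (n < degree + 1L) stop("need at least degree + 1 control points", call. = FALSE)
  knots <- as.numeric(knots)
  if (length(knots) != n + degree + 1L)
    stop(sprintf("knot vector must have length %d (= n + degree + 1)",
                 n + degree + 1L), call. = FALSE)
  if (is.unsorted(knots)) stop("knot vector must be nondecreasing", call. = FALSE)
  if (any(abs(knots[1:(degree + 1L)]) > 1e-12) ||
      any(abs(knots[(n + 1L):(n + degree + 1L)] - 1) > 1e-12))
    stop("knot vector must be clamped: first and last degree + 1 knots at 0 and 1",
         call. = FALSE)
  interior <- knots[(degree + 2L):n]
  if (length(interior) && (any(interior <= 0) || any(interior >= 1)))
    stop("interior knots must lie strictly inside (0, 1)", call. = FALSE)
  weights <- as.numeric(weights)
  if (length(weights) != n || any(weights <= 0))
    stop("`weights` must be n positive values", call. = FALSE)
  structure(list(degree = degree, ctrlpts = unname(ctrlpts), knots = knots,
                 weights = weights),
            class = "nurbs_curve")
}

#' @export
print.nurbs_curve <- function(x, ...) {
  cat(sprintf("<nurbs_curve> degree %d, %d control points, interior knots: %s\n",
              x$degree, nrow(x$ctrlpts),
              paste(signif(interior_knots(x), 4), collapse = ", ")))
  invisible(x)
}

interior_knots <- function(curve) {
  n <- nrow(curve$ctrlpts)
  curve$knots[(curve$degree + 2L):n]
}

#' B-spline basis matrix
#'
#' Evaluates all B-spline basis functions (or a derivative) defined by a
#' clamped knot vector at the given parameter values.  Thin wrapper around
#' [splines::splineDesign()].
#'
#' @param knots full clamped knot vector.
#' @param degree spline degree.
#' @param u parameter values in `[0, 1]`.
#' @param deriv derivative order (0 = value).
#' @return length(u) x n basis matrix.
#' @export
bspline_basis <- function(knots, degree, u, deriv = 0) {
  splines::splineDesign(knots, u, ord = degree + 1L,
                        derivs = rep(as.integer(deriv), length(u)))
}

# normalized superior-inferior parameterization of an axially ordered
# point sequence
axial_params <- function(pts) {
  si <- pts[, 1]
  rng <- range(si)
  if (diff(rng) <= 0)
    stop("degenerate point sequence: no superior-inferior progression; use chord-length parameterization",
         call. = FALSE)
  if (is.unsorted(si))
    stop("axial parameterization requires centroids sorted by increasing superior-inferior coordinate",
         call. = FALSE)
  (si - rng[1]) / diff(rng)
}

# chord-length parameterization of an ordered point sequence
chord_length_params <- function(pts) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate point sequence: zero total chord length", call. = FALSE)
  c(0, cumsum(seg)) / total
}

# Interior knot placement for least-squares approximation with m data
# parameters and n control points of degree p (de Boor-style averaging over
# parameter spans): with d = m / (n - p), interior knot j is the linear
# blend of the two data parameters straddling position j * d.
lsq_knots <- function(params, n_ctrl, degree) {
  m <- length(params)
  n_int <- n_ctrl - degree - 1L
  knots <- c(rep(0, degree + 1L), rep(1, degree + 1L))
  if (n_int > 0L) {
    d <- m / (n_int + 1L)
    interior <- vapply(seq_len(n_int), function(j) {
      i <- floor(j * d)
      alpha <- j * d - i
      (1 - alpha) * params[i] + alpha * params[i + 1L]
    }, numeric(1))
    knots <- c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
  }
  knots
}

#' Fit a cubic NURBS centerline to ordered centroids by least squares
#'
#' Parameterizes the centroids, places interior knots by parameter
#' averaging, and solves for the control points by linear least squares,
#' weighting each centroid by the number of voxels it summarizes (unit
#' NURBS weights, i.e. a nonrational B-spline).  For fixed knots and
#' parameters the solution is the global minimizer of the weighted sum of
#' squared residuals.
#'
#' The default `"axial"` parameterization assigns each centroid a parameter
#' proportional to its superior-inferior coordinate.  K-means centroids of
#' a thick spinal column scatter across the cross-section, so several
#' centroids share nearly the same axial level while differing laterally;
#' axial parameterization treats those as replicate observations of one
#' curve location and lets the least squares average them, whereas
#' chord-length parameterization (also available) follows their lateral
#' zigzag and bends the fitted curve around it.
#'
#' @param clusters a `cluster_set` from [cluster_voxels()], or a plain
#'   k x 3 matrix of ordered points (superior to inferior or vice versa).
#' @param n_ctrlpts number of control points (default 8).
#' @param degree spline degree (default 3).
#' @param parameterization `"axial"` (normalized superior-inferior
#'   coordinate; requires axial monotone ordering) or `"chord"`
#'   (cumulative chord length).
#' @param knots optional full clamped knot vector to impose instead of the
#'   averaged one.
#' @param params optional parameter values (one per centroid, in `[0, 1]`)
#'   to impose instead of the chosen parameterization.
#' @param obs_weights optional nonnegative observation weights, one per
#'   centroid.  When `clusters` is a `cluster_set` these default to the
#'   cluster voxel counts: the clustering step is a computational reduction
#'   of the voxel cloud, and voxel-count weighting makes the centroid fit
#'   the exact sufficient-statistic form of fitting every voxel.  Plain
#'   matrices default to unit weights.
#' @return A [nurbs_curve()].  The fitting parameters, observation weights
#'   and (weighted) residual sum of squares are attached as attribute
#'   `"fit"`.
#' @export
fit_nurbs <- function(clusters, n_ctrlpts = 8, degree = 3,
                      parameterization = c("axial", "chord"), knots = NULL,
                      params = NULL, obs_weights = NULL) {
  is_cluster_set <- inherits(clusters, "cluster_set")
  pts <- if (is_cluster_set) clusters$centroids else as.matrix(clusters)
  parameterization <- match.arg(parameterization)
  n_ctrlpts <- as.integer(n_ctrlpts); degree <- as.integer(degree)
  if (nrow(pts) < n_ctrlpts)
    stop(sprintf("need at least %d ordered centroids to fit %d control points",
                 n_ctrlpts, n_ctrlpts), call. = FALSE)
  if (is.null(obs_weights))
    obs_weights <- if (is_cluster_set && !is.null(clusters$sizes))
      as.numeric(clusters$sizes) else rep(1, nrow(pts))
  if (length(obs_weights) != nrow(pts) || any(obs_weights < 0) ||
      all(obs_weights == 0))
    stop("`obs_weights` must be nonnegative, one per centroid, not all zero",
         call. = FALSE)
  if (is.null(params))
    params <- switch(parameterization,
                     axial = axial_params(pts),
                     chord = chord_length_params(pts))
  if (is.null(knots)) knots <- lsq_knots(params, n_ctrlpts, degree)
  B <- bspline_basis(knots, degree, params)
  sw <- sqrt(obs_weights)
  qrB <- qr(B * sw)
  if (qrB$rank < n_ctrlpts)
    stop("rank-deficient spline design matrix: centroid parameterization is degenerate",
         call. = FALSE)
  ctrl <- qr.coef(qrB, pts * sw)
  rss <- sum(obs_weights * (B %*% ctrl - pts)^2)
  curve <- nurbs_curve(ctrl, knots, degree)
  attr(curve, "fit") <- list(params = params, obs_weights = obs_weights,
                             rss = rss)
  curve
}

#' Evaluate a NURBS curve
#'
#' Rational evaluation of curve points and (optionally) first derivatives
#' at arbitrary parameter values, by the quotient rule on the weighted
#' basis.
#'
#' @param curve a [nurbs_curve()].
#' @param u parameter values in `[0, 1]`.
#' @param derivative if `TRUE`, also return first derivatives.
#' @return A length(u) x 3 matrix of points, or (with `derivative`) a list
#'   `points`, `derivs`.
#' @export
evaluate_curve <- function(curve, u, derivative = FALSE) {
  if (!inherits(curve, "nurbs_curve")) stop("expected a `nurbs_curve`", call. = FALSE)
  B0 <- bspline_basis(curve$knots, curve$degree, u)
  wP <- curve$weights * curve$ctrlpts
  W0 <- as.vector(B0 %*% curve$weights)
  A0 <- B0 %*% wP
  pts <- A0 / W0
  if (!derivative) return(pts)
  B1 <- bspline_basis(curve$knots, curve$degree, u, deriv = 1)
  W1 <- as.vector(B1 %*% curve$weights)
  A1 <- B1 %*% wP
  der <- (A1 * W0 - A0 * W1) / W0^2
  list(points = pts, derivs = der)
}

#' Sample points and unit tangents from a NURBS curve
#'
#' Samples the curve at `n` uniform parameter values in `[0, 1]` and
#' returns the points together with unit tangent vectors (the normalized
#' analytic first derivative).
#'
#' @param curve a [nurbs_curve()].
#' @param n number of samples (default 100).
#' @return An object of class `curve_samples` with `points` (n x 3, mm) and
#'   `tangents` (n x 3, unit norm).
#' @export
sample_curve <- function(curve, n = 100) {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  ev <- evaluate_curve(curve, seq(0, 1, length.out = n), derivative = TRUE)
  nrm <- sqrt(rowSums(ev$derivs^2))
  if (any(nrm < 1e-12))
    stop("degenerate curve: first-derivative norm below 1e-12 at a sample",
         call. = FALSE)
  curve_samples(ev$points, ev$derivs / nrm)
}

#' Construct curve samples
#'
#' @param points n x 3 matrix of curve points, mm.
#' @param tangents n x 3 matrix of unit tangent vectors.
#' @return An object of class `curve_samples`.
#' @export
curve_samples <- function(points, tangents) {
  points <- as.matrix(points); tangents <- as.matrix(tangents)
  if (!identical(dim(points), dim(tangents)) || ncol(points) != 3L)
    stop("`points` and `tangents` must be matching n x 3 matrices", call. = FALSE)
  nrm <- sqrt(rowSums(tangents^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("tangents must be unit vectors (norm within 1e-9 of 1)", call. = FALSE)
  structure(list(points = unname(points), tangents = unname(tangents)),
            class = "curve_samples")
}

#' Normalized control-point and knot loss between two NURBS curves
#'
#' Squared-L2 discrepancy of predicted against ground-truth curve
#' parameters, each term normalized by the ground-truth norm:
#' `|ctrl_gt - ctrl_pred|^2 / |ctrl_gt|^2 + |knot_gt - knot_pred|^2 / |knot_gt|^2`.
#' Because clamped knot vectors pin the first and last `degree + 1` knots at
#' 0 and 1, only the interior knots (the free quartet, for a cubic with 8
#' control points) enter the knot term.
#'
#' @param gt,pred [nurbs_curve()] objects of matching degree and control
#'   point count.
#' @return Nonnegative scalar; 0 iff `pred` equals `gt` in control points
#'   and interior knots.
#' @export
nurbs_param_loss <- function(gt, pred) {
  if (!inherits(gt, "nurbs_curve") || !inherits(pred, "nurbs_curve"))
    stop("expected two `nurbs_curve` objects", call. = FALSE)
  if (gt$degree != pred$degree || nrow(gt$ctrlpts) != nrow(pred$ctrlpts))
    stop("curves must have matching degree and control-point count", call. = FALSE)
  kg <- interior_knots(gt); kp <- interior_knots(pred)
  den_c <- sum(gt$ctrlpts^2); den_k <- sum(kg^2)
  if (den_c <= 0 || den_k <= 0)
    stop("normalization undefined: ground-truth control points or interior knots have zero norm",
         call. = FALSE)
  sum((gt$ctrlpts - pred$ctrlpts)^2) / den_c + sum((kg - kp)^2) / den_k
}

#' Symmetric mean of minimum distance between two sampled curves
#'
#' For each point of one curve, the distance to the nearest point of the
#' other; the two directed mean distances are averaged.
#'
#' @param a,b `curve_samples` objects or n x 3 point matrices.
#' @return Distance in mm (0 for identical point sets); symmetric in its
#'   arguments.
#' @export
curve_distance <- function(a, b) {
  pa <- if (inherits(a, "curve_samples")) a$points else as.matrix(a)
  pb <- if (inherits(b, "curve_samples")) b$points else as.matrix(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) stop("both curves must be nonempty", call. = FALSE)
  # per-coordinate differences (no a^2 + b^2 - 2ab cancellation, so
  # coincident points give exactly zero)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2 +
    outer(pa[, 3], pb[, 3], `-`)^2
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Serialize a NURBS curve to JSON
#'
#' @param curve a [nurbs_curve()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  jsonlite::write_json(curve_payload(curve), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

curve_payload <- function(curve) {
  list(degree = curve$degree, ctrlpts = curve$ctrlpts, knots = curve$knots,
       weights = curve$weights)
}

#' Read a NURBS curve from JSON
#'
#' @param path JSON path written by [write_curve()].
#' @return A [nurbs_curve()].
#' @export
read_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nurbs_curve(x$ctrlpts, x$knots, x$degree, x$weights)
}
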