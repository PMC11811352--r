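# random valid cubic with 8 control points: monotone axial progression,
# random lateral coordinates, random distinct interior knots
random_curve <- function(seed) {
  set.seed(seed)
  si <- sort(runif(8, 0, 300))
  si <- si + seq(0, 70, length.out = 8)         # enforce clear progression
  ctrl <- cbind(si, runif(8, -30, 30), runif(8, -30, 30))
  interior <- sort(runif(4, 0.15, 0.85))
  nurbs_curve(ctrl, c(rep(0, 4), interior, rep(1, 4)))
}

test_that("cluster count follows the one-per-1000-voxels rule on the reference grid", {
  ref <- c(0.90, 0.35, 0.35)
  cube <- function(nvox_side) {
    v <- array(0L, c(nvox_side + 2, 60, 60))
    v[2:(nvox_side + 1), 2:41, 2:41] <- 1L
    segmentation_mask(v, ref)
  }
  m <- cube(8)  # 8 x 40 x 40 = 12800 voxels
  cl <- cluster_voxels(m)
  expect_identical(nrow(cl$centroids), 12L)          # floor(12800 / 1000)
  expect_identical(cl$source_voxel_count, 12800L)
  # centroids inside the foreground bounding box
  bb_lo <- (c(2, 2, 2) - 1) * ref
  bb_hi <- c(9, 41, 41) * ref
  expect_true(all(sweep(cl$centroids, 2, bb_lo, `>=`)))
  expect_true(all(sweep(cl$centroids, 2, bb_hi, `<=`)))
  # sorted by superior-inferior coordinate
  expect_false(is.unsorted(cl$centroids[, 1]))
  # too-small masks are rejected with a pointer at the divisor
  small <- segmentation_mask(array(1L, c(10, 20, 20)), ref)  # 4000 voxels
  expect_error(cluster_voxels(small), "divisor")
})

test_that("the cluster budget is independent of the sampling grid", {
  # same physical slab sampled at two spacings -> same cluster count
  fine <- segmentation_mask(array(1L, c(20, 40, 40)), c(0.90, 0.35, 0.35))
  coarse <- segmentation_mask(array(1L, c(10, 20, 20)), c(1.80, 0.70, 0.70))
  expect_identical(nrow(cluster_voxels(fine)$centroids),
                   nrow(cluster_voxels(coarse)$centroids))
})

test_that("clustering is deterministic under a fixed seed", {
  ph <- make_test_phantom(20, seed = 5, process_length_mm = 0)
  a <- cluster_voxels(ph$mask, seed = 3)
  b <- cluster_voxels(ph$mask, seed = 3)
  expect_identical(a$centroids, b$centroids)
  c <- cluster_voxels(ph$mask, seed = 4)
  expect_false(identical(a$centroids, c$centroids))
})

test_that("centroids of a straight phantom stay inside the column and average onto its axis", {
  ph <- rasterize_phantom(phantom_spec(cobb_angle_deg = 0,
                                       process_length_mm = 0,
                                       spacing_mm = test_spacing, seed = 2))
  cl <- cluster_voxels(ph$mask)
  r <- ph$spec$body_radius_mm
  # individual centroids tile the cross-section, so they scatter up to a
  # body radius laterally -- but never beyond it
  axis_ap_lr <- colMeans(ph$body_centers_mm)[2:3]
  dev <- sqrt((cl$centroids[, 2] - axis_ap_lr[1])^2 +
              (cl$centroids[, 3] - axis_ap_lr[2])^2)
  expect_lt(max(dev), r)
  # the voxel-weighted centroid mean of each body-height band recovers the
  # axis to a small fraction of the radius (this is what the weighted
  # least-squares fit consumes)
  band <- findInterval(cl$centroids[, 1],
                       seq(0, max(cl$centroids[, 1]) + 28, by = 28))
  for (b in unique(band)) {
    i <- band == b
    wm <- c(weighted.mean(cl$centroids[i, 2], cl$sizes[i]),
            weighted.mean(cl$centroids[i, 3], cl$sizes[i]))
    expect_lt(sqrt(sum((wm - axis_ap_lr)^2)), r / 8)
  }
})

test_that("least squares recovers control points exactly for data in the spline space", {
  for (seed in 1:20) {
    cv <- random_curve(seed)
    u <- seq(0, 1, length.out = 200)
    pts <- evaluate_curve(cv, u)
    fit <- fit_nurbs(pts, knots = cv$knots, params = u)
    expect_lt(max(abs(fit$ctrlpts - cv$ctrlpts)), 1e-6)
  }
})

test_that("a straight centroid sequence yields a straight fitted curve", {
  dir <- c(1, 0.2, -0.1) / sqrt(sum(c(1, 0.2, -0.1)^2))
  pts <- outer(seq(0, 280, length.out = 8), dir)
  fit <- fit_nurbs(pts)
  u <- seq(0, 1, length.out = 100)
  ev <- evaluate_curve(fit, u)
  # perpendicular deviation from the line through the endpoints
  rel <- sweep(ev, 2, pts[1, ])
  perp <- rel - outer(as.vector(rel %*% dir), dir)
  expect_lt(max(sqrt(rowSums(perp^2))), 1e-6)
})

test_that("perturbing any fitted control point cannot reduce the residual", {
  ph <- make_test_phantom(40, seed = 1, process_length_mm = 0)
  cl <- cluster_voxels(ph$mask)
  fit <- fit_nurbs(cl)
  info <- attr(fit, "fit")
  B <- bspline_basis(fit$knots, fit$degree, info$params)
  rss <- function(ctrl) sum(info$obs_weights * (B %*% ctrl - cl$centroids)^2)
  base <- rss(fit$ctrlpts)
  expect_equal(base, info$rss, tolerance = 1e-10)
  for (i in seq_len(nrow(fit$ctrlpts))) for (j in 1:3) for (delta in c(-0.1, 0.1)) {
    ctrl <- fit$ctrlpts
    ctrl[i, j] <- ctrl[i, j] + delta
    expect_gte(rss(ctrl), base)
  }
  # and the fitted curve stays within a body radius of the centroids
  fitted <- B %*% fit$ctrlpts
  expect_lt(max(sqrt(rowSums((fitted - cl$centroids)^2))),
            ph$spec$body_radius_mm)
})

test_that("sampling returns unit tangents matching a finite-difference oracle", {
  cv <- random_curve(11)
  s <- sample_curve(cv)                       # default n = 100
  expect_identical(nrow(s$points), 100L)
  expect_true(all(abs(sqrt(rowSums(s$tangents^2)) - 1) < 1e-9))
  h <- 1e-6
  u <- seq(0, 1, length.out = 100)
  for (i in c(2, 25, 50, 75, 99)) {
    fd <- (evaluate_curve(cv, u[i] + h) - evaluate_curve(cv, u[i] - h)) / (2 * h)
    fd <- fd / sqrt(sum(fd^2))
    expect_lt(max(abs(fd - s$tangents[i, ])), 1e-4)
  }
})

test_that("a straight curve has identical tangents; a degenerate curve errors", {
  line <- nurbs_curve(outer(seq(0, 7), c(1, 0, 0)) * 40,
                      c(rep(0, 4), 0.3, 0.5, 0.6, 0.8, rep(1, 4)))
  s <- sample_curve(line)
  expect_lt(max(abs(sweep(s$tangents, 2, s$tangents[1, ]))), 1e-9)
  degenerate <- nurbs_curve(matrix(5, 8, 3),
                            c(rep(0, 4), 0.3, 0.5, 0.6, 0.8, rep(1, 4)))
  expect_error(sample_curve(degenerate), "degenerate")
})

test_that("the normalized parameter loss matches hand-computed values", {
  gt <- nurbs_curve(random_curve(3)$ctrlpts,
                    c(rep(0, 4), 0.2, 0.4, 0.6, 0.8, rep(1, 4)))
  expect_identical(nurbs_param_loss(gt, gt), 0)

  # interior knots differing only in the last one: 0.1^2 / (0.2^2+...+0.8^2)
  pred <- nurbs_curve(gt$ctrlpts, c(rep(0, 4), 0.2, 0.4, 0.6, 0.9, rep(1, 4)))
  expect_equal(nurbs_param_loss(gt, pred), 0.01 / 1.2, tolerance = 1e-9)

  # mismatched shapes rejected
  short <- nurbs_curve(gt$ctrlpts[1:5, ], c(rep(0, 4), 0.5, rep(1, 4)))
  expect_error(nurbs_param_loss(gt, short), "matching")
})

test_that("the loss is nonnegative and zero only at equality", {
  for (seed in 1:5) {
    a <- random_curve(seed)
    b <- random_curve(seed + 100)
    expect_gte(nurbs_param_loss(a, b), 0)
    expect_gt(nurbs_param_loss(a, b), 0)  # random pairs differ
    expect_identical(nurbs_param_loss(a, a), 0)
  }
})

test_that("curve distance is zero at identity, symmetric, and metric-sized for offsets", {
  a <- sample_curve(random_curve(7), 200)
  expect_identical(curve_distance(a, a), 0)
  # two dense parallel straight lines 1 mm apart
  u <- seq(0, 100, length.out = 500)
  la <- cbind(u, 0, 0)
  lb <- cbind(u, 1, 0)
  expect_equal(curve_distance(la, lb), 1, tolerance = 1e-9)
  b <- sample_curve(random_curve(8), 200)
  expect_identical(curve_distance(a, b), curve_distance(b, a))
})

test_that("curves serialize to JSON and back losslessly", {
  cv <- random_curve(21)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_curve(cv, f)
  cv2 <- read_curve(f)
  expect_equal(cv2$ctrlpts, cv$ctrlpts)
  expect_equal(cv2$knots, cv$knots)
  expect_identical(cv2$degree, cv$degree)
})

test_that("malformed curves are rejected", {
  ctrl <- matrix(rnorm(24), 8, 3)
  expect_error(nurbs_curve(ctrl, c(rep(0, 4), 0.5, 0.4, 0.6, 0.8, rep(1, 4))),
               "nondecreasing")
  expect_error(nurbs_curve(ctrl, c(rep(0, 3), 0.1, 0.3, 0.5, 0.6, 0.8, rep(1, 4))),
               "clamped")
  expect_error(nurbs_curve(ctrl, c(rep(0, 4), 0.3, 0.5, 0.8, rep(1, 4))),
               "length")
  expect_error(nurbs_curve(ctrl, c(rep(0, 4), 0.2, 0.4, 0.6, 0.8, rep(1, 4)),
                           weights = rep(0, 8)), "positive")
})
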