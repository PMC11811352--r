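# voxel volume (mm^3) of the reference working grid on which the cluster
# budget is defined: one cluster per `divisor` voxels of 0.90 x 0.35 x 0.35 mm
.REF_VOXEL_MM3 <- 0.90 * 0.35 * 0.35

#' Cluster foreground voxels into centroids for curve fitting
#'
#' Runs K-means on the physical (mm) coordinates of all foreground voxels.
#' The cluster count follows the one-cluster-per-1000-voxels rule stated on
#' the reference 0.90 x 0.35 x 0.35 mm working grid.  So that the budget is
#' independent of the grid the mask happens to be sampled on, it is applied
#' per physical volume: `k = max(n_min, floor(V / (divisor * v_ref)))`,
#' where `V` is the foreground volume in mm^3 and `v_ref` the reference
#' voxel volume.  On the reference grid this is exactly
#' `max(n_min, floor(N / divisor))` with `N` the foreground voxel count.
#' The floor at `n_min` (the control-point count) keeps the downstream
#' least-squares fit determined.  Initialization is k-means++ under a fixed
#' seed, followed by MacQueen K-means iterations, so results are
#' reproducible.
#'
#' @param mask a [segmentation_mask()] (typically after spoke filtering and
#'   small-component removal).
#' @param divisor reference-grid voxels per cluster (default 1000).
#' @param n_min minimum number of clusters (default 8, the control-point
#'   count of the centerline fit).
#' @param seed integer seed for the k-means++ initialization (default 0).
#' @return An object of class `cluster_set`: `centroids` (k x 3 matrix, mm,
#'   sorted by superior-inferior coordinate), `sizes` (voxels per cluster,
#'   used as observation weights by [fit_nurbs()]) and
#'   `source_voxel_count`.
#' @export
cluster_voxels <- function(mask, divisor = 1000, n_min = 8, seed = 0) {
  stop_if_not_mask(mask)
  n <- n_foreground(mask)
  n_equiv <- n * prod(mask$spacing_mm) / .REF_VOXEL_MM3
  if (n_equiv < n_min * divisor)
    stop(sprintf(
      "cluster_voxels: foreground volume %.0f mm^3 supports fewer than %d clusters at %d reference voxels (%.1f mm^3) each; a smaller cluster divisor is needed for masks this small",
      n * prod(mask$spacing_mm), as.integer(n_min), as.integer(divisor),
      divisor * .REF_VOXEL_MM3),
      call. = FALSE)
  k <- max(as.integer(n_min), as.integer(floor(n_equiv / divisor)))
  if (k > n)
    stop("cluster_voxels: more clusters than foreground voxels", call. = FALSE)
  coords <- voxel_coords_mm(mask)

  centers <- kmeanspp_init(coords, k, seed = seed)
  fit <- suppressWarnings(
    stats::kmeans(coords, centers = centers, iter.max = 50L,
                  algorithm = "MacQueen")
  )
  o <- order(fit$centers[, 1])
  centroids <- fit$centers[o, , drop = FALSE]
  dimnames(centroids) <- list(NULL, c("si", "ap", "lr"))
  structure(list(centroids = centroids, sizes = as.integer(fit$size[o]),
                 source_voxel_count = n),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d centroids from %d voxels\n",
              nrow(x$centroids), x$source_voxel_count))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii 2007): the first center is
# drawn uniformly, each further center with probability proportional to the
# squared distance to the nearest already-chosen center.  The scan itself
# runs in C++ on R's RNG stream.
kmeanspp_init <- function(x, k, seed) {
  set.seed(seed)
  kmeanspp_init_cpp(x, as.integer(k))
}

#' Export cluster centroids as CSV
#'
#' @param clusters a `cluster_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(clusters, path) {
  if (!inherits(clusters, "cluster_set")) stop("expected a `cluster_set`", call. = FALSE)
  df <- as.data.frame(clusters$centroids)
  names(df) <- c("si_mm", "ap_mm", "lr_mm")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
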