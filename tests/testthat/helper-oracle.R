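# Naive reference implementation of spoke-kernel filtering, independent of
# the package's C++ path: for every foreground pixel it re-rasterizes each
# diameter with its own Bresenham routine from the translated endpoints and
# applies the both-ends-outside rule, collecting removals and applying them
# once at the end.

oracle_bresenham <- function(x0, y0, x1, y1) {
  # all-quadrant integer midpoint line (classic error-accumulating form,
  # same tie convention as any standard Bresenham: e2 >= dy / e2 <= dx)
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  pts <- matrix(NA_integer_, dx - dy + 1L, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    pts[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(i), , drop = FALSE]
}

oracle_spoke_filter <- function(slice, radius_px) {
  kernel <- build_spoke_kernel(radius_px)
  ends <- lapply(kernel$diameters, `[[`, "endpoints")
  nr <- nrow(slice); nc <- ncol(slice)
  inside_fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
    slice[r, c] != 0
  remove <- matrix(FALSE, nr, nc)
  fg <- which(slice != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    r <- fg[i, 1]; c <- fg[i, 2]
    for (ep in ends) {
      if (inside_fg(r + ep[1, 1], c + ep[1, 2])) next
      if (inside_fg(r + ep[2, 1], c + ep[2, 2])) next
      line <- oracle_bresenham(r + ep[1, 1], c + ep[1, 2],
                               r + ep[2, 1], c + ep[2, 2])
      ok <- line[, 1] >= 1L & line[, 1] <= nr & line[, 2] >= 1L & line[, 2] <= nc
      remove[line[ok, , drop = FALSE]] <- TRUE
    }
  }
  out <- slice
  out[remove] <- 0L
  out
}

# random blobby binary matrix: thresholded sum of a few random rectangles
random_test_mask <- function(nr = 64, nc = 64, n_rect = 6) {
  m <- matrix(0L, nr, nc)
  for (i in seq_len(n_rect)) {
    r0 <- sample.int(nr - 8L, 1); c0 <- sample.int(nc - 8L, 1)
    h <- sample(3:20, 1); w <- sample(3:20, 1)
    m[r0:min(nr, r0 + h), c0:min(nc, c0 + w)] <- 1L
  }
  m
}

# dumbbell fixture: two squares joined by a thin bridge
dumbbell_mask <- function(nr = 200, nc = 200, square = 40, bridge_len = 30,
                          bridge_w = 5) {
  m <- matrix(0L, nr, nc)
  r0 <- (nr - square) %/% 2
  rows <- (r0 + 1):(r0 + square)
  c1 <- 31
  m[rows, c1:(c1 + square - 1)] <- 1L                      # left square
  b0 <- c1 + square
  rb <- (nr - bridge_w) %/% 2
  m[(rb + 1):(rb + bridge_w), b0:(b0 + bridge_len - 1)] <- 1L  # bridge
  m[rows, (b0 + bridge_len):(b0 + bridge_len + square - 1)] <- 1L # right square
  list(mask = m, left = c1:(c1 + square - 1),
       right = (b0 + bridge_len):(b0 + bridge_len + square - 1),
       rows = rows)
}

# 2D 8-connectivity labelling through the package's 3D 26-connectivity
# labeller (a single-slice volume)
label_slice <- function(m) {
  lab <- label_components(segmentation_mask(array(m, c(nrow(m), ncol(m), 1)),
                                            c(1, 1, 1)))
  list(labels = lab$labels[, , 1], counts = lab$counts)
}

# independent midpoint-circle rasterization (second-order difference form)
midpoint_circle_oracle <- function(r) {
  pts <- list()
  x <- r; y <- 0L
  err <- 1L - r
  while (y <= x) {
    pts[[length(pts) + 1L]] <- rbind(
      c(x, y), c(-x, y), c(x, -y), c(-x, -y),
      c(y, x), c(-y, x), c(y, -x), c(-y, -x))
    y <- y + 1L
    if (err < 0L) {
      err <- err + 2L * y + 1L
    } else {
      x <- x - 1L
      err <- err + 2L * (y - x) + 1L
    }
  }
  unique(do.call(rbind, pts))
}
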