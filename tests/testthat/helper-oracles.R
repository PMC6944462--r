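# Independent oracles used across the test suite.  Everything here is
# deliberately written without touching the package's Siddon traversal so
# the two implementations can disagree.

# length of the intersection of segment (x0,y0)-(x1,y1) with the rectangle
# [xl,xh] x [yl,yh] (Liang-Barsky clipping)
seg_rect_len <- function(x0, y0, x1, y1, xl, xh, yl, yh) {
  dx <- x1 - x0
  dy <- y1 - y0
  t0 <- 0
  t1 <- 1
  for (pq in list(c(-dx, x0 - xl), c(dx, xh - x0),
                  c(-dy, y0 - yl), c(dy, yh - y0))) {
    p <- pq[1]
    q <- pq[2]
    if (p == 0) {
      if (q < 0) return(0)
    } else {
      r <- q / p
      if (p < 0) {
        if (r > t1) return(0)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(0)
        if (r < t1) t1 <- r
      }
    }
  }
  if (t1 <= t0) return(0)
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

# dense system matrix by per-pixel rectangle clipping.  Row i corresponds to
# the sinogram entry in column-major order (view fastest), i.e.
# i = v + (e - 1) * n_views, matching as.numeric(sino); column j matches
# as.numeric(image), j = ix + n * iy + 1.
dense_system_matrix <- function(geom) {
  p <- geom$params
  n <- p$image_pixels
  px <- p$pixel_size
  half <- n * px / 2
  nd <- p$n_detector_elements
  V <- geom$n_views
  off <- (seq_len(nd) - 1 - (nd - 1) / 2) * p$detector_element_size
  A <- matrix(0, V * nd, n * n)
  xl <- -half + (seq_len(n) - 1) * px
  for (v in seq_len(V)) {
    x0 <- geom$views[v, "src_x"]; y0 <- geom$views[v, "src_y"]
    for (e in seq_len(nd)) {
      x1 <- geom$views[v, "cen_x"] + off[e] * geom$views[v, "v_x"]
      y1 <- geom$views[v, "cen_y"] + off[e] * geom$views[v, "v_y"]
      i <- v + (e - 1) * V
      for (iy in seq_len(n)) {
        for (ix in seq_len(n)) {
          len <- seg_rect_len(x0, y0, x1, y1, xl[ix], xl[ix] + px,
                              xl[iy], xl[iy] + px)
          if (len > 0) A[i, ix + n * (iy - 1)] <- len
        }
      }
    }
  }
  A
}

# literal doubly-normalized simultaneous update on the dense matrix
dense_sart <- function(A, b, n_iter, beta = 1, f0 = NULL) {
  rs <- rowSums(A)
  cs <- colSums(A)
  f <- if (is.null(f0)) numeric(ncol(A)) else as.numeric(f0)
  for (it in seq_len(n_iter)) {
    r <- as.numeric(b - A %*% f)
    w <- ifelse(rs > 0, r / rs, 0)
    upd <- as.numeric(crossprod(A, w))
    upd <- ifelse(cs > 0, upd / cs, 0)
    f <- f + beta * upd
  }
  f
}

# small geometry used for dense-oracle comparisons
tiny_geometry <- function(n_px = 16, scan_range = 30, n_views = 25,
                          n_det = 24) {
  p <- tct_params(image_pixels = n_px, pixel_size = 353 / n_px,
                  n_views_per_segment = n_views,
                  view_spacing = 30 / n_views,
                  n_detector_elements = n_det,
                  detector_element_size = 800 / n_det)
  build_tct_geometry(p, scan_range)
}

# reduced-view geometry for adjoint tests at a given scan range
small_geometry <- function(scan_range, n_px = 32) {
  p <- tct_params(image_pixels = n_px, pixel_size = 353 / n_px,
                  n_views_per_segment = 10, view_spacing = 3,
                  n_detector_elements = 40, detector_element_size = 20)
  build_tct_geometry(p, scan_range)
}

# disk rasterized with 8x8 subpixel area weighting (anti-aliased), so the
# phantom itself approximates the analytic disk to well under a pixel
aa_disk <- function(n, px, r, cx = 0, cy = 0, ss = 8) {
  xs <- (seq_len(n * ss) - 0.5 - n * ss / 2) * (px / ss)
  X <- matrix(xs, n * ss, n * ss)
  Y <- matrix(xs, n * ss, n * ss, byrow = TRUE)
  fine <- ((X - cx)^2 + (Y - cy)^2 <= r^2) * 1.0
  disk <- matrix(0, n, n)
  for (i in seq_len(ss)) {
    for (j in seq_len(ss)) {
      disk <- disk + fine[seq(i, n * ss, ss), seq(j, n * ss, ss)]
    }
  }
  disk / ss^2
}

# perpendicular ray coordinates relative to a disk centre, computed from
# first principles (source point and ray direction only)
ray_dist_to_point <- function(geom, cx, cy) {
  p <- geom$params
  nd <- p$n_detector_elements
  off <- (seq_len(nd) - 1 - (nd - 1) / 2) * p$detector_element_size
  V <- geom$n_views
  sx <- matrix(geom$views[, "src_x"], V, nd)
  sy <- matrix(geom$views[, "src_y"], V, nd)
  ex <- matrix(geom$views[, "cen_x"], V, nd) + outer(geom$views[, "v_x"], off)
  ey <- matrix(geom$views[, "cen_y"], V, nd) + outer(geom$views[, "v_y"], off)
  dx <- ex - sx
  dy <- ey - sy
  L <- sqrt(dx^2 + dy^2)
  abs((cx - sx) * dy / L - (cy - sy) * dx / L)
}
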