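#' SART reconstruction configuration
#'
#' The simultaneous algebraic reconstruction technique updates every pixel
#' with relaxation-weighted, doubly normalized backprojected residuals:
#' \deqn{f_j^{(n+1)} = f_j^{(n)} + \beta \frac{1}{a_{+j}}
#'       \sum_i \frac{a_{ij}}{a_{i+}} (b_i - A_i f^{(n)})}
#' with relaxation factor `beta = 1` and 2500 sweeps by default.  In
#' `simultaneous` mode (the default, the formula as written) each sweep sums
#' over all M rays at once; `view_sequential` mode performs one sub-update
#' per view in acquisition order, with the normalization sums restricted to
#' that view's rays (the classical SART ordering).
#'
#' @param relax_beta Relaxation factor in (0, 2].
#' @param n_iterations Number of sweeps (>= 0).
#' @param update_mode `"simultaneous"` or `"view_sequential"`.
#' @param nonnegativity Clamp negative pixels to zero after each sweep.
#' @param initial_image Starting image matrix, or `NULL` for zeros.
#' @return An object of class `sart_config`.
#' @export
sart_config <- function(relax_beta = 1,
                        n_iterations = 2500,
                        update_mode = c("simultaneous", "view_sequential"),
                        nonnegativity = FALSE,
                        initial_image = NULL) {
  update_mode <- match.arg(update_mode)
  if (!is.numeric(relax_beta) || relax_beta <= 0 || relax_beta > 2) {
    stop("relax_beta must be in (0, 2]", call. = FALSE)
  }
  if (!is.numeric(n_iterations) || n_iterations < 0 ||
      n_iterations != round(n_iterations)) {
    stop("n_iterations must be a non-negative integer", call. = FALSE)
  }
  structure(list(relax_beta = relax_beta,
                 n_iterations = as.integer(n_iterations),
                 update_mode = update_mode,
                 nonnegativity = isTRUE(nonnegativity),
                 initial_image = initial_image),
            class = "sart_config")
}

#' SART reconstruction from a TCT sinogram
#'
#' Iterates the doubly normalized additive update (see [sart_config()])
#' starting from a zero image (unless `cfg$initial_image` is given).  Rays
#' with zero row sum `a_i+` are skipped; pixels with zero column sum
#' `a_+j` are never touched.  The data-fit residual norm
#' `||A f^(n) - b||` is recorded at every sweep for diagnostics (it is not
#' a stopping rule; the iteration count is fixed).
#'
#' @param sino Sinogram matrix (`n_views x n_detector_elements`).
#' @param geom A `tct_geometry`.
#' @param cfg A [sart_config()].
#' @param op Optional precomputed [projection_operator()] for `geom`
#'   (avoids recomputing the normalization sums across repeated calls).
#' @return A list of class `sart_result`: `image` (reconstruction),
#'   `residuals` (numeric vector of length `n_iterations + 1`; entry `n+1`
#'   is `||A f^(n) - b||` after `n` sweeps, entry 1 the initial residual)
#'   and `config`.
#' @export
sart_reconstruct <- function(sino, geom, cfg = sart_config(), op = NULL) {
  stopifnot(inherits(geom, "tct_geometry"), inherits(cfg, "sart_config"))
  sino <- check_sinogram(sino, geom)
  if (is.null(op)) op <- projection_operator(geom)
  p <- geom$params
  n <- p$image_pixels

  f <- cfg$initial_image
  if (is.null(f)) f <- matrix(0, n, n)
  f <- as_image_matrix(f, geom)

  rs <- op$row_sums
  cs <- op$col_sums
  ray_ok <- !op$zero_rows
  pix_ok <- !op$zero_cols
  rs_safe <- ifelse(ray_ok, rs, 1)
  cs_safe <- ifelse(pix_ok, cs, 1)

  residuals <- numeric(cfg$n_iterations + 1)
  if (cfg$update_mode == "simultaneous") {
    out <- cpp_sart_sweeps(f, unclass(sino), geom$views,
                           seq_len(geom$n_views), p$n_detector_elements,
                           p$detector_element_size, p$pixel_size,
                           cfg$n_iterations, cfg$relax_beta,
                           rs, cs, cfg$nonnegativity)
    f <- out$image
    residuals <- as.numeric(out$residuals)
  } else {
    nd <- p$n_detector_elements
    # per-view column sums (classical SART normalizes within the view)
    ones_row <- matrix(1, 1, nd)
    csv_list <- lapply(seq_len(geom$n_views), function(v) {
      csv <- back_project(ones_row, geom, views = v)
      list(good = csv > 0, safe = ifelse(csv > 0, csv, 1))
    })
    for (it in seq_len(cfg$n_iterations + 1)) {
      r0 <- sino - unclass(forward_project(f, geom))
      residuals[it] <- sqrt(sum(r0[ray_ok]^2))
      if (it > cfg$n_iterations) break
      for (v in seq_len(geom$n_views)) {
        bv <- sino[v, , drop = FALSE]
        av <- unclass(forward_project(f, geom, views = v))
        okv <- ray_ok[v, , drop = FALSE]
        rv <- ifelse(okv, (bv - av) / rs_safe[v, , drop = FALSE], 0)
        upd <- back_project(rv, geom, views = v) / csv_list[[v]]$safe
        upd[!csv_list[[v]]$good] <- 0
        f <- f + cfg$relax_beta * upd
        if (cfg$nonnegativity) f[f < 0] <- 0
      }
    }
  }
  structure(list(image = f, residuals = residuals, config = cfg),
            class = "sart_result")
}

#' FBP reconstruction configuration
#'
#' The TCT rays are rebinned to parallel-beam coordinates (normal angle
#' theta, signed distance s from the rotation axis), ramp-filtered per angle
#' with the Ram-Lak kernel, and backprojected over the covered angles only.
#'
#' @param n_angles Number of angular bins of the rebinning grid; `NULL`
#'   chooses the total number of views of the geometry.
#' @param n_offsets Number of signed-offset bins; `NULL` chooses the number
#'   of detector elements.
#' @param offset_spacing Offset bin width in mm; `NULL` chooses the detector
#'   element size scaled to the isocentre
#'   (`detector_element_size * dist_source_axis / dist_source_detector`).
#' @param filter Reconstruction filter; only `"ram-lak"`.
#' @return An object of class `fbp_config`.
#' @export
fbp_config <- function(n_angles = NULL, n_offsets = NULL,
                       offset_spacing = NULL, filter = "ram-lak") {
  filter <- match.arg(filter, "ram-lak")
  for (f in list(n_angles, n_offsets, offset_spacing)) {
    if (!is.null(f) && (!is.numeric(f) || f <= 0)) {
      stop("fbp_config: grid sizes must be positive", call. = FALSE)
    }
  }
  structure(list(n_angles = n_angles, n_offsets = n_offsets,
                 offset_spacing = offset_spacing, filter = filter),
            class = "fbp_config")
}

# Parallel-beam coordinates of every ray: normal angle theta (radians,
# mapped into a half-turn window centred on the covered range) and signed
# offset s (mm).  A ray along direction phi has normal theta = phi - pi/2
# and s = <source, (cos theta, sin theta)>; (theta + pi, -s) is the same
# line, so theta is folded modulo pi with the sign of s flipped.
ray_parallel_coords <- function(geom) {
  p <- geom$params
  nd <- p$n_detector_elements
  off <- (seq_len(nd) - 1 - (nd - 1) / 2) * p$detector_element_size
  V <- geom$n_views
  src_x <- matrix(geom$views[, "src_x"], V, nd)
  src_y <- matrix(geom$views[, "src_y"], V, nd)
  ex <- matrix(geom$views[, "cen_x"], V, nd) +
    outer(geom$views[, "v_x"], off)
  ey <- matrix(geom$views[, "cen_y"], V, nd) +
    outer(geom$views[, "v_y"], off)
  phi <- atan2(ey - src_y, ex - src_x)
  theta <- phi - pi / 2
  s <- src_x * cos(theta) + src_y * sin(theta)
  # fold into a half-turn window centred on the mean view direction
  ref <- mean(view_angles(geom)) * pi / 180
  k <- round((theta - ref) / pi)
  s <- s * ifelse(k %% 2 == 0, 1, -1)
  theta <- theta - k * pi
  list(theta = theta, s = s)
}

#' Filtered back projection baseline for TCT
#'
#' Rebins the translational fan geometry to parallel-beam coordinates by
#' bilinear scatter accumulation, fills empty bins by interpolation along
#' the offset axis, applies the Ram-Lak ramp filter per angle, and
#' backprojects over the covered angular range only.  With coverage below
#' the classical sufficiency range (180 degrees plus the fan angle) the
#' result shows the usual limited-angle artifacts; the method is provided
#' as the analytic baseline against which SART is compared.
#'
#' @param sino Sinogram matrix (`n_views x n_detector_elements`).
#' @param geom A `tct_geometry`.
#' @param cfg An [fbp_config()].
#' @return A list of class `fbp_result`: `image`, `n_empty_bins` (rebin
#'   cells receiving no ray, filled by interpolation) and `config`.
#' @export
fbp_reconstruct <- function(sino, geom, cfg = fbp_config()) {
  stopifnot(inherits(geom, "tct_geometry"))
  if (!is.null(cfg) && !inherits(cfg, "fbp_config")) {
    stop("cfg must be an fbp_config", call. = FALSE)
  }
  sino <- check_sinogram(sino, geom)
  p <- geom$params

  pc <- ray_parallel_coords(geom)
  n_ang <- if (is.null(cfg$n_angles)) geom$n_views else as.integer(cfg$n_angles)
  n_off <- if (is.null(cfg$n_offsets)) p$n_detector_elements else
    as.integer(cfg$n_offsets)
  ds <- if (is.null(cfg$offset_spacing)) {
    p$detector_element_size * p$dist_source_axis / p$dist_source_detector
  } else cfg$offset_spacing

  th_lo <- min(pc$theta); th_hi <- max(pc$theta)
  # clamp the angular window to a half turn (full-coverage scans fold over)
  if (th_hi - th_lo > pi) { th_hi <- th_lo + pi }
  dth <- (th_hi - th_lo) / max(n_ang - 1, 1)
  thetas <- th_lo + (seq_len(n_ang) - 1) * dth
  s_grid <- (seq_len(n_off) - 1 - (n_off - 1) / 2) * ds

  # fold rays beyond the window back in
  th <- pc$theta; s <- pc$s
  over <- th > th_hi + dth / 2
  th[over] <- th[over] - pi; s[over] <- -s[over]
  under <- th < th_lo - dth / 2
  th[under] <- th[under] + pi; s[under] <- -s[under]

  # bilinear scatter of every ray into the (theta, s) grid
  ta <- (th - th_lo) / dth            # fractional angle index (0-based)
  sa <- (s - s_grid[1]) / ds
  P <- matrix(0, n_ang, n_off)
  Wt <- matrix(0, n_ang, n_off)
  ia0 <- floor(ta); is0 <- floor(sa)
  fa <- ta - ia0; fs <- sa - is0
  val <- as.numeric(sino)
  for (da in 0:1) for (dsb in 0:1) {
    ii <- ia0 + da; jj <- is0 + dsb
    w <- (if (da == 0) 1 - fa else fa) * (if (dsb == 0) 1 - fs else fs)
    keep <- ii >= 0 & ii < n_ang & jj >= 0 & jj < n_off & w > 0
    if (!any(keep)) next
    idx <- ii[keep] + 1 + n_ang * jj[keep]
    P_add <- tapply(w[keep] * val[keep], idx, sum)
    W_add <- tapply(w[keep], idx, sum)
    at <- as.integer(names(P_add))
    P[at] <- P[at] + as.numeric(P_add)
    Wt[at] <- Wt[at] + as.numeric(W_add)
  }
  filled <- Wt > 0
  P[filled] <- P[filled] / Wt[filled]
  n_empty <- sum(!filled)
  if (n_empty > 0) {
    for (a in seq_len(n_ang)) {
      row_ok <- filled[a, ]
      if (!any(row_ok)) { P[a, ] <- 0; next }
      if (all(row_ok)) next
      P[a, !row_ok] <- stats::approx(s_grid[row_ok], P[a, row_ok],
                                     xout = s_grid[!row_ok], rule = 2)$y
    }
  }

  # Ram-Lak: spatial-domain kernel, applied by FFT convolution per angle
  nfft <- 2^ceiling(log2(2 * n_off))
  h <- numeric(nfft)
  k <- c(0:(nfft / 2), (-nfft / 2 + 1):(-1))
  h[k == 0] <- 1 / (4 * ds^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd] * ds)^2
  H <- Re(stats::fft(h))
  Q <- matrix(0, n_ang, n_off)
  for (a in seq_len(n_ang)) {
    row <- c(P[a, ], numeric(nfft - n_off))
    fr <- Re(stats::fft(stats::fft(row) * H, inverse = TRUE)) / nfft
    Q[a, ] <- fr[seq_len(n_off)] * ds
  }

  # backproject over covered angles
  n <- p$image_pixels
  xs <- (seq_len(n) - 0.5 - n / 2) * p$pixel_size
  img <- matrix(0, n, n)
  X <- matrix(xs, n, n)        # first index runs along +x
  Y <- matrix(xs, n, n, byrow = TRUE)
  for (a in seq_len(n_ang)) {
    svals <- X * cos(thetas[a]) + Y * sin(thetas[a])
    z <- stats::approx(s_grid, Q[a, ], xout = as.numeric(svals), rule = 1)$y
    z[is.na(z)] <- 0
    img <- img + matrix(z, n, n)
  }
  img <- img * dth
  structure(list(image = img, n_empty_bins = n_empty, config = cfg),
            class = "fbp_result")
}
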