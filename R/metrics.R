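#' Peak signal-to-noise ratio between a reconstruction and its label
#'
#' `PSNR(x, y) = 10 * log10(max(y)^2 / MSE)` with
#' `MSE = sum((x - y)^2) / N` over all `N` pixels; `y` is the label image
#' and supplies the peak value.  Identical images give `Inf`.
#'
#' @param x Reconstructed image matrix.
#' @param y Label image matrix of the same shape, with `max(y) > 0`.
#' @return PSNR in dB (`Inf` when `x == y` exactly).
#' @export
psnr <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("psnr: shape mismatch", call. = FALSE)
  peak <- max(y)
  if (peak <= 0) stop("psnr: label image must have a positive maximum",
                      call. = FALSE)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity between a reconstruction and its label
#'
#' The single-window (global) SSIM:
#' \deqn{SSIM(x,y) = \frac{(2 \bar x \bar y + C_1)(2 \sigma_{xy} + C_2)}
#'       {(\bar x^2 + \bar y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with means, standard deviations and covariance taken over all pixels
#' (population denominators), `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` and
#' `L = max(y)`.  A windowed variant (11x11 Gaussian, sigma 1.5, mean over
#' windows -- the common reference convention) is available with
#' `windowed = TRUE` for cross-tool comparison.
#'
#' @param x Reconstructed image matrix.
#' @param y Label image matrix of the same shape, with `max(y) > 0`.
#' @param windowed Use the sliding-window variant instead of the global
#'   statistic.
#' @return SSIM value in (-1, 1].
#' @export
ssim <- function(x, y, windowed = FALSE) {
  if (!all(dim(x) == dim(y))) stop("ssim: shape mismatch", call. = FALSE)
  L <- max(y)
  if (L <= 0) stop("ssim: label image must have a positive maximum",
                   call. = FALSE)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  if (!windowed) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  # windowed variant: 11x11 Gaussian window, sigma 1.5
  w <- gaussian_window(11, 1.5)
  mx <- filter2d(x, w); my <- filter2d(y, w)
  sxx <- filter2d(x * x, w) - mx^2
  syy <- filter2d(y * y, w) - my^2
  sxy <- filter2d(x * y, w) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

gaussian_window <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'same'-size 2-D correlation with zero padding
filter2d <- function(img, w) {
  n1 <- nrow(img); n2 <- ncol(img)
  r <- (nrow(w) - 1) / 2
  out <- matrix(0, n1, n2)
  for (di in -r:r) {
    i_src <- max(1, 1 + di):min(n1, n1 + di)
    i_dst <- i_src - di
    for (dj in -r:r) {
      j_src <- max(1, 1 + dj):min(n2, n2 + dj)
      j_dst <- j_src - dj
      out[i_dst, j_dst] <- out[i_dst, j_dst] +
        w[r + 1 + di, r + 1 + dj] * img[i_src, j_src]
    }
  }
  out
}

#' Mean squared error between two images
#' @param x,y Image matrices of the same shape.
#' @return `sum((x - y)^2) / N`.
#' @export
mse <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("mse: shape mismatch", call. = FALSE)
  mean((x - y)^2)
}

#' Image quality report
#'
#' Bundles PSNR, SSIM and MSE for one (reconstruction, label) pair, together
#' with the stabilizing constants used.
#'
#' @param x Reconstructed image matrix.
#' @param y Label image matrix.
#' @return A list of class `metrics_report` with `psnr`, `ssim`, `mse`,
#'   `constants` (C1, C2, L).
#' @export
metrics_report <- function(x, y) {
  L <- max(y)
  structure(list(psnr = psnr(x, y), ssim = ssim(x, y), mse = mse(x, y),
                 constants = list(C1 = (0.01 * L)^2, C2 = (0.03 * L)^2,
                                  L = L)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PSNR %.4f dB   SSIM %.4f   MSE %.6g\n",
              x$psnr, x$ssim, x$mse))
  invisible(x)
}

#' Batch evaluation of reconstructions against labels
#'
#' Emits one row per pair in the layout used for reporting limited-angle
#' results: scanning range, algorithm, PSNR, SSIM.
#'
#' @param recons List of reconstructed image matrices.
#' @param labels List of label image matrices (same length).
#' @param algorithm Character label for the method column.
#' @param scan_range Scanning range in degrees (recycled).
#' @param noise Logical or character noise annotation.
#' @return A data frame with columns `scan_range`, `algorithm`, `noise`,
#'   `item`, `psnr`, `ssim`.
#' @export
evaluate_batch <- function(recons, labels, algorithm, scan_range = NA,
                           noise = FALSE) {
  stopifnot(length(recons) == length(labels))
  data.frame(
    scan_range = scan_range,
    algorithm = algorithm,
    noise = noise,
    item = seq_along(recons),
    psnr = vapply(seq_along(recons),
                  function(i) psnr(recons[[i]], labels[[i]]), numeric(1)),
    ssim = vapply(seq_along(recons),
                  function(i) ssim(recons[[i]], labels[[i]]), numeric(1))
  )
}
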