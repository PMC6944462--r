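#' Write an image or sinogram to 32-bit float TIFF
#'
#' Arrays are stored unscaled as single-precision floats; the Cartesian
#' matrix convention of this package (first index along +x) is transposed to
#' raster row order on write and back on read, so files display upright in
#' external viewers.
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  # raster rows run top-to-bottom: flip y, then put y on rows
  raster <- t(x[, rev(seq_len(ncol(x))), drop = FALSE])
  # float samples store arbitrary values; the [0,1] warning only concerns
  # integer formats
  withCallingHandlers(
    tiff::writeTIFF(raster, path, bits.per.sample = 32, reduce = FALSE),
    warning = function(w) {
      if (grepl("outside the \\[0, 1\\] range", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  raster <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(raster)) == 3) raster <- raster[, , 1]
  x <- t(raster)
  x[, rev(seq_len(ncol(x))), drop = FALSE]
}

#' Map attenuation values to Hounsfield units for display
#'
#' Display-only affine map: the attenuation of water (`mu_water`) maps to
#' 0 HU and zero attenuation to -1000 HU.  Used together with
#' [apply_display_window()] to export 8-bit previews with the conventional
#' soft-tissue window.
#'
#' @param x Attenuation image matrix.
#' @param mu_water Attenuation value corresponding to water.
#' @return Matrix in HU.
#' @export
attenuation_to_hu <- function(x, mu_water = 0.4) {
  1000 * (x - mu_water) / mu_water
}

#' Clamp and scale a HU image into a display window
#'
#' @param hu Matrix in Hounsfield units.
#' @param window Two-element numeric `(lo, hi)`; the default `[800, 1200]`
#'   on an offset scale (HU + 1000) is the soft-tissue window used for the
#'   figures this package's displays mirror.
#' @param offset Added to `hu` before windowing (1000 turns signed HU into
#'   the offset scale of the default window).
#' @return Matrix scaled to `[0, 1]`.
#' @export
apply_display_window <- function(hu, window = c(800, 1200), offset = 1000) {
  z <- (hu + offset - window[1]) / (window[2] - window[1])
  z[z < 0] <- 0
  z[z > 1] <- 1
  z
}

#' Write per-sweep SART residual norms to CSV
#' @param result A `sart_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residuals_csv <- function(result, path) {
  stopifnot(inherits(result, "sart_result"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(sweep = seq_along(result$residuals) - 1L,
                              residual_norm = result$residuals),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a per-epoch loss history to CSV
#' @param model A trained `unet_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loss_csv <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  if (is.null(model$loss_history)) {
    stop("model has no loss history (untrained)", call. = FALSE)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$loss_history, path, row.names = FALSE)
  invisible(path)
}
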