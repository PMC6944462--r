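# Runs code with a private, seeded RNG stream and restores the caller's
# RNG state afterwards, so simulation helpers never perturb user randomness.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

#' Phantom specification
#'
#' Describes a reproducible synthetic attenuation map.  `shepp_logan` is the
#' classical 10-ellipse head phantom (modified contrast values) scaled to the
#' physical field of view.  `random_anatomy` is a torso-like stand-in for the
#' chest/abdomen CT label images the network is meant to learn from: an
#' elliptical body outline of moderate attenuation containing a seeded number
#' of random elliptical internal structures.  No anatomical realism is
#' claimed; the generator exists to produce label images whose limited-angle
#' reconstructions exhibit the characteristic directional artifacts.
#'
#' @param kind `"shepp_logan"` or `"random_anatomy"`.
#' @param n_pixels Image size (square); at least 16.  Default 256.
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @param ellipse_count_range Integer range (min, max) of internal ellipses
#'   for `random_anatomy`.
#' @param intensity_range Attenuation range (arbitrary units) of the internal
#'   structures for `random_anatomy`.
#' @param body_attenuation Baseline attenuation of the body outline.
#' @param pixel_size Pixel size in mm; `NULL` scales so the grid spans the
#'   default 256 * 1.38 mm field of view.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("random_anatomy", "shepp_logan"),
                         n_pixels = 256,
                         seed = 1,
                         ellipse_count_range = c(4L, 10L),
                         intensity_range = c(0.05, 0.9),
                         body_attenuation = 0.4,
                         pixel_size = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n_pixels) || n_pixels < 16) {
    stop("phantom_spec: n_pixels must be >= 16", call. = FALSE)
  }
  if (is.null(pixel_size)) pixel_size <- 256 * 1.38 / n_pixels
  structure(list(kind = kind, n_pixels = as.integer(n_pixels),
                 seed = as.integer(seed),
                 ellipse_count_range = as.integer(ellipse_count_range),
                 intensity_range = intensity_range,
                 body_attenuation = body_attenuation,
                 pixel_size = pixel_size),
            class = "phantom_spec")
}

# classical 10-ellipse phantom, modified contrast values;
# columns: intensity, a, b, x0, y0, angle_deg (unit-square coordinates)
shepp_logan_table <- function() {
  matrix(c(
     1.0, 0.69,   0.92,   0,     0,      0,
    -0.8, 0.6624, 0.8740, 0,    -0.0184, 0,
    -0.2, 0.11,   0.31,   0.22,  0,    -18,
    -0.2, 0.16,   0.41,  -0.22,  0,     18,
     0.1, 0.21,   0.25,   0,     0.35,   0,
     0.1, 0.046,  0.046,  0,     0.1,    0,
     0.1, 0.046,  0.046,  0,    -0.1,    0,
     0.1, 0.046,  0.023, -0.08, -0.605,  0,
     0.1, 0.023,  0.023,  0,    -0.606,  0,
     0.1, 0.023,  0.046,  0.06, -0.605,  0
  ), ncol = 6, byrow = TRUE,
  dimnames = list(NULL, c("val", "a", "b", "x0", "y0", "phi")))
}

# adds `val` inside the rotated ellipse; X, Y are pixel-centre coordinate
# matrices; geometry tested by the analytic membership inequality
add_ellipse <- function(img, X, Y, x0, y0, a, b, phi_deg, val) {
  ph <- phi_deg * pi / 180
  xr <- (X - x0) * cos(ph) + (Y - y0) * sin(ph)
  yr <- -(X - x0) * sin(ph) + (Y - y0) * cos(ph)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  img[inside] <- img[inside] + val
  img
}

#' Generate a synthetic phantom
#'
#' Rasterizes the phantom described by `spec` on its pixel grid: a pixel
#' belongs to an ellipse iff its centre satisfies the analytic membership
#' inequality.  Output values are clipped to be non-negative.  Deterministic:
#' the same spec always yields a bit-identical image.
#'
#' @param spec A [phantom_spec()].
#' @return Square numeric matrix (`n_pixels x n_pixels`) of attenuation
#'   values (arbitrary units), Cartesian orientation (first index along +x).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_pixels
  half <- n * spec$pixel_size / 2
  xs <- (seq_len(n) - 0.5 - n / 2) * spec$pixel_size
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  img <- matrix(0, n, n)

  if (spec$kind == "shepp_logan") {
    tab <- shepp_logan_table()
    for (r in seq_len(nrow(tab))) {
      img <- add_ellipse(img, X, Y,
                         tab[r, "x0"] * half, tab[r, "y0"] * half,
                         tab[r, "a"] * half, tab[r, "b"] * half,
                         tab[r, "phi"], tab[r, "val"])
    }
  } else {
    img <- with_local_seed(spec$seed, {
      # body outline: large ellipse, random eccentricity/tilt
      ba <- stats::runif(1, 0.80, 0.92) * half
      bb <- stats::runif(1, 0.60, 0.85) * half
      bphi <- stats::runif(1, -15, 15)
      im <- add_ellipse(img, X, Y, 0, 0, ba, bb, bphi,
                        spec$body_attenuation)
      body <- im > 0
      k <- sample(seq(spec$ellipse_count_range[1],
                      spec$ellipse_count_range[2]), 1)
      for (i in seq_len(k)) {
        ea <- stats::runif(1, 0.04, 0.28) * half
        eb <- stats::runif(1, 0.04, 0.28) * half
        ex <- stats::runif(1, -0.55, 0.55) * half
        ey <- stats::runif(1, -0.45, 0.45) * half
        ephi <- stats::runif(1, 0, 180)
        val <- stats::runif(1, spec$intensity_range[1],
                            spec$intensity_range[2])
        mask <- matrix(FALSE, n, n)
        mask <- add_ellipse(mask * 0, X, Y, ex, ey, ea, eb, ephi, 1) > 0
        sel <- mask & body
        im[sel] <- val            # structures overwrite, only inside body
      }
      im
    })
  }
  img[img < 0] <- 0
  img
}

#' Gaussian projection-noise model
#'
#' Additive Gaussian noise applied to the line-integral (post-log)
#' projection data, with mean 0 and absolute variance 10 by default.
#'
#' @param mean Noise mean, in projection units (mm times attenuation).
#' @param variance Noise variance (>= 0), in squared projection units.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mean = 0, variance = 10, seed = 1) {
  if (!is.numeric(variance) || variance < 0) {
    stop("noise_model: variance must be >= 0", call. = FALSE)
  }
  structure(list(mean = mean, variance = variance, seed = as.integer(seed)),
            class = "noise_model")
}

#' Add Gaussian noise to a sinogram
#'
#' Returns `sino + e` with `e ~ N(mean, variance)` i.i.d. per entry, drawn
#' from the model's seeded stream.  The input is not modified and the
#' caller's RNG state is untouched.
#'
#' @param sino Sinogram matrix.
#' @param noise A [noise_model()].
#' @return Noisy sinogram of the same shape and class.
#' @export
add_gaussian_noise <- function(sino, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$variance == 0 && noise$mean == 0) return(sino)
  e <- with_local_seed(noise$seed, {
    stats::rnorm(length(sino), mean = noise$mean,
                 sd = sqrt(noise$variance))
  })
  sino + matrix(e, nrow(sino), ncol(sino))
}

#' Build a training/testing dataset of (SART reconstruction, label) pairs
#'
#' For each item: generate a phantom label, forward project it under the
#' limited-angle geometry, optionally add Gaussian projection noise, run
#' SART, and pair the SART image (network input) with the phantom (label).
#' Train and test items draw phantom seeds from disjoint streams derived
#' from `master_seed`, so no phantom can appear in both splits.  The
#' paper-scale configuration is 450 training and 50 testing pairs at
#' 256 x 256; the desk-scale default used throughout the package tests is
#' (20, 5) at 64 x 64 with reduced SART sweeps.
#'
#' @param n_train,n_test Number of pairs per split (>= 1).
#' @param geom A `tct_geometry` (its grid fixes the image size).
#' @param noise A [noise_model()] or `NULL` for noiseless data.
#' @param sart_cfg A [sart_config()].
#' @param master_seed Integer; all per-item seeds derive from it.
#' @param phantom_kind Passed to [phantom_spec()].
#' @return A list of class `tct_dataset` with `train` and `test` lists of
#'   pairs (`input`, `label`, `provenance`) plus `geometry`, `sart_config`,
#'   `noise`, `master_seed`.
#' @export
build_dataset <- function(n_train, n_test, geom, noise = NULL,
                          sart_cfg = sart_config(n_iterations = 300),
                          master_seed = 1,
                          phantom_kind = "random_anatomy") {
  stopifnot(inherits(geom, "tct_geometry"))
  if (n_train < 1 || n_test < 1) {
    stop("build_dataset: counts must be >= 1", call. = FALSE)
  }
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_model"))
  op <- projection_operator(geom)
  n_px <- geom$params$image_pixels

  make_split <- function(count, offset) {
    lapply(seq_len(count), function(i) {
      sd_phantom <- (as.numeric(master_seed) * 1009 + offset + i) %%
        2000000011
      spec <- phantom_spec(kind = phantom_kind, n_pixels = n_px,
                           seed = sd_phantom,
                           pixel_size = geom$params$pixel_size)
      label <- make_phantom(spec)
      sino <- forward_project(label, geom)
      if (!is.null(noise)) {
        nm <- noise_model(noise$mean, noise$variance,
                          seed = (as.numeric(noise$seed) * 7919 + offset +
                                    i) %% 2000000011)
        sino <- add_gaussian_noise(sino, nm)
      }
      rec <- sart_reconstruct(sino, geom, sart_cfg, op = op)
      list(input = rec$image, label = label,
           provenance = list(phantom_seed = sd_phantom,
                             scan_range = geom$scan_range,
                             noise = noise,
                             sart = sart_cfg[c("relax_beta", "n_iterations",
                                               "update_mode")]))
    })
  }
  structure(list(train = make_split(n_train, 0L),
                 test = make_split(n_test, 1000000L),
                 geometry = geom,
                 sart_config = sart_cfg,
                 noise = noise,
                 master_seed = master_seed),
            class = "tct_dataset")
}

#' Save / load a dataset archive
#'
#' The archive is an `.rds` file with a YAML provenance sidecar
#' (`<path>.yaml`) recording the geometry, SART configuration, noise model
#' and master seed needed to regenerate the archive bit-identically.
#'
#' @param dataset A `tct_dataset` from [build_dataset()].
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "tct_dataset"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset, path)
  side <- list(
    n_train = length(dataset$train),
    n_test = length(dataset$test),
    master_seed = dataset$master_seed,
    scan_range_deg = dataset$geometry$scan_range,
    sart = dataset$sart_config[c("relax_beta", "n_iterations",
                                 "update_mode")],
    noise = if (is.null(dataset$noise)) "none" else
      dataset$noise[c("mean", "variance", "seed")]
  )
  writeLines(yaml::as.yaml(side), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "tct_dataset"))
  ds
}
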