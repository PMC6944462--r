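#' @useDynLib tctrecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

as_image_matrix <- function(image, geom) {
  if (is.list(image) && !is.null(image$values)) image <- image$values
  n <- geom$params$image_pixels
  if (!is.matrix(image) || nrow(image) != n || ncol(image) != n) {
    stop("image must be a ", n, " x ", n,
         " matrix matching the geometry's grid", call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  image
}

check_sinogram <- function(sino, geom, n_views = geom$n_views) {
  if (is.list(sino) && !is.null(sino$values)) sino <- sino$values
  if (!is.matrix(sino) || nrow(sino) != n_views ||
      ncol(sino) != geom$params$n_detector_elements) {
    stop("sinogram must be a ", n_views, " x ",
         geom$params$n_detector_elements,
         " matrix matching the geometry", call. = FALSE)
  }
  if (!all(is.finite(sino))) {
    stop("sinogram contains non-finite values", call. = FALSE)
  }
  sino
}

#' Forward projection (line integrals) of an image under a TCT geometry
#'
#' Computes the sinogram `b = A x` where `a_ij` is the exact intersection
#' length (mm) of ray `i` with pixel `j`, found by Siddon traversal of the
#' pixel grid.  One ray per detector element runs from the source point to
#' the element centre.  The operator is matrix-free and shares its weight
#' enumeration with [back_project()], so the pair is exactly adjoint.
#'
#' The image matrix convention is Cartesian: the first index runs along +x
#' and the second along +y, with pixel `(i, j)` (1-based) centred at
#' `((i - 1/2 - n/2) * px, (j - 1/2 - n/2) * px)` relative to the rotation
#' axis.
#'
#' @param image Square numeric matrix of size `image_pixels`, attenuation in
#'   1/mm (or arbitrary units; the sinogram is then in those units times mm).
#' @param geom A `tct_geometry` from [build_tct_geometry()].
#' @param views Optional integer vector of view indices to project (defaults
#'   to all views).
#' @return Numeric matrix `length(views) x n_detector_elements` of line
#'   integrals, with class attribute `tct_sinogram`.
#' @export
forward_project <- function(image, geom, views = seq_len(geom$n_views)) {
  stopifnot(inherits(geom, "tct_geometry"))
  image <- as_image_matrix(image, geom)
  p <- geom$params
  sino <- cpp_forward_project(image, geom$views, as.integer(views),
                              p$n_detector_elements, p$detector_element_size,
                              p$pixel_size)
  structure(sino, class = c("tct_sinogram", class(sino)))
}

#' Unnormalized backprojection (adjoint of the forward projector)
#'
#' Computes the image `A' g`, i.e. pixel `j` receives
#' `sum_i a_ij * g_i` with the identical intersection lengths `a_ij` used by
#' [forward_project()].
#'
#' @param sino Numeric matrix `length(views) x n_detector_elements`.
#' @param geom A `tct_geometry`.
#' @param views Optional integer vector of view indices corresponding to the
#'   rows of `sino` (defaults to all views).
#' @return Square image matrix of size `image_pixels`.
#' @export
back_project <- function(sino, geom, views = seq_len(geom$n_views)) {
  stopifnot(inherits(geom, "tct_geometry"))
  sino <- check_sinogram(sino, geom, n_views = length(views))
  p <- geom$params
  cpp_back_project(unclass(sino), geom$views, as.integer(views),
                   p$n_detector_elements, p$detector_element_size,
                   p$image_pixels, p$pixel_size)
}

#' SART normalization sums of the projection operator
#'
#' Row sums `a_i+ = sum_j a_ij` (one per ray; equal to the forward
#' projection of an all-ones image) and column sums `a_+j = sum_i a_ij`
#' (one per pixel; equal to the backprojection of an all-ones sinogram).
#' Rays that miss the image square have `a_i+ = 0` and are excluded from
#' SART updates; pixels crossed by no ray have `a_+j = 0` and are never
#' updated.
#'
#' @param geom A `tct_geometry`.
#' @return A list with `row_sums` (`n_views x n_detector_elements` matrix),
#'   `col_sums` (image-sized matrix), and logical masks `zero_rows`,
#'   `zero_cols` flagging the excluded sets.
#' @export
normalization_sums <- function(geom) {
  stopifnot(inherits(geom, "tct_geometry"))
  n <- geom$params$image_pixels
  ones_img <- matrix(1, n, n)
  row_sums <- unclass(forward_project(ones_img, geom))
  ones_sino <- matrix(1, geom$n_views, geom$params$n_detector_elements)
  col_sums <- back_project(ones_sino, geom)
  list(row_sums = row_sums,
       col_sums = col_sums,
       zero_rows = row_sums == 0,
       zero_cols = col_sums == 0)
}

#' Matrix-free projection operator bundle
#'
#' Packages forward projection, adjoint backprojection and the SART
#' normalization sums over a fixed geometry into one object, computing the
#' sums once.
#'
#' @param geom A `tct_geometry`.
#' @return A list with functions `apply(image)`, `apply_adjoint(sino)` and
#'   precomputed `row_sums`, `col_sums`, `zero_rows`, `zero_cols`, plus the
#'   `geometry` itself.
#' @export
projection_operator <- function(geom) {
  stopifnot(inherits(geom, "tct_geometry"))
  sums <- normalization_sums(geom)
  list(geometry = geom,
       apply = function(image) forward_project(image, geom),
       apply_adjoint = function(sino) back_project(sino, geom),
       row_sums = sums$row_sums,
       col_sums = sums$col_sums,
       zero_rows = sums$zero_rows,
       zero_cols = sums$zero_cols)
}
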