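#' Geometrical parameters of a translational CT (TCT) system
#'
#' The TCT scanner translates the X-ray source and a flat-panel detector
#' linearly in opposite directions on either side of a stationary object,
#' then is manually rotated by one segment span (30 degrees by default) and
#' the translation is repeated.  The defaults reproduce the simulated system
#' this package targets: source-detector distance 1300 mm, source-axis
#' distance 900 mm, 207 source positions per 30-degree segment sampled every
#' 0.145 degrees, an 800-element flat panel with 1 mm elements, and a
#' 256 x 256 image grid with 1.38 mm pixels.
#'
#' @param dist_source_detector Source-to-detector distance in mm.
#' @param dist_source_axis Source-to-rotation-axis distance in mm; must be
#'   smaller than `dist_source_detector`.
#' @param view_spacing Angular sampling interval between adjacent views, in
#'   degrees.
#' @param segment_span Angular span of one translation segment, in degrees.
#' @param n_views_per_segment Number of source positions (views) per segment.
#' @param n_detector_elements Number of detector elements on the flat panel.
#' @param detector_element_size Size of one detector element, in mm.
#' @param image_pixels Number of pixels along each side of the square
#'   reconstruction grid.
#' @param pixel_size Pixel size in mm.
#' @param fov_diameter Diameter of the field of view in mm; metadata only,
#'   recorded for traceability and never used in any computation.
#'
#' @return An object of class `tct_params`.
#' @seealso [build_tct_geometry()], [desk_params()]
#' @export
#' @examples
#' p <- tct_params()
#' p$n_views_per_segment
tct_params <- function(dist_source_detector = 1300,
                       dist_source_axis = 900,
                       view_spacing = 0.145,
                       segment_span = 30,
                       n_views_per_segment = 207,
                       n_detector_elements = 800,
                       detector_element_size = 1,
                       image_pixels = 256,
                       pixel_size = 1.38,
                       fov_diameter = 352.90) {
  p <- list(dist_source_detector = dist_source_detector,
            dist_source_axis = dist_source_axis,
            view_spacing = view_spacing,
            segment_span = segment_span,
            n_views_per_segment = as.integer(n_views_per_segment),
            n_detector_elements = as.integer(n_detector_elements),
            detector_element_size = detector_element_size,
            image_pixels = as.integer(image_pixels),
            pixel_size = pixel_size,
            fov_diameter = fov_diameter)
  validate_tct_params(p)
  structure(p, class = "tct_params")
}

validate_tct_params <- function(p) {
  num <- c("dist_source_detector", "dist_source_axis", "view_spacing",
           "segment_span", "detector_element_size", "pixel_size")
  cnt <- c("n_views_per_segment", "n_detector_elements", "image_pixels")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("tct_params: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  for (f in cnt) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 1 || p[[f]] != round(p[[f]])) {
      stop("tct_params: `", f, "` must be a positive integer", call. = FALSE)
    }
  }
  if (p$dist_source_axis >= p$dist_source_detector) {
    stop("tct_params: dist_source_axis must be < dist_source_detector",
         call. = FALSE)
  }
  if ((p$n_views_per_segment - 1) * p$view_spacing > p$segment_span + 1e-9) {
    stop("tct_params: (n_views_per_segment - 1) * view_spacing exceeds ",
         "segment_span", call. = FALSE)
  }
  invisible(p)
}

#' Desk-scale TCT parameters
#'
#' A reduced version of the default geometry for CPU-scale experiments:
#' a 64 x 64 grid covering the same ~353 mm field of view, 52 views per
#' segment and a 200-element detector.  The physical distances and the
#' 30-degree segment span are unchanged, so the desk geometry is a coarser
#' sampling of the same scanner, not a different scanner.
#'
#' @param image_pixels Grid size; the pixel size scales to keep the field of
#'   view fixed at 256 * 1.38 mm.
#' @param n_views_per_segment Views per segment.
#' @param n_detector_elements Detector elements.
#' @return A `tct_params` object.
#' @export
desk_params <- function(image_pixels = 64,
                        n_views_per_segment = 52,
                        n_detector_elements = 200) {
  tct_params(
    view_spacing = 30 / n_views_per_segment,
    n_views_per_segment = n_views_per_segment,
    n_detector_elements = n_detector_elements,
    detector_element_size = 800 / n_detector_elements,
    image_pixels = image_pixels,
    pixel_size = 256 * 1.38 / image_pixels
  )
}

#' Build the limited-angle TCT scanning geometry
#'
#' Constructs every source position and detector-element position for a scan
#' covering `scan_range` degrees in segments of `params$segment_span`.
#' Within a segment the source translates along a line at distance
#' `dist_source_axis` from the rotation axis while the detector panel
#' translates in the opposite direction along a parallel line at distance
#' `dist_source_detector - dist_source_axis`; for each view the panel is
#' centred where the source-axis line meets the detector line, so the
#' central ray of every view passes through the rotation axis.  Segment `m`
#' (0-based) is segment 0 rotated rigidly about the axis by
#' `m * segment_span` degrees; segment `m`'s central view direction sits at
#' `m * segment_span + segment_span/2` degrees.
#'
#' Within segment 0 the view at offset angle `gamma` (running from
#' `-span/2` to `+span/2` with `span = (n_views - 1) * view_spacing`) has
#' its source at `(R_s * tan(gamma), R_s)` in the segment frame, where
#' `R_s = dist_source_axis`, and the detector elements are laid out along
#' the translation line at `detector_element_size` spacing.
#'
#' @param params A [tct_params()] object.
#' @param scan_range Total nominal angular coverage in degrees; must be a
#'   positive integer multiple of `params$segment_span` (90, 120 and 150 are
#'   the standard limited-angle ranges).
#' @return An object of class `tct_geometry` with elements `params`,
#'   `scan_range`, `n_segments`, `n_views`, `n_rays` (total ray count M),
#'   `segment` (segment index per view), `gamma` (in-segment offset angle per
#'   view, degrees), and `views`, a `n_views x 6` matrix with columns
#'   `src_x, src_y, cen_x, cen_y, v_x, v_y`: source point, detector-array
#'   centre and the unit vector along the detector array (mm).
#' @export
#' @examples
#' g <- build_tct_geometry(desk_params(), scan_range = 120)
#' g$n_segments
build_tct_geometry <- function(params, scan_range) {
  stopifnot(inherits(params, "tct_params"))
  validate_tct_params(params)
  if (!is.numeric(scan_range) || length(scan_range) != 1 ||
      scan_range <= 0 ||
      abs(scan_range / params$segment_span -
          round(scan_range / params$segment_span)) > 1e-9) {
    stop("scan_range must be a positive integer multiple of segment_span (",
         params$segment_span, " deg)", call. = FALSE)
  }
  n_seg <- as.integer(round(scan_range / params$segment_span))
  nv <- params$n_views_per_segment
  span <- (nv - 1) * params$view_spacing
  gamma0 <- -span / 2 + (seq_len(nv) - 1) * params$view_spacing  # degrees

  Rs <- params$dist_source_axis
  Rd <- params$dist_source_detector - params$dist_source_axis

  n_views <- n_seg * nv
  views <- matrix(0, n_views, 6,
                  dimnames = list(NULL, c("src_x", "src_y", "cen_x", "cen_y",
                                          "v_x", "v_y")))
  segment <- integer(n_views)
  gamma <- numeric(n_views)
  for (m in seq_len(n_seg) - 1L) {
    # central direction of segment m in the global frame
    A <- (m + 0.5) * params$segment_span
    u <- c(cos(A * pi / 180), sin(A * pi / 180))   # axis -> source direction
    v <- c(-u[2], u[1])                            # translation direction
    tg <- tan(gamma0 * pi / 180)
    rows <- m * nv + seq_len(nv)
    views[rows, "src_x"] <- Rs * u[1] + Rs * tg * v[1]
    views[rows, "src_y"] <- Rs * u[2] + Rs * tg * v[2]
    views[rows, "cen_x"] <- -Rd * u[1] - Rd * tg * v[1]
    views[rows, "cen_y"] <- -Rd * u[2] - Rd * tg * v[2]
    views[rows, "v_x"] <- v[1]
    views[rows, "v_y"] <- v[2]
    segment[rows] <- m
    gamma[rows] <- gamma0
  }
  structure(list(params = params,
                 scan_range = scan_range,
                 n_segments = n_seg,
                 n_views = n_views,
                 n_rays = n_views * params$n_detector_elements,
                 segment = segment,
                 gamma = gamma,
                 views = views),
            class = "tct_geometry")
}

#' View angles of a TCT geometry
#'
#' For each view, the angle (degrees, global frame) of the source-axis line,
#' i.e. the direction from the rotation axis to the source.  Within a
#' segment the angles increase strictly by `view_spacing`; the central view
#' of segment `m` sits at `m * segment_span + segment_span / 2`.
#'
#' @param geom A `tct_geometry`.
#' @return Numeric vector of length `geom$n_views`.
#' @export
view_angles <- function(geom) {
  stopifnot(inherits(geom, "tct_geometry"))
  (geom$segment + 0.5) * geom$params$segment_span + geom$gamma
}

#' @export
print.tct_geometry <- function(x, ...) {
  cat("TCT scanning geometry\n")
  cat("  scan range  :", x$scan_range, "deg in", x$n_segments,
      "segments of", x$params$segment_span, "deg\n")
  cat("  views       :", x$n_views, "(", x$params$n_views_per_segment,
      "per segment, spacing", x$params$view_spacing, "deg )\n")
  cat("  detector    :", x$params$n_detector_elements, "elements x",
      x$params$detector_element_size, "mm\n")
  cat("  rays (M)    :", x$n_rays, "\n")
  cat("  image grid  :", x$params$image_pixels, "x", x$params$image_pixels,
      "px of", x$params$pixel_size, "mm\n")
  invisible(x)
}

#' Serialize TCT geometry parameters to a YAML configuration
#'
#' Writes (or returns) a human-readable YAML block echoing the scanner
#' parameter names used throughout this package, for provenance alongside
#' exported sinograms and reconstructions.
#'
#' @param geom A `tct_geometry`.
#' @param file Optional path; if `NULL` the YAML string is returned.
#' @return The YAML string, invisibly when written to `file`.
#' @export
geometry_to_yaml <- function(geom, file = NULL) {
  stopifnot(inherits(geom, "tct_geometry"))
  p <- geom$params
  cfg <- list(
    scan_range_deg = geom$scan_range,
    distance_source_detector_mm = p$dist_source_detector,
    distance_source_axis_mm = p$dist_source_axis,
    view_sampling_interval_deg = p$view_spacing,
    segment_span_deg = p$segment_span,
    number_of_sources_per_segment = p$n_views_per_segment,
    number_of_detector_elements = p$n_detector_elements,
    detector_element_size_mm = p$detector_element_size,
    field_of_view_diameter_mm = p$fov_diameter,
    image_pixels = p$image_pixels,
    pixel_size_mm = p$pixel_size
  )
  txt <- yaml::as.yaml(cfg)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read TCT geometry from a YAML configuration
#'
#' Inverse of [geometry_to_yaml()].
#'
#' @param file Path to a YAML file written by [geometry_to_yaml()].
#' @return A `tct_geometry`.
#' @export
geometry_from_yaml <- function(file) {
  cfg <- yaml::read_yaml(file)
  p <- tct_params(
    dist_source_detector = cfg$distance_source_detector_mm,
    dist_source_axis = cfg$distance_source_axis_mm,
    view_spacing = cfg$view_sampling_interval_deg,
    segment_span = cfg$segment_span_deg,
    n_views_per_segment = cfg$number_of_sources_per_segment,
    n_detector_elements = cfg$number_of_detector_elements,
    detector_element_size = cfg$detector_element_size_mm,
    image_pixels = cfg$image_pixels,
    pixel_size = cfg$pixel_size_mm,
    fov_diameter = cfg$field_of_view_diameter_mm
  )
  build_tct_geometry(p, cfg$scan_range_deg)
}
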