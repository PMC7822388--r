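#' Parallel-beam scan geometry
#'
#' Coordinate conventions (shared by every projector in the package): the
#' rotation center is the image center; pixel (i, j) of an `image_side^2`
#' map sits at `x = (i - (N+1)/2) * pixel_size`,
#' `y = (j - (N+1)/2) * pixel_size` (1-based indices, first matrix index is
#' x); detector cell `u` has signed offset `t = (u - (U+1)/2) * det_pitch`
#' with cell 1 at the negative edge; a view at angle `phi` (radians,
#' measured from the +x axis) integrates along rays
#' `x cos(phi) + y sin(phi) = t`.
#'
#' @param n_views number of projection angles over 180 degrees.
#' @param n_det number of detector cells.
#' @param det_pitch detector cell size, cm.
#' @param image_side reconstruction grid side, pixels.
#' @param pixel_size image pixel size, cm.
#' @param angles optional explicit view angles (radians, strictly increasing
#'   in `[0, pi)`); default: `n_views` angles equally spaced over 180
#'   degrees starting at 0.
#' @return Object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_views, n_det, det_pitch, image_side, pixel_size,
                          angles = NULL) {
  if (is.null(angles))
    angles <- seq(0, pi, length.out = n_views + 1L)[seq_len(n_views)]
  stopifnot(length(angles) == n_views, n_det >= 2L, det_pitch > 0,
            image_side >= 2L, pixel_size > 0)
  if (any(diff(angles) <= 0) || angles[1] < 0 || angles[n_views] >= pi)
    stop("angles must be strictly increasing within [0, pi)", call. = FALSE)
  structure(list(n_views = as.integer(n_views), n_det = as.integer(n_det),
                 det_pitch = det_pitch, angles = angles,
                 image_side = as.integer(image_side),
                 pixel_size = pixel_size),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d views / 180 deg, %d cells x %.4g cm; image %d^2 x %.4g cm\n",
    x$n_views, x$n_det, x$det_pitch, x$image_side, x$pixel_size))
  invisible(x)
}

#' Sinogram container
#'
#' @param values numeric matrix of shape `(n_views, n_det)`.
#' @param kind one of `"absorption"`, `"phase"` (line-integrated phase) or
#'   `"differential_phase"` (refraction angle, the detector-axis derivative).
#' @param geometry a [scan_geometry()].
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(values, kind, geometry) {
  kind <- match.arg(kind, c("absorption", "phase", "differential_phase"))
  values <- as.matrix(values)
  if (!inherits(geometry, "scan_geometry"))
    stop("geometry must be a scan_geometry", call. = FALSE)
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_det)
    stop(sprintf(
      "sinogram shape (%d x %d) does not match geometry (%d views x %d cells)",
      nrow(values), ncol(values), geometry$n_views, geometry$n_det),
      call. = FALSE)
  structure(list(values = values, kind = kind, geometry = geometry),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> kind = %s, %d views x %d cells, range [%.3g, %.3g]\n",
              x$kind, nrow(x$values), ncol(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

.check_image_geometry <- function(image, geometry) {
  image <- as.matrix(image)
  if (nrow(image) != geometry$image_side || ncol(image) != geometry$image_side)
    stop(sprintf("image side (%d x %d) does not match geometry image_side %d",
                 nrow(image), ncol(image), geometry$image_side),
         call. = FALSE)
  image
}
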