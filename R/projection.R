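# Geometric core: forward/backprojection, the discrete differential operator
# D = -d/du along the detector axis, and its stable inversion.

#' Forward projection (Radon transform)
#'
#' Line integrals of an image along the rays of a parallel-beam geometry.
#' The default projector is ray-driven Joseph-style (linear interpolation
#' along the minor axis); `method = "pixel"` is the exact adjoint of the
#' pixel-driven backprojector and exists as the matched pair for adjointness
#' tests.
#'
#' @param image numeric matrix (side `geometry$image_side`) or a
#'   [phantom()] map.
#' @param geometry a [scan_geometry()].
#' @param kind kind tag of the resulting [sinogram()]; line integrals of a
#'   fraction or delta map are `"phase"` (default), of an attenuation map
#'   `"absorption"`.
#' @param method `"joseph"` (default) or `"pixel"`.
#' @return A [sinogram()] in units of image units times cm.
#' @export
forward_project <- function(image, geometry, kind = "phase",
                            method = c("joseph", "pixel")) {
  method <- match.arg(method)
  image <- .check_image_geometry(image, geometry)
  vals <- if (method == "joseph")
    cpp_forward_joseph(image, geometry$angles, geometry$n_det,
                       geometry$det_pitch, geometry$pixel_size)
  else
    cpp_forward_pixel(image, geometry$angles, geometry$n_det,
                      geometry$det_pitch, geometry$pixel_size)
  sinogram(vals, kind, geometry)
}

#' Unfiltered backprojection
#'
#' Pixel-driven backprojection with linear detector interpolation (default),
#' or the exact transpose of the Joseph forward projector
#' (`method = "joseph"`).  Plain sum over views; filtered-backprojection
#' wrappers apply the `pi / n_views` quadrature weight themselves.
#'
#' @param sino a [sinogram()] (any kind).
#' @param geometry geometry to backproject into; defaults to the sinogram's.
#' @param method `"pixel"` (default) or `"joseph"`.
#' @return numeric matrix of side `geometry$image_side`.
#' @export
back_project <- function(sino, geometry = sino$geometry,
                         method = c("pixel", "joseph")) {
  method <- match.arg(method)
  if (!inherits(sino, "sinogram")) stop("sino must be a sinogram",
                                        call. = FALSE)
  if (nrow(sino$values) != geometry$n_views ||
      ncol(sino$values) != geometry$n_det)
    stop("sinogram shape does not match geometry", call. = FALSE)
  if (method == "pixel")
    cpp_back_pixel(sino$values, geometry$image_side, geometry$angles,
                   geometry$det_pitch, geometry$pixel_size)
  else
    cpp_back_joseph(sino$values, geometry$image_side, geometry$angles,
                    geometry$det_pitch, geometry$pixel_size)
}

#' Discrete differential operator D along the detector axis
#'
#' Applies `-d/du` per view: central differences over the detector cells
#' divided by the cell pitch, with one-sided differences at the two boundary
#' cells.  Maps a `"phase"` sinogram to `"differential_phase"`.
#'
#' @param sino a [sinogram()] of kind `"phase"`.
#' @return A [sinogram()] of kind `"differential_phase"`.
#' @export
diff_op <- function(sino) {
  if (!inherits(sino, "sinogram") || sino$kind != "phase")
    stop("diff_op expects a sinogram of kind 'phase'", call. = FALSE)
  sinogram(cpp_diff_rows(sino$values, sino$geometry$det_pitch),
           "differential_phase", sino$geometry)
}

#' Invert the detector-axis differential operator
#'
#' Two inversion routes for `D e = theta`:
#' \describe{
#'   \item{`"gradient_descent"`}{`n_steps` fixed-step steepest-descent
#'     iterations on `||D e - theta||^2` from a zero start (step `1/L`,
#'     `L = 4 / det_pitch^2` the Gershgorin bound on `||D^T D||`).  This is
#'     the error-containing inversion used inside the one-step solver.}
#'   \item{`"cumulative"`}{the running-sum antiderivative consistent with
#'     the central-difference stencil, left boundary pinned to zero — the
#'     classical `D^{-1}` of the projection-domain two-step route.}
#' }
#'
#' @param residual a [sinogram()] of kind `"differential_phase"`.
#' @param n_steps descent steps (`gradient_descent` mode only).
#' @param mode `"gradient_descent"` or `"cumulative"`.
#' @return A [sinogram()] of kind `"phase"`.
#' @export
solve_inverse_diff <- function(residual, n_steps = 30L,
                               mode = c("gradient_descent", "cumulative")) {
  mode <- match.arg(mode)
  if (!inherits(residual, "sinogram") ||
      residual$kind != "differential_phase")
    stop("solve_inverse_diff expects kind 'differential_phase'",
         call. = FALSE)
  p <- residual$geometry$det_pitch
  vals <- if (mode == "cumulative") {
    cpp_dinv_cumulative(residual$values, p)
  } else {
    if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
    cpp_dinv_gd(residual$values, p, as.integer(n_steps))
  }
  sinogram(vals, "phase", residual$geometry)
}

#' Dense system matrix of the Joseph projector
#'
#' Materializes the projection matrix `A` (rows: view-major ray index
#' `(v - 1) * n_det + u`; columns: pixel index column-major) by forward
#' projecting unit images.  Only sensible at toy sizes; used by oracle tests
#' and the literal reference implementation of the coupled update.
#'
#' @param geometry a [scan_geometry()] (keep `image_side` tiny).
#' @return dense numeric matrix of shape
#'   `(n_views * n_det, image_side^2)`.
#' @export
system_matrix <- function(geometry) {
  n <- geometry$image_side
  J <- n * n
  A <- matrix(0, geometry$n_views * geometry$n_det, J)
  for (j in seq_len(J)) {
    e <- matrix(0, n, n)
    e[j] <- 1
    A[, j] <- as.vector(t(cpp_forward_joseph(
      e, geometry$angles, geometry$n_det, geometry$det_pitch,
      geometry$pixel_size)))
  }
  A
}

# Ray-sum matrix A_{u,+} for SART normalization: forward projection of a
# unit image.  Cached per geometry within a solver run by the callers.
.ray_sums <- function(geometry) {
  ones <- matrix(1, geometry$image_side, geometry$image_side)
  cpp_forward_joseph(ones, geometry$angles, geometry$n_det,
                     geometry$det_pitch, geometry$pixel_size)
}
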