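# Image-quality metrics and profile extraction.

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(N Gr^2 / ||I - I*||_2^2)` with `N` the pixel count and
#' `Gr` the maximum gray value of the ground-truth image (this printed form
#' is algebraically identical to the conventional `10 log10(Gr^2 / MSE)`).
#' Identical images return `+Inf`.
#'
#' @param recon reconstructed map (matrix or [recon_image()]).
#' @param truth ground-truth map of the same shape.
#' @param peak optional override of `Gr` (default `max(truth)`).
#' @return PSNR in dB.
#' @export
psnr <- function(recon, truth, peak = NULL) {
  I <- if (inherits(recon, "recon_image")) recon$values else as.matrix(recon)
  T_ <- if (inherits(truth, "recon_image")) truth$values else as.matrix(truth)
  if (!identical(dim(I), dim(T_)))
    stop("recon and truth must have matching shapes", call. = FALSE)
  err2 <- sum((I - T_)^2)
  if (err2 == 0) return(Inf)
  Gr <- if (is.null(peak)) max(T_) else peak
  10 * log10(length(I) * Gr^2 / err2)
}

# bilinear sample of image at continuous (1-based) pixel coordinates
.bilinear <- function(image, xi, yi) {
  n <- nrow(image); m <- ncol(image)
  if (any(xi < 1 | xi > n | yi < 1 | yi > m))
    stop("profile path leaves the image", call. = FALSE)
  x0 <- pmin(floor(xi), n - 1); y0 <- pmin(floor(yi), m - 1)
  fx <- xi - x0; fy <- yi - y0
  image[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    image[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    image[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    image[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Extract a 1-D profile from an image
#'
#' Bilinear samples at unit-pixel spacing along a vertical line or a circle,
#' with arc-length coordinates.  Pixel coordinates are 1-based; the first
#' matrix index is x (column of the displayed image), the second y.
#'
#' @param image numeric matrix (or [recon_image()]).
#' @param path either `list(type = "vertical", column = x0)` (profile along
#'   y at fixed x) or `list(type = "circle", center = c(x0, y0), radius = r)`
#'   (radius in pixels).
#' @return data frame with columns `s` (arc length, pixels) and `value`.
#' @export
extract_profile <- function(image, path) {
  img <- if (inherits(image, "recon_image")) image$values else
    as.matrix(image)
  type <- match.arg(path$type, c("vertical", "circle"))
  if (type == "vertical") {
    x0 <- path$column
    if (x0 < 1 || x0 > nrow(img))
      stop("profile path leaves the image", call. = FALSE)
    yi <- seq_len(ncol(img))
    data.frame(s = yi, value = .bilinear(img, rep(x0, length(yi)), yi))
  } else {
    ctr <- path$center; r <- path$radius
    n_s <- max(8L, ceiling(2 * pi * r))
    ang <- seq(0, 2 * pi, length.out = n_s + 1L)[seq_len(n_s)]
    xi <- ctr[1] + r * cos(ang)
    yi <- ctr[2] + r * sin(ang)
    data.frame(s = r * ang, value = .bilinear(img, xi, yi))
  }
}
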