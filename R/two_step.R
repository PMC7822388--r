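# Classical two-step baselines: analytic FBP reconstructions (Shepp-Logan
# ramp for the absorption channel, imaginary-sign Hilbert kernel for the
# differential-phase channel), TV-regularized iterative variants, and the
# image-domain / projection-domain decomposition routes.

#' Reconstructed single-quantity image
#'
#' @param values numeric matrix.
#' @param quantity `"mu"`, `"delta"` or `"fraction"`.
#' @param pixel_size cm.
#' @param method_tag provenance string.
#' @return Object of class `recon_image`.
#' @export
recon_image <- function(values, quantity = c("mu", "delta", "fraction"),
                        pixel_size, method_tag = "") {
  structure(list(values = as.matrix(values),
                 quantity = match.arg(quantity),
                 pixel_size = pixel_size, method_tag = method_tag),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %s (%s), %d x %d, range [%.3g, %.3g]\n",
              x$quantity, x$method_tag, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# --- FBP filtering (FFT with zero padding to the next power of two >= 2U) --

.pad_len <- function(U) 2^ceiling(log2(2 * U))

# Shepp-Logan apodized ramp, spatial kernel h(n) = -2 / (pi^2 p^2 (4n^2 - 1));
# filtering q = p * conv(row, h) (pitch factor from the convolution
# quadrature).
.filter_shepp_logan <- function(vals, pitch) {
  U <- ncol(vals)
  L <- .pad_len(U)
  n <- c(0:(L / 2), (-L / 2 + 1):(-1))
  h <- -2 / (pi^2 * pitch^2 * (4 * n^2 - 1))
  H <- Re(fft(h))
  pad <- matrix(0, nrow(vals), L)
  pad[, seq_len(U)] <- vals
  ft <- mvfft(t(pad))
  q <- Re(mvfft(ft * H, inverse = TRUE)) / L
  t(q)[, seq_len(U), drop = FALSE] * pitch
}

# Imaginary-sign Hilbert kernel for differential data: the ramp |w| divided
# by the spectrum (-2 pi i w) of the derivative already present in the data,
# i.e. multiplier i * sign(w) / (2 pi).  Dimensionless (no pitch factor).
.filter_hilbert <- function(vals, pitch) {
  U <- ncol(vals)
  L <- .pad_len(U)
  freq <- c(0:(L / 2), (-L / 2 + 1):(-1))
  mult <- 1i * sign(freq) / (2 * pi)
  mult[1] <- 0
  mult[L / 2 + 1] <- 0
  pad <- matrix(0, nrow(vals), L)
  pad[, seq_len(U)] <- vals
  ft <- mvfft(t(pad))
  q <- Re(mvfft(ft * mult, inverse = TRUE)) / L
  t(q)[, seq_len(U), drop = FALSE]
}

.fbp_backproject <- function(filtered, geometry) {
  (pi / geometry$n_views) *
    cpp_back_pixel(filtered, geometry$image_side, geometry$angles,
                   geometry$det_pitch, geometry$pixel_size)
}

#' Filtered backprojection of an absorption sinogram
#'
#' Standard FBP with the Shepp-Logan apodized ramp filter.
#'
#' @param M a [sinogram()] of kind `"absorption"` (or `"phase"`, i.e. any
#'   plain line-integral data).
#' @param geometry reconstruction geometry; default the sinogram's.
#' @return A [recon_image()] with `quantity = "mu"`.
#' @export
fbp_absorption <- function(M, geometry = M$geometry) {
  if (!inherits(M, "sinogram") || M$kind == "differential_phase")
    stop("fbp_absorption expects line-integral data (kind 'absorption' ",
         "or 'phase'), not 'differential_phase'", call. = FALSE)
  q <- .filter_shepp_logan(M$values, geometry$det_pitch)
  recon_image(.fbp_backproject(q, geometry), "mu", geometry$pixel_size,
              "fbp_shepp_logan")
}

#' Filtered backprojection of a differential-phase sinogram
#'
#' FBP with the imaginary-sign Hilbert kernel replacing the ramp, which
#' accounts for the data already being a detector-axis derivative.  The
#' Hilbert route leaves a global additive constant weakly determined; it is
#' fixed by forcing the air corners (pixels outside the inscribed circle,
#' which lie outside any in-field support) to zero mean.
#'
#' @param theta a [sinogram()] of kind `"differential_phase"`.
#' @param geometry reconstruction geometry; default the sinogram's.
#' @return A [recon_image()] with `quantity = "delta"` (in the scaled-delta
#'   convention of the data).
#' @export
fbp_differential_phase <- function(theta, geometry = theta$geometry) {
  if (!inherits(theta, "sinogram") || theta$kind != "differential_phase")
    stop("fbp_differential_phase expects kind 'differential_phase'",
         call. = FALSE)
  q <- .filter_hilbert(theta$values, geometry$det_pitch)
  img <- .fbp_backproject(q, geometry)
  n <- geometry$image_side
  xs <- seq_len(n) - (n + 1) / 2
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  border <- rr > n / 2
  img <- img - mean(img[border])
  recon_image(img, "delta", geometry$pixel_size, "fbp_hilbert")
}

#' TV-regularized SART reconstruction of a single channel
#'
#' SART iterations on one sinogram with a Chambolle TV denoising step after
#' each sweep.  For `differential_phase` data the per-sweep residual passes
#' through the gradient-descent inversion of the differential operator (the
#' single-channel analog of the one-step solver).
#'
#' @param sino a [sinogram()] of kind `"absorption"`, `"phase"` or
#'   `"differential_phase"`.
#' @param lambda_tv fixed TV strength, or the default `NULL` for the
#'   `0.1 * mean(|image|)` rule recomputed each sweep (`0` disables TV).
#' @param n_iter outer sweeps.
#' @param geometry default the sinogram's.
#' @param relaxation SART relaxation factor.
#' @param inner_inverse_steps descent steps of the residual inversion
#'   (differential data only).
#' @param inner_inverse_mode inversion of the differential residual:
#'   `"cumulative"` (boundary-pinned antiderivative), `"anchored_gd"`
#'   (warm-started anchored descent) or `"zero_gd"`; see
#'   [solver_options()].
#' @param tv_fraction fraction for the mean rule.
#' @param view_order `"sequential"` or `"random"` (seeded shuffled
#'   permutation per sweep; accelerates SART convergence for many-view
#'   scans with adjacent, highly correlated angles).
#' @param seed seed for the random view order.
#' @return A [recon_image()] (`quantity` `"mu"` for absorption input,
#'   `"delta"` for differential-phase input).
#' @export
sart_tv_recon <- function(sino, lambda_tv = NULL, n_iter = 100L,
                          geometry = sino$geometry, relaxation = 1,
                          inner_inverse_steps = 30L,
                          inner_inverse_mode = c("cumulative",
                                                 "anchored_gd", "zero_gd"),
                          tv_fraction = 0.1,
                          view_order = c("sequential", "random"),
                          seed = 1L) {
  inner_inverse_mode <- match.arg(inner_inverse_mode)
  view_order <- match.arg(view_order)
  if (!inherits(sino, "sinogram")) stop("sino must be a sinogram",
                                        call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  differential <- sino$kind == "differential_phase"
  n <- geometry$image_side
  x <- matrix(0, n, n)
  rowsum <- .ray_sums(geometry)
  imode <- switch(inner_inverse_mode, zero_gd = 0L, cumulative = 1L,
                  anchored_gd = 2L)
  e_state <- matrix(0, geometry$n_views, geometry$n_det)
  if (view_order == "random") {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  for (m in seq_len(n_iter)) {
    ord <- if (view_order == "sequential") seq_len(geometry$n_views) - 1L
           else sample.int(geometry$n_views) - 1L
    sw <- cpp_sart_sweep(x, sino$values, geometry$angles,
                         geometry$det_pitch, geometry$pixel_size,
                         differential, relaxation,
                         as.integer(inner_inverse_steps), rowsum,
                         as.integer(ord), per_view = TRUE, imode, e_state)
    x <- sw$x
    ltv <- if (is.null(lambda_tv)) tv_fraction * mean(abs(x)) else lambda_tv
    if (ltv > 0) x <- .chambolle(x, ltv, 20L)
  }
  recon_image(x, if (differential) "delta" else "mu", geometry$pixel_size,
              "sart_tv")
}

#' Image-domain two-step decomposition
#'
#' Pixelwise solve of the 2x2 system
#' `[mu1 mu2; delta1 delta2] (f, g)^T = (mu_img, delta_img)^T` from
#' co-registered attenuation and (scaled) phase reconstructions.
#'
#' @param mu_img,delta_img [recon_image()]s (or bare matrices) of the two
#'   channels, co-registered.
#' @param basis a [basis_pair()].
#' @return A [decomposition_result()].
#' @export
decompose_image_domain <- function(mu_img, delta_img, basis) {
  mu <- if (inherits(mu_img, "recon_image")) mu_img$values else
    as.matrix(mu_img)
  de <- if (inherits(delta_img, "recon_image")) delta_img$values else
    as.matrix(delta_img)
  if (!identical(dim(mu), dim(de)))
    stop("mu and delta images must be co-registered (same shape)",
         call. = FALSE)
  s <- .solve_basis(basis, mu, de)
  px <- if (inherits(mu_img, "recon_image")) mu_img$pixel_size else NA_real_
  decomposition_result(s$f, s$g, method_tag = "image_domain", basis = basis,
                       pixel_size = px)
}

#' Projection-domain two-step decomposition
#'
#' Forms the two basis-material line-integral sinograms
#' `A f = (delta2 M - mu2 D^{-1} theta) / (mu1 delta2 - mu2 delta1)` (and
#' the label-swapped analog) using the cumulative antiderivative for
#' `D^{-1}`, then reconstructs each with Shepp-Logan FBP or TV-regularized
#' SART.
#'
#' @param pair a [sinogram_pair()].
#' @param recon `"fbp"` or `"sart_tv"`.
#' @param ... passed to [sart_tv_recon()] (for `recon = "sart_tv"`).
#' @return A [decomposition_result()].
#' @export
decompose_projection_domain <- function(pair, recon = c("fbp", "sart_tv"),
                                        ...) {
  recon <- match.arg(recon)
  basis <- pair$basis
  geometry <- pair$M$geometry
  phi <- cpp_dinv_cumulative(pair$theta$values, geometry$det_pitch)
  s <- .solve_basis(basis, pair$M$values, phi)
  sf <- sinogram(s$f, "phase", geometry)
  sg <- sinogram(s$g, "phase", geometry)
  if (recon == "fbp") {
    f <- fbp_absorption(sf)$values
    g <- fbp_absorption(sg)$values
  } else {
    f <- sart_tv_recon(sf, ...)$values
    g <- sart_tv_recon(sg, ...)$values
  }
  decomposition_result(f, g, method_tag = paste0("projection_domain_", recon),
                       basis = basis, pixel_size = geometry$pixel_size)
}

#' Full image-domain baseline from a sinogram pair
#'
#' Convenience wrapper running the two-step image-domain route end to end:
#' reconstruct the attenuation and scaled-delta images (FBP, or the
#' TV-regularized iterative variant used in the comparisons), then solve the
#' pixelwise 2x2 system.
#'
#' @param pair a [sinogram_pair()].
#' @param recon `"fbp"` or `"sart_tv"`.
#' @param ... passed to [sart_tv_recon()].
#' @return A [decomposition_result()].
#' @export
decompose_image_domain_pair <- function(pair, recon = c("fbp", "sart_tv"),
                                        ...) {
  recon <- match.arg(recon)
  if (recon == "fbp") {
    mu <- fbp_absorption(pair$M)
    de <- fbp_differential_phase(pair$theta)
  } else {
    mu <- sart_tv_recon(pair$M, ...)
    de <- sart_tv_recon(pair$theta, ...)
  }
  out <- decompose_image_domain(mu, de, pair$basis)
  out$method_tag <- paste0("image_domain_", recon)
  out
}
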