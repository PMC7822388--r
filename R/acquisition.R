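# Grating-interferometer measurement simulation: compose absorption and
# differential-phase sinograms from a phantom, then corrupt with noise.

#' Paired absorption / differential-phase sinograms
#'
#' @param M [sinogram()] of kind `"absorption"`.
#' @param theta [sinogram()] of kind `"differential_phase"`.
#' @param basis the [basis_pair()] the pair was composed with.
#' @param photon_count expected photons per ray of the noise model
#'   (`NA` for noise-free data).
#' @return Object of class `sinogram_pair`.
#' @export
sinogram_pair <- function(M, theta, basis, photon_count = NA_real_) {
  stopifnot(inherits(M, "sinogram"), inherits(theta, "sinogram"))
  if (M$kind != "absorption" || theta$kind != "differential_phase")
    stop("expected kinds absorption / differential_phase", call. = FALSE)
  if (!identical(unclass(M$geometry), unclass(theta$geometry)))
    stop("M and theta must share one scan geometry", call. = FALSE)
  structure(list(M = M, theta = theta, basis = basis,
                 photon_count = photon_count),
            class = "sinogram_pair")
}

#' @export
print.sinogram_pair <- function(x, ...) {
  cat(sprintf("<sinogram_pair> %d views x %d cells, basis %s/%s, photons %s\n",
              nrow(x$M$values), ncol(x$M$values), x$basis$names[1],
              x$basis$names[2],
              if (is.na(x$photon_count)) "none (clean)"
              else format(x$photon_count)))
  invisible(x)
}

#' Simulate noise-free absorption and differential-phase sinograms
#'
#' Composes the measurement pair from the fraction maps:
#' `M = mu1 A f + mu2 A g` and
#' `theta = delta1 D(A f) + delta2 D(A g)` with the (rescaled) deltas of the
#' basis.  Shares one code path with the solver's projection estimator.
#'
#' @param ph a [phantom()].
#' @param geometry a [scan_geometry()].
#' @param basis basis pair; default the phantom's own.
#' @return A [sinogram_pair()] (noise-free, `photon_count = NA`).
#' @export
simulate_sinograms <- function(ph, geometry, basis = ph$basis) {
  estimate_projections(ph$f, ph$g, basis, geometry)
}

#' Corrupt a sinogram pair with photon noise
#'
#' Absorption channel: per ray, `n ~ Poisson(photon_count * exp(-M))` and
#' `M_noisy = -log(n / photon_count)`, with the draw clamped to `n >= 1` to
#' avoid `log(0)` (a simulator convention).  Phase channel:
#' \describe{
#'   \item{`"poisson_on_phase"` (default)}{perturbs the integrated phase
#'     projection `Phi = D^{-1} theta` (cumulative inversion) with zero-mean
#'     Gaussian noise of per-ray standard deviation
#'     `phase_noise_scale / sqrt(n)` — the count-statistics (delta-method)
#'     scale at the detected count `n` — and re-differentiates, mirroring
#'     the center-difference pipeline that produced `theta`.}
#'   \item{`"gaussian"`}{adds zero-mean noise of fixed standard deviation
#'     `gaussian_sd` directly to `theta`.}
#' }
#'
#' @param pair a [sinogram_pair()].
#' @param photon_count expected photons per ray (e.g. `1e6`).
#' @param phase_noise `"poisson_on_phase"` or `"gaussian"`.
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @param phase_noise_scale scale factor of the count-based phase noise.
#' @param gaussian_sd standard deviation for `phase_noise = "gaussian"`.
#' @return A [sinogram_pair()] with noisy values and `photon_count` set.
#' @export
add_noise <- function(pair, photon_count,
                      phase_noise = c("poisson_on_phase", "gaussian"),
                      seed = NULL, phase_noise_scale = 1,
                      gaussian_sd = 1e-3) {
  phase_noise <- match.arg(phase_noise)
  if (!is.numeric(photon_count) || photon_count <= 0)
    stop("photon_count must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  M <- pair$M$values
  counts <- rpois(length(M), photon_count * exp(-M))
  counts <- pmax(counts, 1)
  Mn <- matrix(-log(counts / photon_count), nrow(M), ncol(M))

  th <- pair$theta$values
  if (phase_noise == "gaussian") {
    thn <- th + matrix(rnorm(length(th), sd = gaussian_sd), nrow(th),
                       ncol(th))
  } else {
    p <- pair$theta$geometry$det_pitch
    phi <- cpp_dinv_cumulative(th, p)
    n_det <- photon_count * exp(-M)
    sd_phi <- phase_noise_scale / sqrt(pmax(n_det, 1))
    phi_n <- phi + matrix(rnorm(length(phi)), nrow(phi), ncol(phi)) * sd_phi
    thn <- cpp_diff_rows(phi_n, p)
  }
  sinogram_pair(sinogram(Mn, "absorption", pair$M$geometry),
                sinogram(thn, "differential_phase", pair$theta$geometry),
                pair$basis, photon_count = photon_count)
}
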