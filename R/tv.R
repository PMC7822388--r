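#' Total-variation denoising (Chambolle dual projection)
#'
#' Solves `min_u ||u - v||^2 / 2 + lambda_tv * TV(u)` by Chambolle's
#' semi-implicit dual fixed-point iteration (step 1/4).  `lambda_tv = 0`
#' returns the input unchanged.  This is the regularization operator applied
#' to both fraction maps after every outer sweep of the one-step solver, and
#' to the single-channel iterates of the regularized two-step baselines.
#'
#' @param image numeric matrix.
#' @param lambda_tv regularization strength (>= 0), in image units.
#' @param n_iter dual iterations (default 20).
#' @return Denoised matrix of the same shape.
#' @export
tv_regularize <- function(image, lambda_tv, n_iter = 20L) {
  if (!is.numeric(lambda_tv) || length(lambda_tv) != 1L || lambda_tv < 0)
    stop("lambda_tv must be a nonnegative scalar", call. = FALSE)
  image <- as.matrix(image)
  if (lambda_tv == 0) return(image)
  .chambolle(image, lambda_tv, n_iter)
}

# forward differences with replicated (Neumann) boundary
.grad_x <- function(u) rbind(u[-1, , drop = FALSE], u[nrow(u), , drop = FALSE]) - u
.grad_y <- function(u) cbind(u[, -1, drop = FALSE], u[, ncol(u), drop = FALSE]) - u

# divergence, the negative adjoint of the gradient above
.div_p <- function(px, py) {
  n <- nrow(px); m <- ncol(px)
  dx <- px - rbind(matrix(0, 1, m), px[-n, , drop = FALSE])
  dx[n, ] <- -px[n - 1, ]
  dy <- py - cbind(matrix(0, n, 1), py[, -m, drop = FALSE])
  dy[, m] <- -py[, m - 1]
  dx + dy
}

.chambolle <- function(v, lambda, n_iter, tau = 0.25) {
  px <- matrix(0, nrow(v), ncol(v))
  py <- px
  for (k in seq_len(n_iter)) {
    d <- .div_p(px, py) - v / lambda
    gx <- .grad_x(d); gy <- .grad_y(d)
    den <- 1 + tau * sqrt(gx^2 + gy^2)
    px <- (px + tau * gx) / den
    py <- (py + tau * gy) / den
  }
  v - lambda * .div_p(px, py)
}

#' Isotropic total variation of an image
#'
#' Forward-difference isotropic TV; used in tests of the denoiser's
#' variation-reducing property.
#' @param image numeric matrix.
#' @return scalar TV value.
#' @export
total_variation <- function(image) {
  image <- as.matrix(image)
  sum(sqrt(.grad_x(image)^2 + .grad_y(image)^2))
}
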