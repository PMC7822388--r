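# Independent reference implementations used as oracles.  All are literal
# scalar-loop or dense-matrix translations, kept free of the package's
# compiled code paths.

# Literal Joseph-style forward projector (scalar loops, closed-form index).
literal_joseph <- function(img, angles, n_det, pitch, psz) {
  N <- nrow(img)
  half <- (N - 1) / 2
  out <- matrix(0, length(angles), n_det)
  for (v in seq_along(angles)) {
    c0 <- cos(angles[v]); s0 <- sin(angles[v])
    for (u in seq_len(n_det)) {
      t <- (u - 1 - (n_det - 1) / 2) * pitch
      acc <- 0
      if (abs(c0) >= abs(s0)) {
        w <- psz / abs(c0)
        for (j in 0:(N - 1)) {
          y <- (j - half) * psz
          xi <- (t - y * s0) / c0 / psz + half
          i0 <- floor(xi); fr <- xi - i0
          if (i0 >= 0 && i0 < N) acc <- acc + (1 - fr) * img[i0 + 1, j + 1]
          if (i0 + 1 >= 0 && i0 + 1 < N)
            acc <- acc + fr * img[i0 + 2, j + 1]
        }
      } else {
        w <- psz / abs(s0)
        for (i in 0:(N - 1)) {
          x <- (i - half) * psz
          yi <- (t - x * c0) / s0 / psz + half
          j0 <- floor(yi); fr <- yi - j0
          if (j0 >= 0 && j0 < N) acc <- acc + (1 - fr) * img[i + 1, j0 + 1]
          if (j0 + 1 >= 0 && j0 + 1 < N)
            acc <- acc + fr * img[i + 1, j0 + 2]
        }
      }
      out[v, u] <- acc * w
    }
  }
  out
}

# Dense projection matrix from the literal projector (rows view-major).
literal_system_matrix <- function(geometry) {
  n <- geometry$image_side
  A <- matrix(0, geometry$n_views * geometry$n_det, n * n)
  for (j in seq_len(n * n)) {
    e <- matrix(0, n, n); e[j] <- 1
    A[, j] <- as.vector(t(literal_joseph(e, geometry$angles,
                                         geometry$n_det,
                                         geometry$det_pitch,
                                         geometry$pixel_size)))
  }
  A
}

# Dense matrix of the discrete differential operator -d/du (central
# differences, one-sided boundaries).
dense_D <- function(U, pitch) {
  D <- matrix(0, U, U)
  D[1, 1] <- 1 / pitch; D[1, 2] <- -1 / pitch
  if (U > 2) for (u in 2:(U - 1)) {
    D[u, u - 1] <- 1 / (2 * pitch); D[u, u + 1] <- -1 / (2 * pitch)
  }
  D[U, U - 1] <- 1 / pitch; D[U, U] <- -1 / pitch
  D
}

# Projected-gradient dual TV solver (independent of the Chambolle
# semi-implicit iteration in the package).
tv_projected_gradient <- function(v, lambda, n_iter = 50000, tau = 0.2) {
  gx <- function(u) rbind(u[-1, , drop = FALSE],
                          u[nrow(u), , drop = FALSE]) - u
  gy <- function(u) cbind(u[, -1, drop = FALSE],
                          u[, ncol(u), drop = FALSE]) - u
  dv <- function(px, py) {
    n <- nrow(px); m <- ncol(px)
    dx <- px - rbind(matrix(0, 1, m), px[-n, , drop = FALSE])
    dx[n, ] <- -px[n - 1, ]
    dy <- py - cbind(matrix(0, n, 1), py[, -m, drop = FALSE])
    dy[, m] <- -py[, m - 1]
    dx + dy
  }
  px <- py <- matrix(0, nrow(v), ncol(v))
  for (k in seq_len(n_iter)) {
    d <- dv(px, py) - v / lambda
    px <- px + tau * gx(d); py <- py + tau * gy(d)
    nrm <- pmax(1, sqrt(px^2 + py^2))
    px <- px / nrm; py <- py / nrm
  }
  v - lambda * dv(px, py)
}

# Klein-Nishina total cross section by quadrature over the differential
# cross section (solid-angle integral).
kn_quadrature <- function(E) {
  r0 <- 2.8179403262e-13
  a <- E / 511
  f <- function(th) {
    k <- 1 / (1 + a * (1 - cos(th)))
    (r0^2 / 2) * k^2 * (k + 1 / k - sin(th)^2) * 2 * pi * sin(th)
  }
  stats::integrate(f, 0, pi, rel.tol = 1e-12)$value
}

# Literal textbook single-channel SART sweep with a dense matrix.
literal_sart_sweep <- function(x, b, A, n_views, n_det, relax = 1) {
  Au <- rowSums(A)
  for (v in seq_len(n_views)) {
    rows <- (v - 1) * n_det + seq_len(n_det)
    Av <- A[rows, , drop = FALSE]
    e <- b[v, ] - as.vector(Av %*% x)
    r <- ifelse(Au[rows] > 1e-12, e / Au[rows], 0)
    Aj <- colSums(Av)
    upd <- as.vector(t(Av) %*% r)
    x <- x + ifelse(Aj > 1e-12, relax * upd / Aj, 0)
  }
  x
}
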