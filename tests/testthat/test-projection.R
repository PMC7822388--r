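test_that("forward projection is linear and matches the chord closed form", {
  g <- scan_geometry(4, 64, 0.016, 64, 0.016)
  set.seed(1)
  x <- matrix(rnorm(64^2), 64); y <- matrix(rnorm(64^2), 64)
  fx <- forward_project(x, g)$values
  fy <- forward_project(y, g)$values
  fxy <- forward_project(2 * x - 3 * y, g)$values
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-10)
  expect_true(all(forward_project(0 * x, g)$values == 0))

  chord_err <- function(n) {
    gg <- scan_geometry(1, n, 1.024 / n, n, 1.024 / n)
    ph <- make_disk_phantom(n, radius = 0.3, value = 2,
                            pixel_size = 1.024 / n)
    s <- forward_project(ph$f, gg)$values[1, ]
    t_u <- (seq_len(n) - (n + 1) / 2) * (1.024 / n)
    keep <- abs(t_u) < 0.25
    chord <- 2 * 2 * sqrt(0.3^2 - t_u[keep]^2)
    max(abs(s[keep] - chord) / chord)
  }
  e64 <- chord_err(64); e256 <- chord_err(256)
  expect_lt(e64, 0.02)
  expect_lt(e256, e64)       # discretization converges with resolution
})

test_that("compiled projector matches a literal dense-matrix oracle", {
  g <- scan_geometry(4, 12, 0.01, 8, 0.009,
                     angles = c(0, 0.61, pi / 2, 2.4))
  set.seed(4)
  img <- matrix(rnorm(64), 8)
  expect_lt(max(abs(forward_project(img, g)$values -
                      literal_joseph(img, g$angles, 12, 0.01, 0.009))),
            1e-10)
  # dense A built two ways agrees too
  A_lit <- literal_system_matrix(g)
  expect_lt(max(abs(system_matrix(g) - A_lit)), 1e-10)
  expect_lt(max(abs(A_lit %*% as.vector(img) -
                      as.vector(t(forward_project(img, g)$values)))),
            1e-10)
})

test_that("backprojection smears a single cell along its ray", {
  g <- scan_geometry(3, 32, 0.01, 32, 0.01)
  s <- matrix(0, 3, 32); s[2, 20] <- 1
  img <- back_project(sinogram(s, "phase", g))
  expect_true(all(back_project(sinogram(0 * s, "phase", g)) == 0))
  phi <- g$angles[2]
  t20 <- (20 - (32 + 1) / 2) * 0.01
  xs <- (seq_len(32) - (32 + 1) / 2) * 0.01
  dist <- abs(outer(xs * cos(phi), xs * sin(phi), "+") - t20)
  expect_true(all(img[dist > 0.021] == 0))
  expect_gt(sum(img[dist <= 0.011]), 0)
})

test_that("forward and backprojection are adjoint in matched pairs", {
  g <- scan_geometry(5, 20, 0.008, 16, 0.009)
  set.seed(11)
  for (k in 1:3) {
    x <- matrix(rnorm(16^2), 16)
    y <- matrix(rnorm(5 * 20), 5)
    for (m in c("pixel", "joseph")) {
      lhs <- sum(forward_project(x, g, method = m)$values * y)
      rhs <- sum(x * back_project(sinogram(y, "phase", g), method = m))
      expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
    }
  }
})

test_that("differential operator matches its banded-matrix form", {
  g <- scan_geometry(1, 32, 0.02, 8, 0.02)
  u <- (seq_len(32) - 1) * 0.02
  ramp <- sinogram(matrix(3 * u, 1), "phase", g)
  d <- diff_op(ramp)
  expect_equal(d$kind, "differential_phase")
  expect_true(all(abs(d$values[1, ] + 3) < 1e-10))   # -d/du of 3u
  expect_true(all(diff_op(sinogram(matrix(7, 1, 32), "phase",
                                   g))$values == 0))
  set.seed(5)
  r <- matrix(rnorm(32), 1)
  D <- dense_D(32, 0.02)
  expect_lt(max(abs(diff_op(sinogram(r, "phase", g))$values -
                      t(D %*% t(r)))), 1e-12)
  expect_error(diff_op(d), "phase")
})

test_that("cumulative inversion is the exact antiderivative", {
  g <- scan_geometry(2, 64, 0.01, 8, 0.01)
  phi <- matrix(rep(sin(seq(0, 2, length.out = 64))^2, 2), 2,
                byrow = TRUE)
  phi <- phi - phi[, 1]                  # zero left boundary
  th <- diff_op(sinogram(phi, "phase", g))
  rec <- solve_inverse_diff(th, mode = "cumulative")
  expect_equal(rec$kind, "phase")
  expect_lt(max(abs(rec$values - phi)), 1e-12)
})

test_that("gradient-descent inversion descends and reaches the dense
           least-squares solution", {
  g <- scan_geometry(1, 16, 0.05, 4, 0.05)
  set.seed(2)
  r <- matrix(rnorm(16), 1)
  D <- dense_D(16, 0.05)
  resid_norm <- function(n) {
    e <- solve_inverse_diff(sinogram(r, "differential_phase", g),
                            n_steps = n)$values
    sqrt(sum((t(D %*% t(e)) - r)^2))
  }
  rn <- vapply(c(1, 5, 20, 100, 500), resid_norm, numeric(1))
  expect_true(all(diff(rn) <= 1e-12))    # monotone descent
  e_lim <- solve_inverse_diff(sinogram(r, "differential_phase", g),
                              n_steps = 20000)$values
  e_dense <- MASS::ginv(D) %*% t(r)      # min-norm least squares
  expect_lt(max(abs(e_lim[1, ] - e_dense)), 1e-6)
  expect_error(solve_inverse_diff(sinogram(r, "differential_phase", g),
                                  n_steps = 0), ">= 1")
  expect_error(solve_inverse_diff(sinogram(r, "phase", g)),
               "differential_phase")
})
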