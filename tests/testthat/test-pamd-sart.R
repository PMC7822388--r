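test_that("projection estimator equals the acquisition simulator", {
  ph <- make_forbild_like(64, pixel_size = 1.024 / 64)
  g <- scan_geometry(12, 96, 1.024 / 96, 64, 1.024 / 64)
  sim <- simulate_sinograms(ph, g)
  est <- estimate_projections(ph$f, ph$g, ph$basis, g)
  expect_identical(sim$M$values, est$M$values)
  expect_identical(sim$theta$values, est$theta$values)
  z <- estimate_projections(0 * ph$f, 0 * ph$g, ph$basis, g)
  expect_true(all(z$M$values == 0) && all(z$theta$values == 0))
  expect_error(estimate_projections(ph$f[1:32, 1:32], ph$g, ph$basis, g),
               "image side")
})

test_that("exact data is a fixed point of the coupled update", {
  ph <- make_forbild_like(64, pixel_size = 1.024 / 64)
  g <- scan_geometry(12, 96, 1.024 / 96, 64, 1.024 / 64)
  pr <- simulate_sinograms(ph, g)
  upd <- pamd_update(ph$f, ph$g, pr, view = 5L)
  expect_lt(max(abs(upd$f - ph$f)), 1e-9)
  expect_lt(max(abs(upd$g - ph$g)), 1e-9)
  opt <- solver_options(n_iter_max = 1, regularizer = "none",
                        stop_rule = "max_iter")
  res <- run_pamd_sart(pr, g, opt)
  # one sweep from zero must reduce, not overshoot, the data residual
  expect_lt(res$convergence$res_m[1],
            sqrt(sum(pr$M$values^2)) * 1.0001)
})

test_that("coupled view update matches a literal scalar-loop evaluation", {
  g <- scan_geometry(3, 6, 0.01, 4, 0.011)
  b <- basis_pair(c(1.0, 0.5), c(0.8, 1.2), delta_scale = 1)
  set.seed(7)
  f0 <- matrix(runif(16), 4); g0 <- matrix(runif(16), 4)
  pr <- estimate_projections(matrix(runif(16), 4), matrix(runif(16), 4),
                             b, g)
  for (mode in c("zero_gd", "cumulative")) {
    opt <- solver_options(inner_inverse_steps = 40L,
                          inner_inverse_mode = mode)
    upd <- pamd_update(f0, g0, pr, 2L, opt)
    # literal reference: dense matrices, scalar loops
    A <- literal_system_matrix(g)
    U <- 6L; rows <- U + 1:U
    Av <- A[rows, , drop = FALSE]
    p <- 0.01
    D <- dense_D(U, p)
    eM <- pr$M$values[2, ] -
      as.vector(b$mu1 * Av %*% as.vector(f0) +
                  b$mu2 * Av %*% as.vector(g0))
    thres <- pr$theta$values[2, ] -
      as.vector(D %*% (b$delta1 * Av %*% as.vector(f0) +
                         b$delta2 * Av %*% as.vector(g0)))
    if (mode == "zero_gd") {
      e <- rep(0, U)
      for (s in 1:40) e <- e - (p^2 / 4) * t(D) %*% (D %*% e - thres)
    } else {
      e <- rep(0, U); e[2] <- -p * thres[1]
      for (u in 2:(U - 1)) e[u + 1] <- e[u - 1] - 2 * p * thres[u]
    }
    det <- b$mu1 * b$delta2 - b$mu2 * b$delta1
    rf <- (b$delta2 * eM - b$mu2 * e) / det
    rg <- (b$delta1 * eM - b$mu1 * e) / (-det)
    Au <- rowSums(Av); Aj <- colSums(Av)
    fn <- as.vector(f0); gn <- as.vector(g0)
    for (j in 1:16) if (Aj[j] > 1e-12) {
      fn[j] <- fn[j] + sum(Av[, j] * rf / Au) / Aj[j]
      gn[j] <- gn[j] + sum(Av[, j] * rg / Au) / Aj[j]
    }
    expect_lt(max(abs(upd$f - matrix(fn, 4))), 1e-12)
    expect_lt(max(abs(upd$g - matrix(gn, 4))), 1e-12)
  }
})

test_that("relabelling the basis materials permutes the fraction maps", {
  ph <- make_forbild_like(64, pixel_size = 1.024 / 64)
  g <- scan_geometry(24, 96, 1.024 / 96, 64, 1.024 / 64)
  pr <- simulate_sinograms(ph, g)
  b2 <- swap_basis(ph$basis)
  pr2 <- sinogram_pair(pr$M, pr$theta, b2)
  opt <- solver_options(n_iter_max = 3, regularizer = "none",
                        stop_rule = "max_iter")
  r1 <- run_pamd_sart(pr, geometry = g, options = opt)
  r2 <- run_pamd_sart(pr2, geometry = g, options = opt)
  expect_lt(max(abs(r1$f_star - r2$g_star)), 1e-10)
  expect_lt(max(abs(r1$g_star - r2$f_star)), 1e-10)
})

test_that("compiled sweep agrees with sequential single-view updates", {
  ph <- make_forbild_like(64, pixel_size = 1.024 / 64)
  g <- scan_geometry(8, 96, 1.024 / 96, 64, 1.024 / 64)
  disk <- make_disk_phantom(64, radius = 0.25, value = 1,
                            pixel_size = 1.024 / 64, basis = ph$basis)
  pr <- simulate_sinograms(disk, g)
  opt <- solver_options(n_iter_max = 1, regularizer = "none",
                        stop_rule = "max_iter")
  full <- run_pamd_sart(pr, g, opt)
  f <- matrix(0, 64, 64); gm <- matrix(0, 64, 64)
  for (v in seq_len(g$n_views)) {
    upd <- pamd_update(f, gm, pr, v, opt)
    f <- upd$f; gm <- upd$g
  }
  expect_lt(max(abs(full$f_star - f)), 1e-12)
  expect_lt(max(abs(full$g_star - gm)), 1e-12)
})

test_that("solver bookkeeping records one row per sweep and reruns
           identically", {
  ph <- make_disk_phantom(64, radius = 0.25, value = 1,
                          pixel_size = 1.024 / 64)
  g <- scan_geometry(12, 96, 1.024 / 96, 64, 1.024 / 64)
  pr <- simulate_sinograms(ph, g)
  opt <- solver_options(n_iter_max = 1, stop_rule = "max_iter")
  r <- run_pamd_sart(pr, g, opt)
  expect_identical(r$iterations_run, 1L)
  expect_identical(nrow(r$convergence), 1L)
  expect_s3_class(r$options_used, "solver_options")
  opt2 <- solver_options(n_iter_max = 3, stop_rule = "max_iter",
                         view_order = "random", seed = 42L)
  ra <- run_pamd_sart(pr, g, opt2)
  rb <- run_pamd_sart(pr, g, opt2)
  expect_identical(ra$f_star, rb$f_star)
  expect_identical(nrow(ra$convergence), 3L)
  expect_error(solver_options(relaxation = 2.5), "relaxation")
  expect_error(solver_options(n_iter_max = 0), "n_iter_max")
})

test_that("noise-free two-disk decomposition converges below 2% error", {
  b <- make_basis("bone", "water", 20)
  f <- make_disk_phantom(128, radius = 0.18, value = 1, channel = "f",
                         pixel_size = 1.024 / 128, basis = b)$f
  gmap <- make_disk_phantom(128, radius = 0.3, value = 1, channel = "g",
                            pixel_size = 1.024 / 128, basis = b)$g
  # offset the disks so the supports differ
  gmap <- gmap[c(20:128, 1:19), ]
  ph <- phantom(f, gmap, 1.024 / 128, b)
  g <- scan_geometry(180, 192, 1.07 / 192, 128, 1.024 / 128)
  pr <- simulate_sinograms(ph, g)
  opt <- solver_options(n_iter_max = 100, regularizer = "none",
                        stop_rule = "max_iter")
  r <- run_pamd_sart(pr, g, opt, ground_truth = ph)
  expect_lt(r$convergence$rel_error[100], 0.02)
})

test_that("Chambolle TV denoising matches an independent dual solver", {
  m <- matrix(as.numeric(1:9), 3)
  expect_identical(tv_regularize(m, 0), m)
  expect_error(tv_regularize(matrix(0, 3, 3), -1), "nonnegative")
  set.seed(9)
  v <- matrix(rep(c(0, 1), each = 32), 8) + matrix(rnorm(64, sd = 0.1), 8)
  out <- tv_regularize(v, 0.15, n_iter = 20000)
  oracle <- tv_projected_gradient(v, 0.15, n_iter = 100000)
  expect_lt(max(abs(out - oracle)), 1e-4)
  expect_lte(total_variation(out), total_variation(v))
})
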