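test_that("Klein-Nishina reaches the Thomson limit and decreases with
           energy", {
  r0 <- 2.8179403262e-13
  thomson <- 8 * pi / 3 * r0^2
  expect_equal(klein_nishina(1e-6), thomson, tolerance = 1e-4)
  E <- c(1, 5, 12, 20, 30, 60, 120, 511, 1000)
  expect_true(all(diff(klein_nishina(E)) < 0))
  expect_error(klein_nishina(-1), "positive")
  expect_error(klein_nishina(0), "positive")
})

test_that("Klein-Nishina matches solid-angle quadrature of the
           differential cross section", {
  for (E in c(20, 120, 511)) {
    expect_equal(klein_nishina(E), kn_quadrature(E), tolerance = 1e-6)
  }
})

test_that("phase constant scales as 1/E^2 and predicts water's delta", {
  expect_equal(phase_constant(40) / phase_constant(20), 1 / 4)
  expect_true(all(phase_constant(c(1, 10, 100)) > 0))
  # delta = C_PC * rho_e cross-check against the tabulated water value
  expect_equal(phase_constant(20) * electron_density("water"), 5.653e-7,
               tolerance = 0.02)
  expect_error(phase_constant(0), "positive")
})

test_that("effective atomic number reproduces the tabulated compounds", {
  expect_equal(effective_Z("water"), 7.417, tolerance = 0.005 / 7.417)
  expect_equal(effective_Z("PTFE"), 8.433, tolerance = 0.005 / 8.433)
  expect_equal(effective_Z("PMMA"), 6.467, tolerance = 0.005 / 6.467)
  expect_equal(effective_Z("LDPE"), 5.444, tolerance = 0.005 / 5.444)
})

test_that("effective atomic number is a bounded, monotone power mean", {
  expect_equal(effective_Z(data.frame(Z = 8, n = 3)), 8)
  comp <- data.frame(Z = c(1, 6, 8), n = c(8, 5, 2))
  z <- effective_Z(comp)
  expect_gt(z, 1); expect_lt(z, 8)
  # shifting electrons toward the heavier element raises Z
  heavier <- data.frame(Z = c(1, 6, 8), n = c(6, 5, 3))
  expect_gt(effective_Z(heavier), z)
  expect_error(effective_Z(data.frame(Z = numeric(), n = numeric())),
               "nonempty")
})

test_that("attenuation-model fit recovers its generating coefficients", {
  gen <- quant_coefficients(1.004, 3.027, 3.619)
  mats <- c("water", "PTFE", "PMMA", "LDPE")
  rho_e <- vapply(mats, function(m)
    material_lookup(m, 20)$delta / phase_constant(20), numeric(1))
  Z <- vapply(mats, effective_Z, numeric(1))
  obs <- do.call(rbind, lapply(c(12, 20), function(E)
    data.frame(mu = mu_model(rho_e, Z, E, gen), energy = E,
               rho_e = rho_e, Z = Z)))
  fit <- fit_mu_model(observations = obs)
  expect_equal(fit$C_p, 1.004, tolerance = 1e-3)
  expect_equal(fit$C_E, 3.027, tolerance = 1e-3)
  expect_equal(fit$C_Z, 3.619, tolerance = 1e-3)
  # permutation invariance of the observation order
  fit2 <- fit_mu_model(observations = obs[sample(nrow(obs)), ])
  expect_equal(fit2$C_p, fit$C_p, tolerance = 1e-8)
  # underdetermined / single-energy guards
  expect_error(fit_mu_model(observations = obs[1:2, ]), "underdetermined")
  expect_error(fit_mu_model(energies = 20), "two or more energies")
})

test_that("noisy Monte-Carlo refits stay within 5% in the median", {
  gen <- quant_coefficients(1.004, 3.027, 3.619)
  mats <- c("water", "PTFE", "PMMA", "LDPE")
  rho_e <- vapply(mats, function(m)
    material_lookup(m, 20)$delta / phase_constant(20), numeric(1))
  Z <- vapply(mats, effective_Z, numeric(1))
  base <- do.call(rbind, lapply(c(12, 20), function(E)
    data.frame(mu = mu_model(rho_e, Z, E, gen), energy = E,
               rho_e = rho_e, Z = Z)))
  set.seed(31)
  fits <- t(vapply(1:100, function(k) {
    obs <- base
    obs$mu <- obs$mu * exp(rnorm(nrow(obs), sd = 0.01))
    f <- fit_mu_model(observations = obs)
    c(f$C_p, f$C_E, f$C_Z)
  }, numeric(3)))
  med <- apply(fits, 2, median)
  expect_equal(med, c(1.004, 3.027, 3.619), tolerance = 0.05)
})

test_that("quantification maps close the loop on pure materials", {
  co <- default_quant_coefficients()
  b <- make_basis("water", "PTFE", 20)
  uniform_water <- decomposition_result(matrix(1, 4, 4), matrix(0, 4, 4))
  m <- maps_from_basis(uniform_water, b, co, E_virtual = 12)
  expect_true(all(abs(m$Z - 7.417) < 0.05))
  expect_equal(m$n_masked, 0L)
  # virtual attenuation at the acquisition energy is the composed map
  m20 <- maps_from_basis(uniform_water, b, co, E_virtual = 20)
  expect_lt(max(abs(m20$mu_virtual - m20$mu)), 1e-12)
  # empty pixels are masked and counted, not fatal
  bg <- decomposition_result(matrix(0, 2, 2), matrix(0, 2, 2))
  mb <- maps_from_basis(bg, b, co)
  expect_identical(mb$n_masked, 4L)
  expect_true(all(is.na(mb$Z)))
})

test_that("dual-energy inversion is exact on model data and degenerates
           gracefully", {
  co <- quant_coefficients(10, 3, 3.5)
  rho_e <- matrix(c(3.3e23, 6e23, 4e23, 3.4e23), 2)
  Z <- matrix(c(7.42, 8.43, 6.47, 5.44), 2)
  mu20 <- mu_model(rho_e, Z, 20, co)
  mu12 <- mu_model(rho_e, Z, 12, co)
  de <- dual_energy_Z(mu20, mu12, co, 20, 12)
  expect_lt(max(abs(de$Z - Z)), 1e-8)
  expect_lt(max(abs(de$rho_e - rho_e) / rho_e), 1e-8)
  expect_message(bad <- dual_energy_Z(mu20, mu12, co, 20, 20),
                 "degenerate")
  expect_identical(bad$n_masked, 4L)
  expect_error(dual_energy_Z(mu20, matrix(0, 3, 3), co, 20, 12),
               "co-registered")
})

test_that("conditioning study reproduces the printed stability numbers", {
  rep <- stability_demo()
  expect_equal(rep$dual_energy$condition, 36.96, tolerance = 0.05 / 36.96)
  expect_equal(rep$phase_absorption$condition, 11.66,
               tolerance = 0.05 / 11.66)
  expect_equal(rep$dual_energy$angle_deg, 3.70, tolerance = 0.02 / 3.70)
  expect_equal(rep$phase_absorption$angle_deg, 9.93,
               tolerance = 0.02 / 9.93)
  # the phase-absorption system is the better conditioned of the two
  expect_lt(rep$phase_absorption$condition, rep$dual_energy$condition)
  expect_true(all(abs(rep$phase_absorption$solution - 0.1) < 0.005))
  # identity probe
  expect_equal(condition_2norm(diag(2)), 1)
  expect_equal(line_angle_deg(diag(2)), 90)
})
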