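test_that("equilibrium pressure inverts the hoop relation and is monotone", {
  g <- default_geom()
  p <- reference_params("WT", 12)

  # identity-like state at lam_z = 1: zero stress, zero pressure
  expect_equal(equilibrium_pressure(four_fiber_params(c = 10), g, 1, 1), 0,
               tolerance = 1e-12)

  # direct inversion: P = sigma_theta h / ri recovered in mmHg
  lt <- 1.5; lz <- 1.7
  fw <- deformed_geometry(g, lt, lz)
  sig <- cauchy_stress(p, deformation_from_stretches(lt, lz))
  expect_equal(equilibrium_pressure(p, g, lt, lz),
               kpa_to_mmhg(sig[["sigma_theta"]] * fw$h / fw$ri),
               tolerance = 1e-10)

  # strictly increasing over the physiologic stretch range
  P <- equilibrium_pressure(p, g, seq(1, 1.8, by = 0.05), 1.7)
  expect_true(all(diff(P) > 0))
})

test_that("state_at_pressure and equilibrium_pressure are an inverse pair", {
  g <- default_geom()
  p <- reference_params("WT", 12)
  for (P in c(10, 80, 120, 140)) {
    s <- state_at_pressure(p, g, P, 1.7)
    expect_equal(equilibrium_pressure(p, g, s$lam_theta, 1.7), P,
                 tolerance = 1e-8)
  }
  s80 <- state_at_pressure(p, g, 80, 1.7)
  s120 <- state_at_pressure(p, g, 120, 1.7)
  expect_gt(s120$lam_theta, s80$lam_theta)

  # P = 0 lands at the energy minimum over lam_theta at fixed lam_z
  s0 <- state_at_pressure(p, g, 0, 1.7)
  lt_grid <- seq(0.55, 1.5, by = 0.001)
  W <- vapply(lt_grid, function(l)
    strain_energy(p, deformation_from_stretches(l, 1.7)), numeric(1))
  expect_equal(s0$lam_theta, lt_grid[which.min(W)], tolerance = 2e-3)

  # an isotropic-only wall carries a bounded maximum pressure
  expect_error(state_at_pressure(four_fiber_params(c = 10), g, 500, 1.7),
               "no solution")
})

test_that("distensibility matches its defining ratio and invariances", {
  expect_equal(distensibility(1500, 1500), 0)
  expect_equal(distensibility(1560, 1500, 120, 80), 1e-3, tolerance = 1e-12)
  expect_equal(distensibility(3120, 3000, 120, 80),
               distensibility(1560, 1500, 120, 80), tolerance = 1e-15)
  expect_error(distensibility(1560, 1500, 80, 120), "P_sys > P_dia")
})

test_that("fitted metrics reproduce ground-truth metrics end to end", {
  sp <- noisefree_spec(seed = 51)
  rec <- simulate_subject(sp, "m-01")
  fit <- fit_parameters(rec, fit_config(seed = 5, n_starts = 8))
  m_fit <- compute_invivo_metrics(fit, rec)
  m_true <- compute_invivo_metrics(sp$params, rec, lam_z_iv = sp$lam_z_iv)
  for (col in c("lam_z_iv", "lam_theta_sys", "sigma_theta_sys", "sigma_z_sys",
                "C_tttt_sys", "C_zzzz_sys", "W_sys", "h_sys", "di_sys",
                "di_dia", "distensibility"))
    expect_equal(m_fit[[col]], m_true[[col]], tolerance = 0.03 * abs(m_true[[col]]),
                 label = col)

  # physiologic sanity: stored energy grows along loading, stiffness in the
  # 0.5-10 MPa range, positive distensibility
  lt80 <- state_at_pressure(sp$params, rec$geometry, 80, sp$lam_z_iv)
  expect_gt(m_true$W_sys, strain_energy(sp$params, lt80))
  expect_gt(m_true$C_tttt_sys, 0.5)
  expect_lt(m_true$C_tttt_sys, 10)
  expect_gt(m_true$distensibility, 0)
})

test_that("stiffening the circumferential family raises C_tttt and lowers D", {
  sp <- noisefree_spec(seed = 52)
  rec <- simulate_subject(sp, "m-02")
  base <- compute_invivo_metrics(sp$params, rec, lam_z_iv = sp$lam_z_iv)
  stiffer <- sp$params
  stiffer$c1[2] <- 10 * max(stiffer$c1[2], 1)
  m2 <- compute_invivo_metrics(stiffer, rec, lam_z_iv = sp$lam_z_iv)
  expect_gt(m2$C_tttt_sys, base$C_tttt_sys)
  expect_lt(m2$distensibility, base$distensibility)
})
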