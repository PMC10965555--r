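test_that("stored energy matches direct evaluations and vanishes at identity", {
  id <- deformation_from_stretches(1, 1)
  set.seed(3)
  for (k in 1:10) expect_identical(strain_energy(rand_params(), id), 0)

  # purely isotropic material
  s <- deformation_from_stretches(1.2, 1.5)
  expect_equal(strain_energy(four_fiber_params(c = 10), s),
               5 * (s$I_C - 3), tolerance = 1e-12)
  expect_equal(strain_energy(four_fiber_params(c = 10), s), 4.99321,
               tolerance = 1e-5)

  # single circumferential family: W = c1/(4 c2) (exp(c2 (IV-1)^2) - 1)
  p <- four_fiber_params(c1_circ = 1, c2_circ = 1)
  expect_equal(strain_energy(p, deformation_from_stretches(1.1, 1)),
               0.25 * (exp(0.21^2) - 1), tolerance = 1e-12)
  expect_equal(strain_energy(p, deformation_from_stretches(1.1, 1)),
               0.011272, tolerance = 1e-4)
})

test_that("the c2 -> 0 family limit is the exact quadratic, not 0/0", {
  s <- deformation_from_stretches(1.3, 1.1)
  q <- 1.3^2 - 1
  p0 <- four_fiber_params(c1_circ = 7, c2_circ = 0)
  expect_equal(strain_energy(p0, s), 7 / 4 * q^2, tolerance = 1e-12)
  # continuity across the switch threshold
  peps <- four_fiber_params(c1_circ = 7, c2_circ = 1e-9)
  pabove <- four_fiber_params(c1_circ = 7, c2_circ = 1e-7)
  expect_equal(strain_energy(peps, s), strain_energy(p0, s), tolerance = 1e-8)
  expect_equal(strain_energy(pabove, s), strain_energy(p0, s), tolerance = 1e-6)
})

test_that("energy is non-negative for admissible inputs", {
  set.seed(4)
  for (k in 1:50) {
    W <- strain_energy(rand_params(), rand_state())
    expect_gte(W, 0)
  }
})

test_that("Cauchy stress matches the isotropic closed form and is zero at identity", {
  id <- deformation_from_stretches(1, 1)
  set.seed(5)
  for (k in 1:10)
    expect_equal(unname(cauchy_stress(rand_params(), id)), c(0, 0),
                 tolerance = 1e-14)

  s <- deformation_from_stretches(1.2, 1.5)
  sig <- cauchy_stress(four_fiber_params(c = 10), s)
  expect_equal(sig[["sigma_theta"]], 10 * (1.2^2 - s$lam_r^2), tolerance = 1e-12)
  expect_equal(sig[["sigma_theta"]], 11.3136, tolerance = 1e-4)
  expect_equal(sig[["sigma_z"]], 19.4136, tolerance = 1e-4)
})

test_that("Cauchy stress agrees with the energy-derivative oracle", {
  set.seed(6)
  for (k in 1:30) {
    p <- rand_params(); s <- rand_state()
    got <- cauchy_stress(p, s)
    want <- fd_stress(p, s$lam_theta, s$lam_z)
    expect_equal(unname(got), unname(want),
                 tolerance = 1e-6 * max(1, max(abs(want))))
  }
})

test_that("stiffness agrees with both finite-difference assembly routes", {
  set.seed(7)
  for (k in 1:30) {
    p <- rand_params(); s <- rand_state()
    got <- material_stiffness(p, s)
    a <- fd_stiffness_stress_route(p, s$lam_theta, s$lam_z)
    b <- fd_stiffness_energy_route(p, s$lam_theta, s$lam_z)
    scale <- max(1, max(abs(got)))
    expect_equal(unname(got), unname(a), tolerance = 1e-4 * scale)
    expect_equal(unname(got), unname(b), tolerance = 1e-4 * scale)
  }
})

test_that("stiffness symmetries hold", {
  # isotropic material at identity: theta <-> z symmetry
  st <- material_stiffness(four_fiber_params(c = 10),
                           deformation_from_stretches(1, 1))
  expect_equal(st[["C_tttt"]], st[["C_zzzz"]], tolerance = 1e-12)

  # minor symmetry C_ttzz = C_zztt: the theta-z coupling must be identical
  # whether probed through sigma_theta vs lam_z or sigma_z vs lam_theta
  set.seed(8)
  for (k in 1:10) {
    p <- rand_params(); s <- rand_state()
    h <- 1e-6
    dz <- (cauchy_stress(p, deformation_from_stretches(s$lam_theta, s$lam_z + h))[["sigma_theta"]] -
             cauchy_stress(p, deformation_from_stretches(s$lam_theta, s$lam_z - h))[["sigma_theta"]]) / (2 * h)
    dt <- (cauchy_stress(p, deformation_from_stretches(s$lam_theta + h, s$lam_z))[["sigma_z"]] -
             cauchy_stress(p, deformation_from_stretches(s$lam_theta - h, s$lam_z))[["sigma_z"]]) / (2 * h)
    expect_equal(s$lam_z * dz, s$lam_theta * dt,
                 tolerance = 1e-5 * max(1, abs(s$lam_z * dz)))
  }
})

test_that("circumferential stiffness is non-decreasing in lam_theta for a
           circumferentially dominated material", {
  p <- four_fiber_params(c = 5, c1_circ = 20, c2_circ = 1.5)
  lt <- seq(1, 1.8, by = 0.05)
  Ct <- vapply(lt, function(l)
    material_stiffness(p, deformation_from_stretches(l, 1.3))[["C_tttt"]],
    numeric(1))
  expect_true(all(diff(Ct) >= 0))
})
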