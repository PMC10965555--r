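test_that("simulated protocols are seed-deterministic and window-respecting", {
  sp <- simulation_spec(seed = 81)  # default (noisy) noise model
  r1 <- simulate_subject(sp, "d-01")
  r2 <- simulate_subject(sp, "d-01")
  expect_identical(r1$data, r2$data)

  fl <- r1$data[startsWith(r1$data$protocol, "fl"), ]
  # the force window is enforced before noise; allow the noise margin only
  expect_true(all(fl$axial_force_g >= -0.5 - 4 * 0.02 * 5))
  expect_true(all(fl$axial_force_g <= 5 + 4 * 0.02 * 5))

  spz <- noisefree_spec(seed = 81)
  flz <- simulate_subject(spz, "d-02")$data
  flz <- flz[startsWith(flz$protocol, "fl"), ]
  expect_true(all(flz$axial_force_g >= -0.5 & flz$axial_force_g <= 5))
})

test_that("force-length curves cross at the spec's in-vivo stretch", {
  sp <- noisefree_spec(seed = 82)
  # least-squares slope of the interpolated force against pressure at a
  # given stretch; zero at the force-invariance point by definition
  slope_at <- function(lam_z) {
    P <- c(10, 60, 100, 140)
    f <- vapply(P, function(p) {
      d <- simulate_fl_protocol(sp, p)
      d <- d[d$cycle == 2, ]
      approx(d$axial_length_mm / sp$geometry$L, d$axial_force_g,
             xout = lam_z)$y
    }, numeric(1))
    unname(coef(lm(f ~ P))[2])
  }
  s_lo <- slope_at(sp$lam_z_iv * 0.95)
  s_iv <- slope_at(sp$lam_z_iv)
  s_hi <- slope_at(sp$lam_z_iv * 1.05)
  expect_lt(s_lo, 0)
  expect_gt(s_hi, 0)
  expect_lt(abs(s_iv), 0.1 * min(abs(s_lo), abs(s_hi)))
})

test_that("zero-noise simulator output reproduces constitutive stresses", {
  sp <- noisefree_spec(seed = 83)
  red <- reduce_record(simulate_subject(sp, "d-03"))
  th <- aortamech:::.ffp_to_vec(sp$params)
  s <- aortamech:::.stress_vec(th, red$lam_theta, red$lam_z)
  expect_equal(red$sigma_theta, unname(s[, 1]), tolerance = 1e-6)
  expect_equal(red$sigma_z, unname(s[, 2]), tolerance = 1e-6)
  # thin-wall regime holds for the default fixture at physiologic pressures
  pd <- red[startsWith(as.character(red$protocol), "pd") &
              red$pressure_mmHg >= 60, ]
  expect_true(all(pd$h_um / pd$ri_um <= 0.08))
})

test_that("refining the pressure grid leaves fitted parameters unchanged", {
  cfg <- fit_config(seed = 5, n_starts = 6)
  sp1 <- noisefree_spec(seed = 84)
  sp2 <- noisefree_spec(seed = 84, pressure_grid = seq(10, 140, by = 2.5))
  f1 <- fit_parameters(simulate_subject(sp1, "g-01"), cfg)
  f2 <- fit_parameters(simulate_subject(sp2, "g-02"), cfg)
  for (nm in c("c", "c1_diag", "alpha0"))
    expect_equal(f1$par[[nm]], f2$par[[nm]], tolerance = 1e-3 * max(1, f1$par[[nm]]),
                 label = nm)
})

test_that("cohort simulation is reproducible and honours dilatation multipliers", {
  specs <- list(WT = noisefree_spec(seed = 1))
  c1 <- simulate_cohort(specs, n_per_group = 4, seed = 9, records = FALSE)
  c2 <- simulate_cohort(specs, n_per_group = 4, seed = 9, records = FALSE)
  expect_identical(c1$metadata, c2$metadata)

  # a 1.6x dilatation multiplier pushes a subgroup past the aneurysm threshold
  set.seed(91)
  healthy <- simulate_allometric_cohort(200, s_log = 0.04)
  m <- fit_allometric(healthy$body_mass_g, healthy$di_um)
  dil <- simulate_allometric_cohort(50, s_log = 0.01, multiplier = 1.6)
  st <- classify_vessel(m, dil$body_mass_g, dil$di_um)$status
  expect_true(all(st == "aneurysmal"))

  # scaled-geometry records hit their target systolic diameter exactly
  c3 <- simulate_cohort(specs, n_per_group = 2, seed = 9, records = TRUE)
  for (i in 1:2) {
    rec <- c3$records[[i]]
    fitm <- compute_invivo_metrics(specs$WT$params, rec,
                                   lam_z_iv = specs$WT$lam_z_iv)
    expect_equal(fitm$di_sys, c3$metadata$di_true_um[i],
                 tolerance = 1e-6 * fitm$di_sys)
  }
})
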