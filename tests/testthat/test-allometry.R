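test_that("log-log OLS recovers an exact power law to full precision", {
  bm <- seq(15, 35, length.out = 56)
  m <- fit_allometric(bm, 671.7862 * bm^0.2816)
  expect_equal(m$beta, 0.2816, tolerance = 1e-7)
  expect_equal(m$alpha, 671.7862, tolerance = 1e-6 * 671.7862)
  expect_equal(m$s_log, 0, tolerance = 1e-10)
  expect_equal(m$n, 56)

  # constant diameters: beta = 0, alpha = the diameter
  m0 <- fit_allometric(bm, rep(1500, 56))
  expect_equal(m0$beta, 0, tolerance = 1e-12)
  expect_equal(m0$alpha, 1500, tolerance = 1e-9)

  # rescaling diameters scales alpha, leaves beta and classification alone
  mk <- fit_allometric(bm, 2 * 671.7862 * bm^0.2816)
  expect_equal(mk$beta, m$beta, tolerance = 1e-10)
  expect_equal(mk$alpha, 2 * m$alpha, tolerance = 1e-6 * m$alpha)

  expect_error(fit_allometric(bm, -bm), "positive")
  expect_error(fit_allometric(1:2, 1:2), "at least 3")
})

test_that("normalized diameter is unit-invariant", {
  set.seed(61)
  coh <- simulate_allometric_cohort(40, s_log = 0.04)
  m_um <- fit_allometric(coh$body_mass_g, coh$di_um)
  m_mm <- fit_allometric(coh$body_mass_g, coh$di_um / 1000)
  q <- c(20, 28)
  d <- predict(m_um, q) * 1.2
  expect_equal(classify_vessel(m_um, q, d)$normalized_diameter,
               classify_vessel(m_mm, q, d / 1000)$normalized_diameter,
               tolerance = 1e-10)
})

test_that("classification boundary sits exactly at the prediction bound", {
  set.seed(62)
  coh <- simulate_allometric_cohort(60, s_log = 0.05)
  m <- fit_allometric(coh$body_mass_g, coh$di_um)
  bm <- 26
  x <- log(bm)
  lev <- 1 / m$n + (x - m$mean_logbm)^2 / m$sxx
  upper <- predict(m, bm) * exp(qnorm(0.975) * m$s_log * sqrt(1 + lev))
  eps <- 1e-9
  expect_equal(as.character(classify_vessel(m, bm, upper * (1 + eps))$status),
               "dilated")
  expect_equal(as.character(classify_vessel(m, bm, upper * (1 - eps))$status),
               "normal")

  # on-curve vessel is normal with normalized diameter 1
  cls <- classify_vessel(m, bm, predict(m, bm))
  expect_equal(cls$normalized_diameter, 1, tolerance = 1e-12)
  expect_equal(as.character(cls$status), "normal")

  # normalized diameter 1.6 with small scatter: aneurysmal
  cls <- classify_vessel(m, bm, 1.6 * predict(m, bm))
  expect_equal(as.character(cls$status), "aneurysmal")

  # monotone in diameter at fixed mass
  di <- predict(m, bm) * seq(0.9, 1.8, by = 0.05)
  st <- classify_vessel(m, rep(bm, length(di)), di)$status
  expect_true(all(diff(as.integer(st)) >= 0))

  # lower-tail outlier is flagged small, never dilated
  lower <- predict(m, bm) * exp(-qnorm(0.975) * m$s_log * sqrt(1 + lev))
  cls <- classify_vessel(m, bm, lower * 0.98)
  expect_true(cls$small)
  expect_equal(as.character(cls$status), "normal")
})

test_that("a healthy cohort triggers the dilated call at the nominal 2.5% rate", {
  set.seed(63)
  coh <- simulate_allometric_cohort(2000, s_log = 0.04)
  m <- fit_allometric(coh$body_mass_g, coh$di_um)
  cls <- classify_vessel(m, coh$body_mass_g, coh$di_um)
  frac <- mean(cls$status != "normal")
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.035)
})
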