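test_that("Spearman rs matches hand evaluations and basic identities", {
  r <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rs, 0.8, tolerance = 1e-12)

  # strictly monotone pair
  expect_equal(spearman_cor(1:6, exp(1:6))$rs, 1)

  set.seed(71)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(spearman_cor(x, y)$rs, spearman_cor(y, x)$rs)
  expect_equal(spearman_cor(x, -y)$rs, -spearman_cor(x, y)$rs)
  # invariance under strictly monotone transforms
  expect_equal(spearman_cor(exp(x), y)$rs, spearman_cor(x, y)$rs)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rs, spearman_cor(x, y)$rs)

  # mid-ranks for ties: agreement with the base-R reference implementation
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 7)
  expect_equal(spearman_cor(xt, yt)$rs,
               suppressWarnings(stats::cor.test(xt, yt, method = "spearman")$estimate[[1]]),
               tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant input")
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
})

test_that("exact permutation p agrees with an independent enumeration oracle", {
  set.seed(72)
  for (k in 1:10) {
    n <- sample(5:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    got <- spearman_cor(x, y, method = "exact")
    want <- oracle_spearman_perm_p(x, y)
    expect_equal(got$rs, want$rs, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("t approximation agrees with enumeration in rejection decisions at n 7-8", {
  set.seed(73)
  agree <- vapply(1:50, function(k) {
    n <- sample(7:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    pt_ <- spearman_cor(x, y, method = "t")$p_value
    pex <- spearman_cor(x, y, method = "exact")$p_value
    (pt_ < 0.05) == (pex < 0.05)
  }, logical(1))
  expect_true(all(agree))
})

test_that("strength labels partition [-1, 1] with inclusive boundaries", {
  expect_equal(correlation_strength(0.842), "strong")
  expect_equal(correlation_strength(-0.561), "moderate")
  expect_equal(correlation_strength(-0.328), "mild")
  expect_equal(correlation_strength(0.5), "mild")
  expect_equal(correlation_strength(0.75), "moderate")
  expect_equal(correlation_strength(-0.75), "moderate")
  expect_equal(correlation_strength(1), "strong")
  expect_equal(correlation_strength(0), "none")
  grid <- seq(-1, 1, by = 0.001)
  expect_false(anyNA(correlation_strength(grid)))
  expect_error(correlation_strength(1.2), "<= 1")
})

test_that("group summary computes mean and SEM with singleton handling", {
  d <- data.frame(genotype = c("WT", "WT", "WT", "dMut"),
                  m = c(1, 2, 3, 7))
  g <- group_summary(d, metrics = "m")
  wt <- g[g$group == "WT", ]
  expect_equal(wt$mean, 2)
  expect_equal(wt$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(wt$sem, 0.5774, tolerance = 1e-4)
  expect_true(is.na(g$sem[g$group == "dMut"]))

  # identical values: SEM exactly zero; row order irrelevant
  d2 <- data.frame(genotype = rep("WT", 4), m = rep(3, 4))
  expect_equal(group_summary(d2, metrics = "m")$sem, 0)
  dperm <- d[c(4, 2, 1, 3), ]
  expect_equal(group_summary(dperm, metrics = "m"), g)
})
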