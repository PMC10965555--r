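# Independent finite-difference oracles and random-case generators.
# These deliberately avoid the package's analytic derivative code paths:
# everything here differentiates strain_energy() numerically.

# reduced energy What(lam_theta, lam_z) with incompressibility built in
.What <- function(params, lt, lz) {
  strain_energy(params, deformation_from_stretches(lt, lz))
}

# stress oracle: sigma_theta = lam_theta dWhat/dlam_theta (central difference)
fd_stress <- function(params, lt, lz, h = 1e-6) {
  c(sigma_theta = lt * (.What(params, lt + h, lz) - .What(params, lt - h, lz)) / (2 * h),
    sigma_z = lz * (.What(params, lt, lz + h) - .What(params, lt, lz - h)) / (2 * h))
}

# stiffness oracle, route (a): finite differences of cauchy_stress with
# respect to small superposed biaxial stretches
fd_stiffness_stress_route <- function(params, lt, lz, h = 1e-6) {
  s_tp <- cauchy_stress(params, deformation_from_stretches(lt + h, lz))
  s_tm <- cauchy_stress(params, deformation_from_stretches(lt - h, lz))
  s_zp <- cauchy_stress(params, deformation_from_stretches(lt, lz + h))
  s_zm <- cauchy_stress(params, deformation_from_stretches(lt, lz - h))
  c(C_tttt = lt * (s_tp[["sigma_theta"]] - s_tm[["sigma_theta"]]) / (2 * h),
    C_zzzz = lz * (s_zp[["sigma_z"]] - s_zm[["sigma_z"]]) / (2 * h),
    C_ttzz = lz * (s_zp[["sigma_theta"]] - s_zm[["sigma_theta"]]) / (2 * h))
}

# stiffness oracle, route (b): assemble the small-on-large components from
# second-order finite differences of the reduced energy in x = lam_theta^2,
# y = lam_z^2 (stress terms also from first-order energy differences)
fd_stiffness_energy_route <- function(params, lt, lz, h = 1e-4) {
  x <- lt^2; y <- lz^2
  W <- function(x, y) .What(params, sqrt(x), sqrt(y))
  Wx <- (W(x + h, y) - W(x - h, y)) / (2 * h)
  Wy <- (W(x, y + h) - W(x, y - h)) / (2 * h)
  Wxx <- (W(x + h, y) - 2 * W(x, y) + W(x - h, y)) / h^2
  Wyy <- (W(x, y + h) - 2 * W(x, y) + W(x, y - h)) / h^2
  Wxy <- (W(x + h, y + h) - W(x + h, y - h) - W(x - h, y + h) + W(x - h, y - h)) /
    (4 * h^2)
  c(C_tttt = 2 * (2 * x * Wx) + 4 * x^2 * Wxx,
    C_zzzz = 2 * (2 * y * Wy) + 4 * y^2 * Wyy,
    C_ttzz = 4 * x * y * Wxy)
}

# random admissible parameter sets and states (moderate exponents keep the
# finite-difference oracles in their accurate range)
rand_params <- function() {
  four_fiber_params(c = runif(1, 1, 30),
                    c1_axial = runif(1, 0, 30), c2_axial = runif(1, 0.01, 2),
                    c1_circ = runif(1, 0, 30), c2_circ = runif(1, 0.01, 2),
                    c1_diag = runif(1, 0, 30), c2_diag = runif(1, 0.01, 2),
                    alpha0 = runif(1, 20, 70))
}

rand_state <- function() {
  deformation_from_stretches(runif(1, 0.8, 1.6), runif(1, 0.8, 1.6))
}

# default synthetic fixtures shared across test files
default_geom <- function() vessel_geometry(540, 90, 4)

noisefree_spec <- function(genotype = "WT", age_weeks = 12, seed = 1L, ...) {
  simulation_spec(genotype, age_weeks, noise = noise_model(0, 0, 0),
                  seed = seed, ...)
}

# independent permutation enumeration for the Spearman oracle: builds
# permutations by successive insertion (distinct from the package's
# lexicographic recursion) and uses the classical 1 - 6 sum(d^2)/(n(n^2-1))
# formula, valid for the tie-free draws used in tests
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  perms <- list(1L)
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p)
      lapply(0:(k - 1), function(pos) append(p, k, after = pos))),
      recursive = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rs_obs <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  rs_all <- vapply(perms, function(p)
    1 - 6 * sum((rx - ry[p])^2) / (n * (n^2 - 1)), numeric(1))
  list(rs = rs_obs, p = mean(abs(rs_all) >= abs(rs_obs) - 1e-12))
}
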