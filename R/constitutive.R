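# Constitutive law: stored energy, Cauchy stress, and small-on-large stiffness
# for the incompressible four-fiber-family material.
#
# Internal work is fully vectorised over (lam_theta, lam_z) pairs with the
# parameter 8-vector layout of .ffp_to_vec(); the exported functions wrap
# single (params, state) evaluations around these kernels.

# squared direction cosines of the four families against theta (s2) and z
# (k2), with k2 = 1 - s2 enforced so that the invariant excess
# q = (lam_theta^2 - 1) s2 + (lam_z^2 - 1) k2 is exactly zero at identity
.fiber_weights <- function(alpha0_deg) {
  s2d <- sin(alpha0_deg * pi / 180)^2
  list(s2 = c(0, 1, s2d, s2d),
       k2 = c(1, 0, 1 - s2d, 1 - s2d))
}

# Stored energy density (kPa). The c2 -> 0 limit of a family term is the exact
# quadratic (c1/4) q^2 (1 + c2 q^2 / 2 + ...); switching below 1e-8 avoids 0/0
# for parameter sets whose exponents are printed at ~1e-14.
.energy_vec <- function(th, lt, lz) {
  n <- max(length(lt), length(lz))
  lt <- rep_len(lt, n); lz <- rep_len(lz, n)
  lr2 <- 1 / (lt * lz)^2
  W <- th[1] / 2 * (lt^2 + lz^2 + lr2 - 3)
  w <- .fiber_weights(th[8])
  c1 <- th[c(2, 4, 6, 6)]
  c2 <- th[c(3, 5, 7, 7)]
  for (i in 1:4) {
    if (c1[i] == 0) next
    q <- (lt^2 - 1) * w$s2[i] + (lz^2 - 1) * w$k2[i]   # IV_i - 1
    W <- W + if (c2[i] < 1e-8) {
      c1[i] / 4 * q^2 * (1 + 0.5 * c2[i] * q^2)
    } else {
      c1[i] / (4 * c2[i]) * expm1(c2[i] * q^2)
    }
  }
  W
}

# In-plane Cauchy stress (kPa), Lagrange multiplier eliminated via sigma_rr = 0.
# Returns cbind(sigma_theta, sigma_z).
.stress_vec <- function(th, lt, lz) {
  n <- max(length(lt), length(lz))
  lt <- rep_len(lt, n); lz <- rep_len(lz, n)
  lr2 <- 1 / (lt * lz)^2
  st <- th[1] * (lt^2 - lr2)
  sz <- th[1] * (lz^2 - lr2)
  w <- .fiber_weights(th[8])
  c1 <- th[c(2, 4, 6, 6)]
  c2 <- th[c(3, 5, 7, 7)]
  for (i in 1:4) {
    if (c1[i] == 0) next
    q <- (lt^2 - 1) * w$s2[i] + (lz^2 - 1) * w$k2[i]   # IV_i - 1
    g <- c1[i] * q * exp(c2[i] * q^2)   # 2 dW/dIV_i
    st <- st + g * lt^2 * w$s2[i]
    sz <- sz + g * lz^2 * w$k2[i]
  }
  cbind(sigma_theta = st, sigma_z = sz)
}

# Small-on-large stiffness components (kPa) at a finite biaxial deformation.
# With x = lam_theta^2, y = lam_z^2 and What(x, y) the incompressibility-reduced
# energy (C_rr = 1/(x y) substituted), the in-plane normal stresses are
# sigma_theta = 2 x What_x, sigma_z = 2 y What_y, and the linearised moduli are
#   C_tttt = 2 sigma_theta + 4 x^2 What_xx
#   C_zzzz = 2 sigma_z     + 4 y^2 What_yy
#   C_ttzz =                 4 x y What_xy
# Returns cbind(C_tttt, C_zzzz, C_ttzz).
.stiffness_vec <- function(th, lt, lz) {
  n <- max(length(lt), length(lz))
  lt <- rep_len(lt, n); lz <- rep_len(lz, n)
  x <- lt^2; y <- lz^2
  s <- .stress_vec(th, lt, lz)
  Wxx <- th[1] / (x^3 * y)
  Wyy <- th[1] / (x * y^3)
  Wxy <- th[1] / (2 * x^2 * y^2)
  w <- .fiber_weights(th[8])
  c1 <- th[c(2, 4, 6, 6)]
  c2 <- th[c(3, 5, 7, 7)]
  for (i in 1:4) {
    if (c1[i] == 0) next
    q <- (x - 1) * w$s2[i] + (y - 1) * w$k2[i]   # IV_i - 1
    gp <- c1[i] / 2 * exp(c2[i] * q^2) * (1 + 2 * c2[i] * q^2)  # d2W/dIV^2
    Wxx <- Wxx + gp * w$s2[i]^2
    Wyy <- Wyy + gp * w$k2[i]^2
    Wxy <- Wxy + gp * w$s2[i] * w$k2[i]
  }
  cbind(C_tttt = 2 * s[, 1] + 4 * x^2 * Wxx,
        C_zzzz = 2 * s[, 2] + 4 * y^2 * Wyy,
        C_ttzz = 4 * x * y * Wxy)
}

#' Stored energy density of the four-fiber-family material
#'
#' `W = (c/2)(I_C - 3) + sum_i c1_i/(4 c2_i) (exp(c2_i (IV_i - 1)^2) - 1)`,
#' in kPa, evaluated at an incompressible biaxial deformation. Families with
#' `c1_i = 0` contribute exactly zero; the `c2_i -> 0` limit of a family term
#' is the quadratic `(c1_i/4)(IV_i - 1)^2`, implemented explicitly.
#'
#' @param params A [four_fiber_params()] set.
#' @param state A [deformation_from_stretches()] state.
#' @return Energy density in kPa (0 at the reference configuration).
#' @examples
#' p <- four_fiber_params(c = 10)
#' strain_energy(p, deformation_from_stretches(1.2, 1.5))
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "four_fiber_params"),
            inherits(state, "deformation_state"))
  as.numeric(.energy_vec(.ffp_to_vec(params), state$lam_theta, state$lam_z))
}

#' In-plane Cauchy stress under the membrane assumption
#'
#' Evaluates `sigma = -p I + 2 F (dW/dC) t(F)` with the Lagrange multiplier
#' `p` fixed by the traction condition `sigma_rr = 0` (thin-walled membrane).
#' Shear components vanish identically: the two diagonal families are mirror
#' images about the axis, so their in-plane shears cancel.
#'
#' @inheritParams strain_energy
#' @return Named numeric vector `c(sigma_theta, sigma_z)` in kPa.
#' @examples
#' p <- four_fiber_params(c = 10)
#' cauchy_stress(p, deformation_from_stretches(1.2, 1.5))
#' # sigma_theta = c (lam_theta^2 - lam_r^2) for the purely isotropic material
#' @export
cauchy_stress <- function(params, state) {
  stopifnot(inherits(params, "four_fiber_params"),
            inherits(state, "deformation_state"))
  drop(.stress_vec(.ffp_to_vec(params), state$lam_theta, state$lam_z)[1, ])
}

#' Small-on-large linearized stiffness
#'
#' Components of the elasticity tensor for small deformations superposed on a
#' finite biaxial state,
#' `C_ijkl = sigma_il d_jk + sigma_lj d_ik + 4 F_iI F_jJ F_kK F_lL d2What/dC_IJ dC_KL`,
#' where `What` is the stored energy with incompressibility enforced
#' (`C_rr = 1/(C_thth C_zz)`). Returns the circumferential, axial, and
#' coupling components used to summarise wall stiffness at in-vivo loads.
#'
#' @inheritParams strain_energy
#' @return Named numeric vector `c(C_tttt, C_zzzz, C_ttzz)` in kPa.
#' @export
material_stiffness <- function(params, state) {
  stopifnot(inherits(params, "four_fiber_params"),
            inherits(state, "deformation_state"))
  drop(.stiffness_vec(.ffp_to_vec(params), state$lam_theta, state$lam_z)[1, ])
}
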