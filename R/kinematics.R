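#' Biaxial deformation state of an incompressible vessel wall
#'
#' Builds the kinematic state for a membrane element of artery wall under
#' combined circumferential stretch `lam_theta` and axial stretch `lam_z`.
#' The radial stretch follows from incompressibility (`det F = 1`):
#' `lam_r = 1/(lam_theta * lam_z)`. The deformation gradient is
#' `F = diag(lam_r, lam_theta, lam_z)` in cylindrical coordinates
#' `(r, theta, z)`, and `C = t(F) F` is the right Cauchy-Green tensor.
#'
#' @param lam_theta Circumferential stretch, `> 0`.
#' @param lam_z Axial stretch, `> 0`.
#' @return Object of class `deformation_state`: list with `lam_theta`,
#'   `lam_z`, `lam_r`, `F` (3x3), `C` (3x3), and the first invariant `I_C`.
#' @examples
#' s <- deformation_from_stretches(1.2, 1.5)
#' s$lam_r       # 1/(1.2*1.5)
#' s$I_C         # tr(C)
#' @export
deformation_from_stretches <- function(lam_theta, lam_z) {
  if (!is.finite(lam_theta) || lam_theta <= 0)
    stop("deformation_from_stretches: lam_theta must be > 0, got ", lam_theta)
  if (!is.finite(lam_z) || lam_z <= 0)
    stop("deformation_from_stretches: lam_z must be > 0, got ", lam_z)
  lam_r <- 1 / (lam_theta * lam_z)
  F <- diag(c(lam_r, lam_theta, lam_z))
  C <- diag(c(lam_r^2, lam_theta^2, lam_z^2))
  structure(list(lam_theta = lam_theta, lam_z = lam_z, lam_r = lam_r,
                 F = F, C = C, I_C = sum(diag(C))),
            class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf(
    "Deformation state: lam_theta = %.6g, lam_z = %.6g, lam_r = %.6g, I_C = %.6g\n",
    x$lam_theta, x$lam_z, x$lam_r, x$I_C))
  invisible(x)
}

#' Fourth (fiber) invariants of a deformation state
#'
#' `IV_i = M_i . C M_i` is the squared stretch along fiber family `i`, for the
#' family directions `M_i = (0, sin a_i, cos a_i)` implied by a parameter set.
#' Equals 1 for every family in the reference configuration.
#'
#' @param state A [deformation_from_stretches()] state.
#' @param params A [four_fiber_params()] set (only the angles are used).
#' @return Numeric length-4 vector (axial, circumferential, diagonal +, diagonal -).
#' @export
fourth_invariants <- function(state, params) {
  s2 <- sin(params$angles_deg * pi / 180)^2
  1 + (state$lam_theta^2 - 1) * s2 + (state$lam_z^2 - 1) * (1 - s2)
}
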