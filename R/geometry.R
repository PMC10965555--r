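#' Unloaded vessel geometry
#'
#' Traction-free reference geometry of an excised aortic segment: outer
#' radius, wall thickness (both micrometres), and axial length (millimetres).
#'
#' @param Ro_um Unloaded outer radius (um), `> 0`.
#' @param H_um Unloaded wall thickness (um), `0 < H < Ro`.
#' @param L_mm Unloaded axial length (mm), `> 0`.
#' @return Object of class `vessel_geometry` with fields `Ro`, `H`, `L`,
#'   derived inner radius `Ri = Ro - H` and mid-wall radius `Rm`.
#' @export
vessel_geometry <- function(Ro_um, H_um, L_mm) {
  if (!is.finite(Ro_um) || Ro_um <= 0) stop("vessel_geometry: Ro_um must be > 0")
  if (!is.finite(H_um) || H_um <= 0 || H_um >= Ro_um)
    stop("vessel_geometry: need 0 < H_um < Ro_um")
  if (!is.finite(L_mm) || L_mm <= 0) stop("vessel_geometry: L_mm must be > 0")
  structure(list(Ro = Ro_um, H = H_um, L = L_mm,
                 Ri = Ro_um - H_um, Rm = Ro_um - H_um / 2),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry: Ro = %.4g um, H = %.4g um (Ri = %.4g um), L = %.4g mm\n",
              x$Ro, x$H, x$Ri, x$L))
  invisible(x)
}

#' Loaded wall geometry from a measured outer diameter
#'
#' Inverts incompressible volume conservation for the deformed inner radius
#' and thickness given the acquired outer diameter and axial stretch:
#' `ri = sqrt((od/2)^2 - (Ro^2 - Ri^2)/lam_z)`, `h = od/2 - ri`. Wall volume
#' `pi (ro^2 - ri^2) l` is conserved exactly relative to the unloaded state.
#'
#' @param geom A [vessel_geometry()].
#' @param od_um Measured outer diameter (um); may be a vector.
#' @param lam_z Axial stretch (current length / unloaded length).
#' @return List with vectors `ri`, `h` (um). A negative radicand means the
#'   (od, lam_z) pair is volumetrically impossible and raises an
#'   inconsistent-measurement error.
#' @export
current_geometry <- function(geom, od_um, lam_z) {
  stopifnot(inherits(geom, "vessel_geometry"))
  ro <- od_um / 2
  rad <- ro^2 - (geom$Ro^2 - geom$Ri^2) / lam_z
  if (any(rad < 0))
    stop("current_geometry: inconsistent measurement (outer diameter too small ",
         "for incompressible wall at lam_z = ", signif(lam_z[which(rad < 0)[1]], 4), ")")
  ri <- sqrt(rad)
  list(ri = ri, h = ro - ri)
}

#' Loaded wall geometry from mid-wall stretches (forward map)
#'
#' Maps a mid-wall circumferential stretch and axial stretch to the deformed
#' annulus: `r_mid = lam_theta * Rm`, thickness from incompressibility
#' `h = (Ro^2 - Ri^2)/(2 r_mid lam_z)`, `ri = r_mid - h/2`. Exact inverse of
#' [current_geometry()] composed with [circumferential_stretch()].
#'
#' @inheritParams current_geometry
#' @param lam_theta Mid-wall circumferential stretch; may be a vector.
#' @return List with vectors `ri`, `h`, `ro`, `od` (um).
#' @export
deformed_geometry <- function(geom, lam_theta, lam_z) {
  stopifnot(inherits(geom, "vessel_geometry"))
  rm <- lam_theta * geom$Rm
  h <- (geom$Ro^2 - geom$Ri^2) / (2 * rm * lam_z)
  ri <- rm - h / 2
  if (any(ri <= 0))
    stop("deformed_geometry: collapse (inner radius <= 0) at lam_theta = ",
         signif(lam_theta[which(ri <= 0)[1]], 4))
  list(ri = ri, h = h, ro = rm + h / 2, od = 2 * (rm + h / 2))
}

#' Mid-wall circumferential stretch from loaded geometry
#'
#' @inheritParams current_geometry
#' @param ri_um,h_um Deformed inner radius and thickness (um).
#' @return `lam_theta = (ri + h/2) / Rm`.
#' @export
circumferential_stretch <- function(geom, ri_um, h_um) {
  stopifnot(inherits(geom, "vessel_geometry"))
  (ri_um + h_um / 2) / geom$Rm
}

#' Mean wall stress from pressure, axial force, and loaded geometry
#'
#' Laplace / mean-wall equilibrium for a pressurised cylinder:
#' `sigma_theta = P ri / h` and
#' `sigma_z = (f + P pi ri^2) / (pi h (2 ri + h))`,
#' with the transducer units (mmHg, gram-force) converted internally to kPa
#' and mN.
#'
#' @param P_mmhg Luminal pressure (mmHg).
#' @param f_g Axial force (gram-force).
#' @param ri_um,h_um Deformed inner radius and wall thickness (um).
#' @return Named list with vectors `sigma_theta`, `sigma_z` (kPa).
#' @examples
#' experimental_wall_stress(100, 1.0, 600, 40)
#' @export
experimental_wall_stress <- function(P_mmhg, f_g, ri_um, h_um) {
  if (any(ri_um <= 0) || any(h_um <= 0))
    stop("experimental_wall_stress: ri and h must be > 0")
  P <- mmhg_to_kpa(P_mmhg)
  f <- gf_to_mn(f_g)
  ri <- ri_um / 1000  # mm; kPa * mm^2 = mN
  h <- h_um / 1000
  list(sigma_theta = P * ri / h,
       sigma_z = (f + P * pi * ri^2) / (pi * h * (2 * ri + h)))
}

# inverse of the axial equilibrium: force (gram) that equilibrates the given
# wall stresses at pressure P (mmHg) and geometry (um)
.axial_force_g <- function(sigma_z_kpa, P_mmhg, ri_um, h_um) {
  P <- mmhg_to_kpa(P_mmhg)
  ri <- ri_um / 1000; h <- h_um / 1000
  mn_to_gf(sigma_z_kpa * pi * h * (2 * ri + h) - P * pi * ri^2)
}
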