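# Structural response and derived in-vivo metrics at diastole (80 mmHg) and
# systole (120 mmHg).

# vectorised luminal pressure (mmHg) equilibrating the wall at given stretches
.eq_pressure_vec <- function(th, geom, lt, lz) {
  g <- deformed_geometry(geom, lt, lz)
  s <- .stress_vec(th, lt, lz)
  kpa_to_mmhg(s[, 1] * g$h / g$ri)
}

#' Equilibrium luminal pressure at a given biaxial deformation
#'
#' Closes the constitutive law into a structural response through thin-wall
#' hoop equilibrium: `P = sigma_theta * h / ri`, with the loaded geometry
#' `(ri, h)` from incompressible volume conservation at the given mid-wall
#' stretches. Exact inverse of the hoop relation in
#' [experimental_wall_stress()].
#'
#' @param params A [four_fiber_params()] set.
#' @param geom A [vessel_geometry()].
#' @param lam_theta Mid-wall circumferential stretch (vectorised).
#' @param lam_z Axial stretch.
#' @return Pressure in mmHg.
#' @export
equilibrium_pressure <- function(params, geom, lam_theta, lam_z) {
  stopifnot(inherits(params, "four_fiber_params"))
  as.numeric(.eq_pressure_vec(.ffp_to_vec(params), geom, lam_theta, lam_z))
}

# root-find lam_theta for one target pressure; th is the parameter 8-vector
.lam_theta_at_pressure <- function(th, geom, P_mmhg, lam_z,
                                   interval = c(0.5, 3)) {
  f <- function(lt) tryCatch(.eq_pressure_vec(th, geom, lt, lam_z) - P_mmhg,
                             error = function(e) NA_real_)
  lo <- interval[1]; hi <- interval[2]
  # exponential fiber terms can overflow near the upper bracket, and the wall
  # collapses (ri <= 0) near the lower one: shrink the bracket until evaluable
  while (hi > lo && !is.finite(f(hi))) hi <- lo + 0.9 * (hi - lo)
  while (lo < hi && !is.finite(f(lo))) lo <- hi - 0.9 * (hi - lo)
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("state_at_pressure: no solution - pressure ", P_mmhg,
         " mmHg not bracketed by lam_theta in [", lo, ", ", signif(hi, 4), "]")
  uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
}

#' Deformation state at a prescribed pressure and axial stretch
#'
#' Root-finds the mid-wall circumferential stretch at which
#' [equilibrium_pressure()] equals the target, by bracketed bisection-secant
#' search; the residual pressure at the returned state is below `1e-8` mmHg
#' for monotone responses.
#'
#' @inheritParams equilibrium_pressure
#' @param P_mmhg Target luminal pressure (mmHg).
#' @param interval Search bracket for `lam_theta`.
#' @return A [deformation_from_stretches()] state.
#' @export
state_at_pressure <- function(params, geom, P_mmhg, lam_z,
                              interval = c(0.5, 3)) {
  stopifnot(inherits(params, "four_fiber_params"))
  lt <- .lam_theta_at_pressure(.ffp_to_vec(params), geom, P_mmhg, lam_z, interval)
  deformation_from_stretches(lt, lam_z)
}

#' Cyclic aortic distensibility
#'
#' `D = (di_sys - di_dia) / (di_dia * (P_sys - P_dia))`, the fractional
#' luminal diameter change per unit pulse pressure — an inverse measure of
#' structural stiffness. Unit-invariant in the diameters.
#'
#' @param di_sys,di_dia Systolic and diastolic luminal diameters (same unit).
#' @param P_sys,P_dia Systolic and diastolic pressures (mmHg), `P_sys > P_dia > 0`.
#' @return Distensibility in 1/mmHg.
#' @examples
#' distensibility(1560, 1500, 120, 80)  # 1e-3 per mmHg
#' @export
distensibility <- function(di_sys, di_dia, P_sys = 120, P_dia = 80) {
  if (any(P_sys <= P_dia) || any(P_dia <= 0))
    stop("distensibility: need P_sys > P_dia > 0")
  if (any(di_sys <= 0) || any(di_dia <= 0))
    stop("distensibility: diameters must be positive")
  (di_sys - di_dia) / (di_dia * (P_sys - P_dia))
}

#' In-vivo mechanical metrics of a fitted vessel
#'
#' Evaluates the fitted constitutive model at representative diastolic
#' (80 mmHg) and systolic (120 mmHg) transmural pressures, at the subject's
#' in-vivo axial stretch: biaxial stretches, mean wall stresses, linearized
#' circumferential and axial stiffness (reported in MPa), stored energy
#' (kPa), loaded wall thickness, model-predicted luminal diameters, and
#' cyclic distensibility (reported both in 1/mmHg and scaled by 1e3 for
#' display).
#'
#' @param fit A [fit_parameters()] result (or a bare [four_fiber_params()]
#'   set, for metrics of a known ground truth).
#' @param record The matching [subject_record()].
#' @param lam_z_iv In-vivo axial stretch; estimated from the record via
#'   [estimate_invivo_stretch()] when `NULL`.
#' @param P_sys,P_dia Evaluation pressures (mmHg).
#' @return One-row data frame of class `invivo_metrics` with columns
#'   `sample_id`, `genotype`, `age_weeks`, `body_mass_g`, `lam_z_iv`,
#'   `lam_theta_sys`, `sigma_theta_sys`, `sigma_z_sys` (kPa),
#'   `C_tttt_sys`, `C_zzzz_sys` (MPa), `W_sys` (kPa), `h_sys`, `di_sys`,
#'   `di_dia` (um), `distensibility` (1/mmHg), `distensibility_e3`,
#'   and `normalized_diameter` (NA until filled by the allometric layer).
#' @export
compute_invivo_metrics <- function(fit, record, lam_z_iv = NULL,
                                   P_sys = 120, P_dia = 80) {
  params <- if (inherits(fit, "fff_fit")) fit$params else fit
  stopifnot(inherits(params, "four_fiber_params"),
            inherits(record, "subject_record"))
  if (is.null(lam_z_iv)) lam_z_iv <- estimate_invivo_stretch(record)
  geom <- record$geometry
  th <- .ffp_to_vec(params)
  res <- tryCatch({
    lt_sys <- .lam_theta_at_pressure(th, geom, P_sys, lam_z_iv)
    lt_dia <- .lam_theta_at_pressure(th, geom, P_dia, lam_z_iv)
    g_sys <- deformed_geometry(geom, lt_sys, lam_z_iv)
    g_dia <- deformed_geometry(geom, lt_dia, lam_z_iv)
    s <- .stress_vec(th, lt_sys, lam_z_iv)
    stf <- .stiffness_vec(th, lt_sys, lam_z_iv)
    D <- distensibility(2 * g_sys$ri, 2 * g_dia$ri, P_sys, P_dia)
    data.frame(
      sample_id = record$id, genotype = record$genotype,
      age_weeks = record$age_weeks, body_mass_g = record$body_mass_g,
      lam_z_iv = lam_z_iv, lam_theta_sys = lt_sys,
      sigma_theta_sys = s[1, 1], sigma_z_sys = s[1, 2],
      C_tttt_sys = stf[1, 1] / 1000, C_zzzz_sys = stf[1, 2] / 1000,
      W_sys = .energy_vec(th, lt_sys, lam_z_iv),
      h_sys = g_sys$h, di_sys = 2 * g_sys$ri, di_dia = 2 * g_dia$ri,
      distensibility = D, distensibility_e3 = 1000 * D,
      normalized_diameter = NA_real_,
      stringsAsFactors = FALSE)
  }, error = function(e) {
    stop("compute_invivo_metrics [sample ", record$id, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  class(res) <- c("invivo_metrics", class(res))
  res
}

#' Cohort metrics table
#'
#' Applies [compute_invivo_metrics()] to matched lists of fits and records.
#'
#' @param fits List of fit results (or parameter sets).
#' @param records List of [subject_record()]s of equal length.
#' @param ... Passed to [compute_invivo_metrics()].
#' @return Data frame with one row per sample.
#' @export
cohort_metrics <- function(fits, records, ...) {
  stopifnot(length(fits) == length(records))
  out <- do.call(rbind, Map(function(f, r) {
    m <- compute_invivo_metrics(f, r, ...)
    class(m) <- "data.frame"
    m
  }, fits, records))
  rownames(out) <- NULL
  out
}
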