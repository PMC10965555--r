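# Synthetic-data generator: vessels whose ground truth follows the
# four-fiber-family law, subjected to the biaxial testing protocols
# (cyclic pressurization 10-140 mmHg at the in-vivo axial stretch and +/-5%;
# force-length sweeps at 10/60/100/140 mmHg within the -0.5 to 5 g window),
# and cohorts following the allometric diameter-mass law.

#' Measurement noise model for the simulator
#'
#' Multiplicative Gaussian noise on diameter and force (coefficients of
#' variation typical of camera edge-tracking and load-cell precision) and
#' additive Gaussian jitter on pressure (transducer resolution).
#'
#' @param diameter_cv,force_cv Coefficients of variation (default 1% and 2%).
#' @param pressure_sd_mmhg Additive pressure jitter SD (default 0.5 mmHg).
#' @return List of class `noise_model`. Use `noise_model(0, 0, 0)` for
#'   noise-free ground-truth protocols.
#' @export
noise_model <- function(diameter_cv = 0.01, force_cv = 0.02,
                        pressure_sd_mmhg = 0.5) {
  if (any(c(diameter_cv, force_cv, pressure_sd_mmhg) < 0))
    stop("noise_model: noise magnitudes must be >= 0")
  structure(list(diameter_cv = diameter_cv, force_cv = force_cv,
                 pressure_sd_mmhg = pressure_sd_mmhg), class = "noise_model")
}

#' Simulation specification for one synthetic vessel
#'
#' Bundles the ground-truth constitutive parameters, unloaded geometry,
#' protocol grids, noise model, and seed that define a simulated biaxial
#' test session. Protocol defaults mirror the experimental design: pressure
#' sweeps 10-140 mmHg at the in-vivo stretch and +/-5% of it, and
#' force-length sweeps at 10/60/100/140 mmHg truncated to the -0.5 to 5 g
#' force window.
#'
#' @param genotype,age_weeks Cohort labels; also select the default
#'   [reference_params()] row.
#' @param params Ground-truth [four_fiber_params()].
#' @param geometry Unloaded [vessel_geometry()]. The default
#'   (`Ro = 540 um, H = 90 um, L = 4 mm`) yields loaded dimensions in the
#'   physiologic range of the murine ascending aorta (luminal diameter
#'   ~1.2-1.7 mm, loaded thickness ~30-50 um).
#' @param lam_z_iv In-vivo axial stretch; computed from the mechanics via
#'   [invariant_stretch()] when `NULL` (it is an emergent property of the
#'   parameters and geometry, not a free setting).
#' @param pressure_grid Pressures (mmHg) of the pressure-diameter sweeps.
#' @param stretch_offsets Relative offsets of the pd protocols around
#'   `lam_z_iv`.
#' @param fl_pressures Constant pressures (mmHg) of the force-length sweeps.
#' @param fl_span,fl_n Relative half-width and point count of the axial
#'   stretch grid of the fl sweeps.
#' @param force_window Retained force range (g) of the fl sweeps.
#' @param noise A [noise_model()].
#' @param seed Integer seed; all stochastic output is reproducible from it.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(genotype = "WT", age_weeks = 12,
                            params = reference_params(genotype, age_weeks),
                            geometry = vessel_geometry(540, 90, 4),
                            lam_z_iv = NULL,
                            pressure_grid = seq(10, 140, by = 5),
                            stretch_offsets = c(-0.05, 0, 0.05),
                            fl_pressures = c(10, 60, 100, 140),
                            fl_span = 0.12, fl_n = 15,
                            force_window = c(-0.5, 5),
                            noise = noise_model(), seed = 1L) {
  stopifnot(inherits(params, "four_fiber_params"),
            inherits(geometry, "vessel_geometry"),
            inherits(noise, "noise_model"))
  if (any(pressure_grid < 10 - 1e-9) || any(pressure_grid > 140 + 1e-9))
    stop("simulation_spec: pressure grid must stay within 10-140 mmHg")
  if (!all(fl_pressures %in% c(10, 60, 100, 140)))
    stop("simulation_spec: fl pressures must be among 10/60/100/140 mmHg")
  if (is.null(lam_z_iv))
    lam_z_iv <- invariant_stretch(params, geometry, pressures = fl_pressures)
  structure(list(genotype = genotype, age_weeks = age_weeks, params = params,
                 geometry = geometry, lam_z_iv = lam_z_iv,
                 pressure_grid = pressure_grid,
                 stretch_offsets = stretch_offsets,
                 fl_pressures = fl_pressures, fl_span = fl_span, fl_n = fl_n,
                 force_window = force_window, noise = noise,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Force-invariant (in-vivo) axial stretch of a modelled vessel
#'
#' The axial stretch at which axial force is insensitive to pressurization:
#' for each candidate stretch the least-squares slope of force vs pressure
#' over the force-length test pressures is computed from the structural
#' response, and the zero of the slope is located by bracketed root search.
#'
#' @param params Ground-truth [four_fiber_params()].
#' @param geom A [vessel_geometry()].
#' @param lam_z_range Search range for the stretch.
#' @param pressures Pressures (mmHg) over which the slope is evaluated.
#' @return In-vivo axial stretch (dimensionless).
#' @export
invariant_stretch <- function(params, geom, lam_z_range = c(1.2, 2.2),
                              pressures = c(10, 60, 100, 140)) {
  th <- .ffp_to_vec(params)
  slope <- function(lz) {
    lt <- vapply(pressures, function(P)
      .lam_theta_at_pressure(th, geom, P, lz), numeric(1))
    g <- deformed_geometry(geom, lt, lz)
    s <- .stress_vec(th, lt, lz)
    f <- .axial_force_g(s[, 2], pressures, g$ri, g$h)
    unname(coef(lm(f ~ pressures))[2])
  }
  # evaluate the slope on a coarse grid first: at extreme stretches the
  # circumferential equilibrium may have no solution at the lowest pressure,
  # and the sign change need not span the whole range
  grid <- seq(lam_z_range[1], lam_z_range[2], length.out = 11)
  sl <- vapply(grid, function(lz)
    tryCatch(slope(lz), error = function(e) NA_real_), numeric(1))
  ok <- which(is.finite(sl))
  br <- NULL
  for (k in seq_along(ok)[-1]) {
    i <- ok[k - 1]; j <- ok[k]
    if (j == i + 1 && sl[i] * sl[j] <= 0) { br <- c(grid[i], grid[j]); break }
  }
  if (is.null(br))
    stop("invariant_stretch: force-pressure slope does not change sign over ",
         "lam_z in [", lam_z_range[1], ", ", lam_z_range[2], "]")
  uniroot(slope, br, tol = 1e-8)$root
}

# exact structural response at one (lam_theta, lam_z): od, pressure, force
.forward_point <- function(th, geom, lt, lz) {
  g <- deformed_geometry(geom, lt, lz)
  s <- .stress_vec(th, lt, lz)
  P <- kpa_to_mmhg(s[, 1] * g$h / g$ri)
  f <- .axial_force_g(s[, 2], P, g$ri, g$h)
  list(od = g$od, P = P, f = f)
}

.apply_noise <- function(df, noise) {
  n <- nrow(df)
  df$pressure_mmHg <- df$pressure_mmHg + rnorm(n, 0, noise$pressure_sd_mmhg)
  df$outer_diameter_um <- df$outer_diameter_um * (1 + rnorm(n, 0, noise$diameter_cv))
  df$axial_force_g <- df$axial_force_g * (1 + rnorm(n, 0, noise$force_cv))
  df
}

#' Simulate one pressure-diameter protocol
#'
#' Holds the vessel at a fixed axial stretch and sweeps the luminal pressure
#' over the spec's grid. Each grid pressure is realised exactly by
#' root-finding the equilibrium circumferential stretch; the outer diameter
#' and the axial force follow from incompressible geometry and axial
#' equilibrium, then measurement noise is applied. Two cycles are emitted
#' (cycle 1 preconditioning, cycle 2 analysis), matching the acquisition
#' convention that analysis uses the last cycle.
#'
#' @param spec A [simulation_spec()].
#' @param lam_z Axial stretch held during the sweep.
#' @param label Protocol tag (e.g. `"pd_iv"`, `"pd_p5"`, `"pd_m5"`).
#' @return Data frame of raw acquisition rows (see [subject_record()]).
#' @export
simulate_pd_protocol <- function(spec, lam_z, label = "pd_iv") {
  stopifnot(inherits(spec, "simulation_spec"))
  th <- .ffp_to_vec(spec$params)
  lt <- vapply(sort(spec$pressure_grid), function(P)
    .lam_theta_at_pressure(th, spec$geometry, P, lam_z), numeric(1))
  if (any(diff(lt) <= 0))
    stop("simulate_pd_protocol: non-monotone pressure-diameter response ",
         "for this simulation spec")
  fw <- .forward_point(th, spec$geometry, lt, lam_z)
  one <- function(cycle) data.frame(
    protocol = label, cycle = cycle, pressure_mmHg = fw$P,
    outer_diameter_um = fw$od, axial_length_mm = lam_z * spec$geometry$L,
    axial_force_g = fw$f)
  .apply_noise(rbind(one(1L), one(2L)), spec$noise)
}

#' Simulate one force-length protocol
#'
#' Holds the luminal pressure constant and sweeps the axial stretch over the
#' spec's grid (centred on the in-vivo stretch), solving the circumferential
#' equilibrium at each length and truncating to the force window before
#' noise is applied.
#'
#' @param spec A [simulation_spec()].
#' @param P_mmhg Constant pressure of the sweep (mmHg).
#' @return Data frame of raw acquisition rows tagged `fl_<P>`.
#' @export
simulate_fl_protocol <- function(spec, P_mmhg) {
  stopifnot(inherits(spec, "simulation_spec"))
  th <- .ffp_to_vec(spec$params)
  lz <- spec$lam_z_iv * seq(1 - spec$fl_span, 1 + spec$fl_span,
                            length.out = spec$fl_n)
  # at extreme axial stretches the circumferential equilibrium may have no
  # solution at this pressure; those lengths are simply not acquirable
  lt <- vapply(lz, function(z)
    tryCatch(.lam_theta_at_pressure(th, spec$geometry, P_mmhg, z),
             error = function(e) NA_real_), numeric(1))
  lz <- lz[is.finite(lt)]; lt <- lt[is.finite(lt)]
  if (length(lz) < 3)
    stop("simulate_fl_protocol: fewer than 3 acquirable lengths at ",
         P_mmhg, " mmHg")
  g <- deformed_geometry(spec$geometry, lt, lz)
  s <- .stress_vec(th, lt, lz)
  f <- .axial_force_g(s[, 2], P_mmhg, g$ri, g$h)
  keep <- f >= spec$force_window[1] & f <= spec$force_window[2]
  one <- function(cycle) data.frame(
    protocol = sprintf("fl_%g", P_mmhg), cycle = cycle,
    pressure_mmHg = P_mmhg, outer_diameter_um = g$od[keep],
    axial_length_mm = lz[keep] * spec$geometry$L, axial_force_g = f[keep])
  .apply_noise(rbind(one(1L), one(2L)), spec$noise)
}

#' Simulate a full biaxial test session for one vessel
#'
#' Runs the pressure-diameter protocols at the in-vivo stretch and at the
#' spec's offsets around it, and the force-length protocols at each fl
#' pressure, and assembles a [subject_record()]. Seed-deterministic.
#'
#' @param spec A [simulation_spec()].
#' @param id Sample identifier.
#' @param body_mass_g Body mass recorded in the metadata.
#' @return A [subject_record()].
#' @export
simulate_subject <- function(spec, id = "sim-01", body_mass_g = 25) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tags <- ifelse(spec$stretch_offsets == 0, "pd_iv",
                 sprintf("pd_%s%g", ifelse(spec$stretch_offsets > 0, "p", "m"),
                         abs(spec$stretch_offsets) * 100))
  pd <- Map(function(off, tag)
    simulate_pd_protocol(spec, spec$lam_z_iv * (1 + off), tag),
    spec$stretch_offsets, tags)
  fl <- lapply(spec$fl_pressures, function(P) simulate_fl_protocol(spec, P))
  subject_record(id, spec$genotype, spec$age_weeks, body_mass_g,
                 spec$geometry, do.call(rbind, c(pd, fl)))
}

#' Simulate an allometric cohort of body masses and luminal diameters
#'
#' Draws body masses uniformly over `mass_range` and diameters from the
#' power law `alpha * BM^beta` with log-normal scatter `s_log`, optionally
#' inflated by a dilatation `multiplier`.
#'
#' @param n Number of animals.
#' @param alpha,beta Power-law coefficients (um g^-beta, dimensionless).
#' @param s_log Residual SD on the natural-log scale.
#' @param mass_range Body-mass range (g).
#' @param multiplier Diameter multiplier (1 = healthy scaling).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Data frame with `body_mass_g`, `di_um`.
#' @export
simulate_allometric_cohort <- function(n, alpha = 671.7862, beta = 0.2816,
                                       s_log = 0.04, mass_range = c(15, 35),
                                       multiplier = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bm <- runif(n, mass_range[1], mass_range[2])
  data.frame(body_mass_g = bm,
             di_um = multiplier * alpha * bm^beta * exp(rnorm(n, 0, s_log)))
}

#' Simulate a multi-genotype cohort with raw biaxial records
#'
#' Draws each animal's body mass and target systolic luminal diameter from
#' the allometric law (times a per-genotype dilatation multiplier), scales
#' the genotype's reference vessel geometry so that its modelled systolic
#' diameter matches the target (the structural response is invariant to a
#' common geometric scale, so scaling is exact), and simulates the full
#' protocol session per animal. Fully reproducible from the seed.
#'
#' @param specs Named list of [simulation_spec()]s, one per genotype.
#' @param n_per_group Animals per genotype (recycled over `specs`).
#' @param allometric List with `alpha`, `beta`, `s_log` — the cohort truth.
#' @param multipliers Named numeric dilatation multipliers per genotype
#'   (default 1 for every group).
#' @param mass_range Body-mass range (g).
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param records Set `FALSE` to skip raw-record simulation and return
#'   metadata (with true diameters) only — convenient for classifier
#'   calibration at large n.
#' @return List with `metadata` (data frame: sample_id, genotype, age_weeks,
#'   body_mass_g, geometry columns, `di_true_um`) and `records` (named list
#'   of [subject_record()]s, or `NULL`).
#' @export
simulate_cohort <- function(specs, n_per_group = 5,
                            allometric = list(alpha = 671.7862, beta = 0.2816,
                                              s_log = 0.04),
                            multipliers = NULL, mass_range = c(15, 35),
                            seed = 1L, records = TRUE) {
  stopifnot(all(vapply(specs, inherits, logical(1), "simulation_spec")))
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "genotype")
  if (is.null(multipliers))
    multipliers <- setNames(rep(1, length(specs)), names(specs))
  n_per_group <- rep_len(n_per_group, length(specs))
  # reference systolic diameter of each genotype's unit-scale vessel
  di_ref <- vapply(specs, function(sp) {
    lt <- .lam_theta_at_pressure(.ffp_to_vec(sp$params), sp$geometry, 120,
                                 sp$lam_z_iv)
    2 * deformed_geometry(sp$geometry, lt, sp$lam_z_iv)$ri
  }, numeric(1))
  set.seed(seed)
  meta <- NULL
  recs <- list()
  k <- 0L
  for (gi in seq_along(specs)) {
    sp <- specs[[gi]]
    gname <- names(specs)[gi]
    for (j in seq_len(n_per_group[gi])) {
      k <- k + 1L
      id <- sprintf("%s-%02d", gname, j)
      bm <- runif(1, mass_range[1], mass_range[2])
      di <- multipliers[[gname]] * allometric$alpha * bm^allometric$beta *
        exp(rnorm(1, 0, allometric$s_log))
      sc <- di / di_ref[gi]
      geom <- vessel_geometry(sp$geometry$Ro * sc, sp$geometry$H * sc,
                              sp$geometry$L)
      meta <- rbind(meta, data.frame(
        sample_id = id, genotype = gname, age_weeks = sp$age_weeks,
        body_mass_g = bm, Ro_um = geom$Ro, H_um = geom$H, L_mm = geom$L,
        di_true_um = di, stringsAsFactors = FALSE))
      if (records) {
        spk <- sp
        spk$geometry <- geom
        spk$seed <- as.integer((seed + 7919 * k) %% .Machine$integer.max)
        recs[[id]] <- simulate_subject(spk, id, body_mass_g = bm)
      }
    }
  }
  list(metadata = meta, records = if (records) recs else NULL)
}
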