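# Subject records: one animal's metadata, unloaded geometry, and raw biaxial
# protocol data, plus CSV I/O and reduction to stretches and wall stresses.

.BIAXIAL_COLS <- c("sample_id", "protocol", "cycle", "pressure_mmHg",
                   "outer_diameter_um", "axial_length_mm", "axial_force_g")
.META_COLS <- c("sample_id", "genotype", "age_weeks", "body_mass_g",
                "Ro_um", "H_um", "L_mm")
.GENOTYPES <- c("WT", "Hspg2+/-", "mgDlpn", "dMut")

#' Subject record: one animal's metadata, geometry, and biaxial data
#'
#' @param id Sample identifier (character).
#' @param genotype One of `"WT"`, `"Hspg2+/-"`, `"mgDlpn"`, `"dMut"`.
#' @param age_weeks Age in weeks.
#' @param body_mass_g Body mass in grams, `> 0`.
#' @param geometry A [vessel_geometry()].
#' @param data Data frame of raw acquisition rows with columns `protocol`,
#'   `cycle`, `pressure_mmHg`, `outer_diameter_um`, `axial_length_mm`,
#'   `axial_force_g`. Pressure-diameter protocols are tagged `pd_*`,
#'   force-length protocols `fl_*`.
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(id, genotype, age_weeks, body_mass_g, geometry, data) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (!genotype %in% .GENOTYPES)
    stop("subject_record: unknown genotype '", genotype, "'")
  if (!is.finite(body_mass_g) || body_mass_g <= 0)
    stop("subject_record: body_mass_g must be > 0")
  need <- setdiff(.BIAXIAL_COLS[-1], names(data))
  if (length(need))
    stop("subject_record: data missing column(s): ", paste(need, collapse = ", "))
  structure(list(id = as.character(id), genotype = genotype,
                 age_weeks = age_weeks, body_mass_g = body_mass_g,
                 geometry = geometry, data = data),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s (%s, %g wk, %.3g g): %d data rows in %d protocols\n",
              x$id, x$genotype, x$age_weeks, x$body_mass_g,
              nrow(x$data), length(unique(x$data$protocol))))
  invisible(x)
}

# sanity bands on acquisition rows; returns character reason or NA
.row_reject_reason <- function(d) {
  reason <- rep(NA_character_, nrow(d))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(!is.finite(d$pressure_mmHg) | d$pressure_mmHg < 0 |
                  d$pressure_mmHg > 200, "pressure outside [0, 200] mmHg")
  reason <- bad(!is.finite(d$outer_diameter_um) | d$outer_diameter_um <= 0,
                "non-positive outer diameter")
  reason <- bad(!is.finite(d$axial_length_mm) | d$axial_length_mm <= 0,
                "non-positive axial length")
  reason <- bad(!is.finite(d$axial_force_g) | d$axial_force_g < -2 |
                  d$axial_force_g > 10, "force outside [-2, 10] g")
  reason
}

#' Read raw biaxial acquisition data and cohort metadata CSVs
#'
#' The data CSV holds one row per acquired point with columns `sample_id`,
#' `protocol`, `cycle`, `pressure_mmHg`, `outer_diameter_um`,
#' `axial_length_mm`, `axial_force_g`; the metadata CSV one row per sample
#' with columns `sample_id`, `genotype`, `age_weeks`, `body_mass_g`, `Ro_um`,
#' `H_um`, `L_mm`. Rows outside the acquisition sanity bands (pressure in
#' `[0, 200]` mmHg, force in `[-2, 10]` g, positive diameter and length) are
#' rejected with a logged reason.
#'
#' @param data_file,metadata_file CSV paths.
#' @param quiet Suppress the row-count log messages.
#' @return Named list of [subject_record()] objects.
#' @export
read_cohort <- function(data_file, metadata_file, quiet = FALSE) {
  d <- read.csv(data_file, stringsAsFactors = FALSE)
  m <- read.csv(metadata_file, stringsAsFactors = FALSE)
  need <- setdiff(.BIAXIAL_COLS, names(d))
  if (length(need)) stop("read_cohort: data file missing column(s): ",
                         paste(need, collapse = ", "))
  need <- setdiff(.META_COLS, names(m))
  if (length(need)) stop("read_cohort: metadata file missing column(s): ",
                         paste(need, collapse = ", "))
  reason <- .row_reject_reason(d)
  if (!quiet) {
    message(sprintf("read_cohort: %d data rows, %d samples, %d rows rejected",
                    nrow(d), nrow(m), sum(!is.na(reason))))
    for (why in unique(stats::na.omit(reason)))
      message("  rejected ", sum(reason == why, na.rm = TRUE), " row(s): ", why)
  }
  d <- d[is.na(reason), ]
  records <- lapply(seq_len(nrow(m)), function(i) {
    mi <- m[i, ]
    subject_record(mi$sample_id, mi$genotype, mi$age_weeks, mi$body_mass_g,
                   vessel_geometry(mi$Ro_um, mi$H_um, mi$L_mm),
                   d[d$sample_id == mi$sample_id, .BIAXIAL_COLS[-1]])
  })
  setNames(records, m$sample_id)
}

#' Write subject records to the cohort CSV pair
#'
#' @param records List of [subject_record()] objects.
#' @param data_file,metadata_file Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(records, data_file, metadata_file) {
  dat <- do.call(rbind, lapply(records, function(r)
    cbind(sample_id = r$id, r$data[, .BIAXIAL_COLS[-1]])))
  meta <- do.call(rbind, lapply(records, function(r)
    data.frame(sample_id = r$id, genotype = r$genotype,
               age_weeks = r$age_weeks, body_mass_g = r$body_mass_g,
               Ro_um = r$geometry$Ro, H_um = r$geometry$H, L_mm = r$geometry$L)))
  write.csv(dat, data_file, row.names = FALSE)
  write.csv(meta, metadata_file, row.names = FALSE)
  invisible(c(data_file, metadata_file))
}

#' Reduce raw biaxial data to stretches and experimental wall stresses
#'
#' Keeps the last recorded cycle of each protocol (the analysis cycle;
#' earlier cycles are preconditioning), derives the loaded wall geometry from
#' each measured outer diameter via [current_geometry()], the mid-wall
#' circumferential stretch, the axial stretch `lam_z = l / L`, and the mean
#' wall stresses via [experimental_wall_stress()]. Points whose diameter is
#' volumetrically inconsistent with the axial stretch are dropped with a
#' message.
#'
#' @param record A [subject_record()].
#' @return Data frame with one row per retained point: `protocol`,
#'   `pressure_mmHg`, `axial_force_g`, `lam_theta`, `lam_z`, `ri_um`, `h_um`,
#'   `sigma_theta`, `sigma_z`.
#' @export
reduce_record <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  d <- record$data
  keep <- unlist(lapply(split(seq_len(nrow(d)), d$protocol),
                        function(ix) ix[d$cycle[ix] == max(d$cycle[ix])]))
  d <- d[sort(keep), ]
  lam_z <- d$axial_length_mm / record$geometry$L
  ro <- d$outer_diameter_um / 2
  rad <- ro^2 - (record$geometry$Ro^2 - record$geometry$Ri^2) / lam_z
  ok <- rad > 0
  if (any(!ok))
    message("reduce_record: dropping ", sum(!ok),
            " volumetrically inconsistent point(s) for sample ", record$id)
  d <- d[ok, ]; lam_z <- lam_z[ok]
  g <- current_geometry(record$geometry, d$outer_diameter_um, lam_z)
  s <- experimental_wall_stress(d$pressure_mmHg, d$axial_force_g, g$ri, g$h)
  data.frame(protocol = d$protocol, pressure_mmHg = d$pressure_mmHg,
             axial_force_g = d$axial_force_g,
             lam_theta = circumferential_stretch(record$geometry, g$ri, g$h),
             lam_z = lam_z, ri_um = g$ri, h_um = g$h,
             sigma_theta = s$sigma_theta, sigma_z = s$sigma_z)
}

#' Estimate the in-vivo axial stretch from force-length protocols
#'
#' The in-vivo axial stretch of an artery is the working length at which the
#' axial force does not change with pressurization. For each distinct axial
#' length in the force-length protocols, the slope of force vs pressure is
#' fit by least squares; the in-vivo stretch is where the slope crosses zero,
#' located by linear interpolation between the bracketing lengths.
#'
#' @param record A [subject_record()] whose `fl_*` protocols share a common
#'   axial-length grid (at least 3 distinct lengths spanning the crossover).
#' @return The in-vivo axial stretch (dimensionless), within the tested range.
#' @export
estimate_invivo_stretch <- function(record) {
  red <- reduce_record(record)
  fl <- red[startsWith(as.character(red$protocol), "fl"), ]
  if (nrow(fl) == 0)
    stop("estimate_invivo_stretch: no force-length protocol in record ", record$id)
  lz_key <- round(fl$lam_z, 8)
  groups <- split(fl, lz_key)
  groups <- groups[vapply(groups, function(g)
    length(unique(g$pressure_mmHg)) >= 2, logical(1))]
  if (length(groups) < 3)
    stop("estimate_invivo_stretch: need force-pressure data at >= 3 distinct ",
         "axial lengths, got ", length(groups))
  lz <- vapply(groups, function(g) g$lam_z[1], numeric(1))
  slope <- vapply(groups, function(g)
    coef(lm(axial_force_g ~ pressure_mmHg, data = g))[2], numeric(1))
  ord <- order(lz)
  lz <- lz[ord]; slope <- slope[ord]
  if (all(slope > 0) || all(slope < 0))
    stop("estimate_invivo_stretch: no crossover - axial force slope has the ",
         "same sign at every tested stretch (range does not bracket the ",
         "in-vivo point)")
  if (any(slope == 0)) return(unname(lz[which(slope == 0)[1]]))
  i <- which(diff(sign(slope)) != 0)[1]
  unname(lz[i] + (lz[i + 1] - lz[i]) * (0 - slope[i]) / (slope[i + 1] - slope[i]))
}
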