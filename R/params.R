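#' Four-fiber-family constitutive parameters
#'
#' Constructs the parameter set of the eight-parameter stored-energy function
#' used for passive arterial tissue: an isotropic (elastin-dominated) neo-Hookean
#' term with modulus `c`, plus four exponential fiber families — axial (angle 0
#' from the vessel axis), circumferential (90 degrees), and two diagonal families
#' at +/- `alpha0` that share one stiffness `c1_diag` and one exponent `c2_diag`.
#'
#' Each fiber family `i` contributes
#' `c1_i/(4 c2_i) * (exp(c2_i (IV_i - 1)^2) - 1)` to the stored energy, where
#' `IV_i = M_i . C M_i` is the squared fiber stretch along the family direction
#' `M_i = (0, sin a_i, cos a_i)` (angle measured from the axial direction).
#'
#' @param c Isotropic modulus (kPa), `>= 0`.
#' @param c1_axial,c2_axial Axial family stiffness (kPa) and dimensionless
#'   exponent, both `>= 0`.
#' @param c1_circ,c2_circ Circumferential family stiffness and exponent.
#' @param c1_diag,c2_diag Shared stiffness and exponent of the two symmetric
#'   diagonal families.
#' @param alpha0 Diagonal family angle in degrees from the axial direction,
#'   in `[0, 90]`.
#' @return An object of class `four_fiber_params`: list with elements `c`,
#'   `c1` (length 4: axial, circumferential, diagonal, diagonal), `c2`
#'   (length 4), `alpha0` (degrees), and `angles_deg` (the four family angles
#'   `0, 90, +alpha0, -alpha0`).
#' @examples
#' p <- four_fiber_params(c = 14.46, c1_axial = 12.98, c2_axial = 0.07,
#'                        c1_circ = 0.03, c2_circ = 1.75,
#'                        c1_diag = 29.45, c2_diag = 0.20, alpha0 = 53)
#' p
#' @export
four_fiber_params <- function(c = 0, c1_axial = 0, c2_axial = 0,
                              c1_circ = 0, c2_circ = 0,
                              c1_diag = 0, c2_diag = 0, alpha0 = 45) {
  vals <- c(c = c, c1_axial = c1_axial, c2_axial = c2_axial,
            c1_circ = c1_circ, c2_circ = c2_circ,
            c1_diag = c1_diag, c2_diag = c2_diag, alpha0 = alpha0)
  if (any(!is.finite(vals)))
    stop("four_fiber_params: all parameters must be finite numbers")
  neg <- vals[seq_len(7)] < 0
  if (any(neg))
    stop("four_fiber_params: negative parameter(s): ",
         paste(names(vals[seq_len(7)])[neg], collapse = ", "))
  if (alpha0 < 0 || alpha0 > 90)
    stop("four_fiber_params: alpha0 must lie in [0, 90] degrees, got ", alpha0)
  structure(list(
    c = c,
    c1 = c(c1_axial, c1_circ, c1_diag, c1_diag),
    c2 = c(c2_axial, c2_circ, c2_diag, c2_diag),
    alpha0 = alpha0,
    angles_deg = c(0, 90, alpha0, -alpha0)
  ), class = "four_fiber_params")
}

#' @export
print.four_fiber_params <- function(x, ...) {
  cat("Four-fiber-family parameters\n")
  cat(sprintf("  isotropic       c  = %.4g kPa\n", x$c))
  cat(sprintf("  axial           c1 = %.4g kPa, c2 = %.4g\n", x$c1[1], x$c2[1]))
  cat(sprintf("  circumferential c1 = %.4g kPa, c2 = %.4g\n", x$c1[2], x$c2[2]))
  cat(sprintf("  diagonal (+/-%.3g deg) c1 = %.4g kPa, c2 = %.4g\n",
              x$alpha0, x$c1[3], x$c2[3]))
  invisible(x)
}

# 8-vector <-> params mapping used by the fitter:
# (c, c1_ax, c2_ax, c1_circ, c2_circ, c1_diag, c2_diag, alpha0_deg)
.ffp_to_vec <- function(p) {
  c(p$c, p$c1[1], p$c2[1], p$c1[2], p$c2[2], p$c1[3], p$c2[3], p$alpha0)
}

.vec_to_ffp <- function(th) {
  four_fiber_params(c = th[1], c1_axial = th[2], c2_axial = th[3],
                    c1_circ = th[4], c2_circ = th[5],
                    c1_diag = th[6], c2_diag = th[7], alpha0 = th[8])
}

.ffp_par_names <- c("c", "c1_axial", "c2_axial", "c1_circ", "c2_circ",
                    "c1_diag", "c2_diag", "alpha0")

#' Reference constitutive parameter sets for murine ascending aortas
#'
#' Bundled best-fit parameter sets describing the representative passive
#' mechanical response of the ascending thoracic aorta in four mouse
#' genotypes (wild type, perlecan-haploinsufficient `Hspg2+/-`, the Marfan
#' `mgDlpn` strain, and the double mutant) at 4, 12, and 30 weeks of age.
#' These serve as ground truth for the synthetic-data generator and as
#' recovery targets for the fitter.
#'
#' Several entries are printed at magnitudes around `1e-14`-`1e-4`, i.e.
#' numerically indistinguishable from zero for stress-like quantities;
#' `reference_params()` zeroes entries below `zero_threshold` so that
#' simulation fixtures are exactly reproducible.
#'
#' @param genotype One of `"WT"`, `"Hspg2+/-"`, `"mgDlpn"`, `"dMut"`.
#' @param age_weeks One of 4, 12, 30 (availability depends on genotype).
#' @param zero_threshold Parameters below this magnitude are set to exactly 0
#'   (default `1e-3`; set to 0 to keep the printed values).
#' @return `reference_params()`: a [four_fiber_params] object.
#'   `reference_params_table()`: data frame of all bundled rows with the
#'   as-printed values.
#' @export
reference_params <- function(genotype = "WT", age_weeks = 12,
                             zero_threshold = 1e-3) {
  tab <- reference_params_table()
  row <- tab[tab$genotype == genotype & tab$age_weeks == age_weeks, ]
  if (nrow(row) != 1)
    stop("no reference parameter set for genotype '", genotype,
         "' at ", age_weeks, " weeks")
  v <- as.numeric(row[, c("c", "c1_axial", "c2_axial", "c1_circ", "c2_circ",
                          "c1_diag", "c2_diag")])
  v[abs(v) < zero_threshold] <- 0
  four_fiber_params(c = v[1], c1_axial = v[2], c2_axial = v[3],
                    c1_circ = v[4], c2_circ = v[5],
                    c1_diag = v[6], c2_diag = v[7], alpha0 = row$alpha0)
}

#' @rdname reference_params
#' @export
reference_params_table <- function() {
  data.frame(
    genotype = c("WT", "WT", "WT", "Hspg2+/-", "mgDlpn", "mgDlpn", "mgDlpn", "dMut"),
    age_weeks = c(4, 12, 30, 12, 4, 12, 30, 12),
    c        = c(25.05, 14.46, 21.48, 14.77, 30.07, 2.32e-14, 27.78, 5.28e-11),
    c1_axial = c(15.85, 12.98, 7.52, 12.69, 2.79, 14.79, 2.83e-4, 12.88),
    c2_axial = c(0.04, 0.07, 2.22e-14, 0.05, 0.41, 2.32e-14, 6.67e-6, 3.24e-12),
    c1_circ  = c(11.36, 0.03, 9.42, 0.01, 1.75e-10, 3.31, 1.33e-7, 2.41),
    c2_circ  = c(2.34e-14, 1.75, 0.45, 2.09, 8.57, 1.05, 18.59, 0.63),
    c1_diag  = c(11.06, 29.45, 17.52, 32.91, 13.22, 23.44, 21.31, 30.15),
    c2_diag  = c(0.40, 0.20, 0.27, 0.18, 0.63, 0.44, 1.58, 0.35),
    alpha0   = c(51, 53, 46, 53, 53, 50, 59, 49),
    stringsAsFactors = FALSE
  )
}
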