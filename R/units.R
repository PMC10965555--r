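# Unit conversions used at the I/O boundary. Internal computations are in
# kPa (stress), mN (force), mm (axial length), um (radii/thickness).

#' Unit conversions for pressure and force
#'
#' Pressures are acquired in mmHg and forces in gram-force; all constitutive
#' and equilibrium computations run in kPa and mN. `1 mmHg = 0.1333224 kPa`,
#' `1 gf = 9.80665 mN`.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name units
NULL

.MMHG_PER_KPA <- 0.1333224
.MN_PER_GF <- 9.80665

#' @rdname units
#' @export
mmhg_to_kpa <- function(x) x * .MMHG_PER_KPA

#' @rdname units
#' @export
kpa_to_mmhg <- function(x) x / .MMHG_PER_KPA

#' @rdname units
#' @export
gf_to_mn <- function(x) x * .MN_PER_GF

#' @rdname units
#' @export
mn_to_gf <- function(x) x / .MN_PER_GF
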