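#' Certified isotope reference standards
#'
#' Certified ratios of the NBS 981 common-lead standard and the NBS 997
#' thallium standard used for MC-ICP-MS mass-bias calibration, together with
#' typical repeatability of repeated lead isotope measurements on the
#' instrument (relative deviations). Useful as fixture fingerprints and for
#' setting realistic noise levels in simulations.
#'
#' @format `nbs981` is a named numeric vector of certified lead isotope
#'   ratios; `nbs997` is the certified 205Tl/203Tl ratio;
#'   `mc_icpms_repeatability` gives upper bounds on the relative standard
#'   deviation of repeated ratio measurements (dimensionless, e.g. 2e-4 =
#'   0.02%).
#' @name pb_standards
NULL

#' @rdname pb_standards
#' @export
nbs981 <- c(
  Pb208_206 = 2.167710,
  Pb207_206 = 0.914750,
  Pb206_204 = 16.9405,
  Pb207_204 = 15.4963,
  Pb208_204 = 36.7219
)

#' @rdname pb_standards
#' @export
nbs997 <- c(Tl205_203 = 2.3871)

#' @rdname pb_standards
#' @export
mc_icpms_repeatability <- c(
  Pb207_206 = 2e-4,
  Pb208_206 = 2e-4,
  Pb206_204 = 4e-4
)
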