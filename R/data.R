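#' Reference descriptor tables for model-membrane monolayers
#'
#' Reported isotherm descriptors for azolectin and lecithin monolayers on
#' water, alone and with the cationic antimicrobial peptides P2, P4, P5
#' and P6 in the aqueous subphase: lift-off area, collapse area and
#' pressure, the area/pressure/value of the compressibility-modulus
#' maximum, the packing ratio chi and the dynamic-rise slope
#' (`reference_descriptors()`), and the per-loop compression
#' reversibility factors of three successive hysteresis loops
#' (`reference_reversibility()`). Areas in A^2/molecule, pressures and
#' moduli in mN/m, Rv in percent. Shipped as plain CSV under
#' `extdata/`; used in validation and as worked-example input.
#'
#' @return A data.frame.
#' @examples
#' ref <- reference_descriptors()
#' compute_chi(ref$A_collapse, ref$A_lift_off)
#' @export
reference_descriptors <- function() {
  utils::read.csv(system.file("extdata", "monolayer_descriptors.csv",
                              package = "langmuir"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_descriptors
#' @export
reference_reversibility <- function() {
  utils::read.csv(system.file("extdata", "monolayer_reversibility.csv",
                              package = "langmuir"),
                  stringsAsFactors = FALSE)
}
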