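# Physical constants used throughout. Energies cross the engine boundary in
# hartree and are converted to eV exactly once, in consumer code.
HARTREE_EV <- 27.211386
COULOMB_EV_ANG <- 14.3996   # e^2 / (4 pi eps0), in eV * Angstrom
BOHR_ANG <- 0.529177210903
NM_EV <- 1239.842           # hc, in eV * nm

#' Atomic numbers for common light elements
#'
#' @param elements character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @keywords internal
atomicNumbers <- function(elements) {
  z <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
         F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
         S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Br = 35L, I = 53L)
  out <- z[elements]
  if (anyNA(out)) {
    stop("unsupported element(s): ",
         paste(unique(elements[is.na(out)]), collapse = ", "))
  }
  unname(out)
}
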