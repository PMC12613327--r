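#' @include AllClasses.R
NULL

## Built-in 9-solvent table. Static dielectric constants follow the benchmark
## set; optical constants are the square of the refractive index where not
## printed alongside the static value. Cyclohexane's n^2 (2.035) marginally
## exceeds its static constant in standard tables, so it is capped at eps
## (for a nonpolar solvent eps ~ n^2).
.solventTable <- data.frame(
  name = c("cyclohexane", "toluene", "chloroform", "THF", "DCM",
           "ethanol", "methanol", "DMF", "DMSO"),
  eps = c(2.02, 2.38, 4.81, 7.58, 8.93, 24.5, 32.7, 36.7, 46.7),
  epsInf = c(2.02, 2.24, 2.09, 1.98, 2.03, 1.85, 1.77, 2.04, 2.19),
  stringsAsFactors = FALSE)

#' Look up a solvent in the built-in table
#'
#' Nine common UV/Vis solvents with static (`eps`) and optical (`epsInf`,
#' squared refractive index) dielectric constants. Matching is
#' case-insensitive; individual constants can be overridden.
#'
#' @param name solvent name (e.g. `"DCM"`, `"dmso"`).
#' @param eps,epsInf optional overrides.
#' @return a [SolventSpec-class].
#' @examples
#' solventLookup("DCM")     # eps = 8.93, epsInf = 2.03
#' @export
solventLookup <- function(name, eps = NULL, epsInf = NULL) {
  hit <- match(tolower(name), tolower(.solventTable$name))
  if (is.na(hit))
    stop(sprintf("unknown solvent '%s'; known solvents: %s", name,
                 paste(.solventTable$name, collapse = ", ")))
  SolventSpec(.solventTable$name[hit],
              if (is.null(eps)) .solventTable$eps[hit] else eps,
              if (is.null(epsInf)) .solventTable$epsInf[hit] else epsInf)
}

#' List the built-in solvent table
#'
#' @return a data.frame with columns name, eps, epsInf.
#' @export
solventTable <- function() .solventTable
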