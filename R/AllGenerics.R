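#' @include constants.R
NULL

#' Run a ground-state calculation through an engine
#'
#' Engine contract: every backend (the built-in mock engine or an adapter to a
#' real electronic-structure code) must provide deterministic ground-state
#' energetics for a molecule under a given set of RSH parameters and a
#' solvation mode. Repeated identical calls must return identical results.
#'
#' @param engine an engine object (see [mockEngine()]).
#' @param molecule a [Molecule-class] object.
#' @param params a [RSHParams-class] object.
#' @param solvation a [SolvationMode-class] object.
#' @return a [GroundStateResult-class] object. Energies are in hartree at this
#'   boundary; polarization charges are returned whenever a continuum is
#'   active and are empty in gas mode.
#' @export
setGeneric("runGroundState", function(engine, molecule, params, solvation)
  standardGeneric("runGroundState"))

#' Run an excited-state calculation through an engine
#'
#' @inheritParams runGroundState
#' @param nStates number of excited states requested (default 10, the
#'   first-ten-states protocol used for spectral simulation).
#' @return an [ExcitationSet-class] with exactly `nStates` states in
#'   ascending energy.
#' @export
setGeneric("runExcitedStates",
           function(engine, molecule, params, solvation, nStates = 10L)
  standardGeneric("runExcitedStates"))

#' @rdname accessors
#' @export
setGeneric("gammaOpt", function(x) standardGeneric("gammaOpt"))

#' @rdname accessors
#' @export
setGeneric("j2Opt", function(x) standardGeneric("j2Opt"))

#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' @rdname accessors
#' @export
setGeneric("oscillatorStrengths", function(x) standardGeneric("oscillatorStrengths"))

#' @rdname accessors
#' @export
setGeneric("dipoles", function(x) standardGeneric("dipoles"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname accessors
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
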