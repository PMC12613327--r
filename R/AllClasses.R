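#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- Molecule

#' Molecular geometry with charge state
#'
#' A molecule is a set of atoms (element symbols plus Cartesian coordinates in
#' Angstrom), a net charge (0 neutral, +1 cation = N-1 electrons, -1 anion =
#' N+1 electrons) and a spin multiplicity. Validity enforces the parity
#' consistency between electron count and multiplicity.
#'
#' @slot elements character vector of element symbols.
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot charge integer net charge (electron-count offset).
#' @slot multiplicity positive integer spin multiplicity.
#' @aliases Molecule
#' @export
setClass("Molecule",
  representation(elements = "character", coords = "matrix",
                 charge = "integer", multiplicity = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@elements)
    if (n < 1L) msg <- c(msg, "molecule must contain at least one atom")
    if (!is.numeric(object@coords) || !all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite numeric")
    if (nrow(object@coords) != n || ncol(object@coords) != 3L)
      msg <- c(msg, "coords must be an n x 3 matrix matching elements")
    if (length(object@multiplicity) != 1L || object@multiplicity < 1L)
      msg <- c(msg, "multiplicity must be a positive integer")
    if (length(msg) == 0L) {
      nelec <- sum(atomicNumbers(object@elements)) - object@charge
      if (nelec < 1L) msg <- c(msg, "molecule must retain at least one electron")
      # multiplicity 2S+1 with S = n_unpaired/2: nelec and (multiplicity - 1)
      # must share parity
      else if ((nelec %% 2L) != ((object@multiplicity - 1L) %% 2L))
        msg <- c(msg, sprintf(
          "electron count %d inconsistent with multiplicity %d",
          nelec, object@multiplicity))
    }
    if (length(msg)) msg else TRUE
  })

#' @param elements character vector of element symbols.
#' @param coords n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param charge integer net charge.
#' @param multiplicity spin multiplicity; if `NULL`, the lowest consistent
#'   value (1 for even electron count, 2 for odd) is chosen.
#' @return a `Molecule` object.
#' @rdname Molecule-class
#' @examples
#' h2o <- Molecule(c("O", "H", "H"),
#'                 rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0)))
#' nAtoms(h2o)
#' @export
Molecule <- function(elements, coords, charge = 0L, multiplicity = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  charge <- as.integer(charge)
  if (is.null(multiplicity)) {
    nelec <- sum(atomicNumbers(elements)) - charge
    multiplicity <- if (nelec %% 2L == 0L) 1L else 2L
  }
  new("Molecule", elements = as.character(elements), coords = coords,
      charge = charge, multiplicity = as.integer(multiplicity))
}

#' Derive an ionized copy of a molecule
#'
#' Returns the same geometry with the net charge changed and the multiplicity
#' reset to the lowest value consistent with the new electron count (vertical
#' ionization / attachment at fixed geometry).
#'
#' @param molecule a [Molecule-class].
#' @param charge the new net charge.
#' @return a [Molecule-class].
#' @export
setCharge <- function(molecule, charge) {
  Molecule(molecule@elements, molecule@coords, charge = charge,
           multiplicity = NULL)
}

setMethod("nAtoms", "Molecule", function(x) length(x@elements))
setMethod("coords", "Molecule", function(x) x@coords)
setMethod("elements", "Molecule", function(x) x@elements)
setMethod("netCharge", "Molecule", function(x) x@charge)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d atoms, charge %+d, multiplicity %d\n",
              nAtoms(object), object@charge, object@multiplicity))
  cat(" formula:", paste(names(table(object@elements)),
                         table(object@elements), collapse = " "), "\n")
})

## --------------------------------------------------------------- RSHParams

#' Range-separated hybrid functional parameters
#'
#' The RSH exchange partition uses a short-range exact-exchange fraction
#' `alpha`, a long-range increment `beta` (so `alpha + beta` is the asymptotic
#' exact-exchange fraction) and the range-separation parameter `gamma` in
#' inverse Bohr. Defaults are the wPBEh values (0.2, 0.8, 0.2).
#'
#' @slot alpha short-range Fock fraction (dimensionless).
#' @slot beta long-range increment (dimensionless).
#' @slot gamma range-separation parameter (a0^-1).
#' @aliases RSHParams
#' @export
setClass("RSHParams",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    ab <- object@alpha + object@beta
    if (ab < 0 || ab > 1) msg <- c(msg, "alpha + beta must lie in [0, 1]")
    if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param alpha,beta,gamma see slots.
#' @rdname RSHParams-class
#' @examples
#' RSHParams()                 # wPBEh defaults
#' RSHParams(gamma = 0.15)
#' @export
RSHParams <- function(alpha = 0.2, beta = 0.8, gamma = 0.2) {
  new("RSHParams", alpha = alpha, beta = beta, gamma = gamma)
}

setMethod("show", "RSHParams", function(object) {
  cat(sprintf("RSHParams: alpha = %.3f, beta = %.3f, gamma = %.4f a0^-1\n",
              object@alpha, object@beta, object@gamma))
})

## -------------------------------------------------------------- SolventSpec

#' Solvent dielectric specification
#'
#' @slot name text label.
#' @slot eps static dielectric constant.
#' @slot epsInf optical dielectric constant (square of the refractive index).
#' @aliases SolventSpec
#' @export
setClass("SolventSpec",
  representation(name = "character", eps = "numeric", epsInf = "numeric"),
  validity = function(object) {
    if (object@epsInf < 1 || object@epsInf > object@eps)
      "must satisfy 1 <= epsInf <= eps" else TRUE
  })

#' @param name,eps,epsInf see slots.
#' @rdname SolventSpec-class
#' @export
SolventSpec <- function(name, eps, epsInf) {
  new("SolventSpec", name = as.character(name), eps = eps, epsInf = epsInf)
}

setMethod("show", "SolventSpec", function(object) {
  cat(sprintf("SolventSpec: %s (eps = %.3g, epsInf = %.3g)\n",
              object@name, object@eps, object@epsInf))
})

## ---------------------------------------------------------- FrozenSlowField

#' Frozen slow (nuclear) polarization field
#'
#' The slow component of the equilibrium polarization charges of a reference
#' run (normally the neutral state), kept fixed while the fast (electronic)
#' polarization re-equilibrates at the optical dielectric constant.
#'
#' @slot positions m x 3 matrix of cavity surface positions (Angstrom).
#' @slot charges numeric vector of slow charges (e).
#' @slot provenance character tag recording the source run.
#' @aliases FrozenSlowField
#' @export
setClass("FrozenSlowField",
  representation(positions = "matrix", charges = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@positions) != length(object@charges))
      msg <- c(msg, "positions and charges must have matching length")
    if (!all(is.finite(object@charges)))
      msg <- c(msg, "charges must be finite")
    if (length(msg)) msg else TRUE
  })

#' @param positions,charges,provenance see slots.
#' @rdname FrozenSlowField-class
#' @export
FrozenSlowField <- function(positions, charges, provenance = "unspecified") {
  new("FrozenSlowField", positions = matrix(as.numeric(positions), ncol = 3L),
      charges = as.numeric(charges), provenance = provenance)
}

## ------------------------------------------------------------ SolvationMode

#' Solvation mode
#'
#' The axis distinguishing the three tuning schemes: `gas` (no continuum),
#' `equilibrium` (both fast and slow polarization respond, static eps) and
#' `nonequilibrium` (only fast polarization responds, optical epsInf, with an
#' optional frozen slow field from a reference equilibrium run).
#'
#' @slot tag one of "gas", "equilibrium", "nonequilibrium".
#' @slot eps static dielectric constant (equilibrium mode only; NA otherwise).
#' @slot epsInf optical dielectric constant (nonequilibrium only; NA otherwise).
#' @slot frozenField a list holding at most one [FrozenSlowField-class].
#' @aliases SolvationMode
#' @export
setClass("SolvationMode",
  representation(tag = "character", eps = "numeric", epsInf = "numeric",
                 frozenField = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@tag %in% c("gas", "equilibrium", "nonequilibrium"))
      msg <- c(msg, "tag must be gas, equilibrium or nonequilibrium")
    if (object@tag == "gas" && (!is.na(object@eps) || !is.na(object@epsInf)))
      msg <- c(msg, "gas mode carries no dielectric")
    if (object@tag == "equilibrium" && (is.na(object@eps) || object@eps < 1))
      msg <- c(msg, "equilibrium mode requires eps >= 1")
    if (object@tag == "nonequilibrium" &&
        (is.na(object@epsInf) || object@epsInf < 1))
      msg <- c(msg, "nonequilibrium mode requires epsInf >= 1")
    if (length(object@frozenField) > 0L &&
        !methods::is(object@frozenField[[1L]], "FrozenSlowField"))
      msg <- c(msg, "frozenField must hold a FrozenSlowField")
    if (length(msg)) msg else TRUE
  })

#' @return a `SolvationMode`.
#' @rdname SolvationMode-class
#' @export
gasMode <- function() {
  new("SolvationMode", tag = "gas", eps = NA_real_, epsInf = NA_real_,
      frozenField = list())
}

#' @param eps static dielectric constant.
#' @rdname SolvationMode-class
#' @export
equilibriumMode <- function(eps) {
  new("SolvationMode", tag = "equilibrium", eps = eps, epsInf = NA_real_,
      frozenField = list())
}

#' @param epsInf optical dielectric constant.
#' @param frozenField optional [FrozenSlowField-class]; `NULL` selects plain
#'   linear-response nonequilibrium solvation.
#' @rdname SolvationMode-class
#' @export
nonequilibriumMode <- function(epsInf, frozenField = NULL) {
  new("SolvationMode", tag = "nonequilibrium", eps = NA_real_, epsInf = epsInf,
      frozenField = if (is.null(frozenField)) list() else list(frozenField))
}

setMethod("show", "SolvationMode", function(object) {
  extra <- switch(object@tag,
    gas = "",
    equilibrium = sprintf(" (eps = %.3g)", object@eps),
    nonequilibrium = sprintf(" (epsInf = %.3g%s)", object@epsInf,
      if (length(object@frozenField)) ", frozen slow field" else ""))
  cat("SolvationMode:", object@tag, extra, "\n", sep = "")
})

## -------------------------------------------------------------- DensityGrid

#' Scalar field on an orthogonal rectangular grid
#'
#' Carrier for electron densities (e * Angstrom^-3) or orbital amplitudes on a
#' cube-style grid. File I/O follows Gaussian cube conventions (Bohr on disk,
#' Angstrom in memory); see [readCube()] / [writeCube()].
#'
#' @slot origin numeric length-3 grid origin (Angstrom).
#' @slot step numeric length-3 axis step sizes (Angstrom).
#' @slot counts integer length-3 number of points per axis.
#' @slot values numeric vector of length prod(counts), x fastest-varying last
#'   (cube ordering: z fastest).
#' @aliases DensityGrid
#' @export
setClass("DensityGrid",
  representation(origin = "numeric", step = "numeric", counts = "integer",
                 values = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 3L || length(object@step) != 3L ||
        length(object@counts) != 3L)
      msg <- c(msg, "origin, step and counts must have length 3")
    else {
      if (any(object@step <= 0)) msg <- c(msg, "step sizes must be positive")
      if (length(object@values) != prod(object@counts))
        msg <- c(msg, "values length must equal prod(counts)")
    }
    if (length(msg)) msg else TRUE
  })

#' @param origin,step,counts,values see slots.
#' @rdname DensityGrid-class
#' @export
DensityGrid <- function(origin, step, counts, values) {
  new("DensityGrid", origin = as.numeric(origin), step = as.numeric(step),
      counts = as.integer(counts), values = as.numeric(values))
}

setMethod("gridValues", "DensityGrid", function(x) x@values)

#' Grid point coordinates of a DensityGrid
#'
#' @param grid a [DensityGrid-class].
#' @return a prod(counts) x 3 matrix of Cartesian points (Angstrom), ordered
#'   with z fastest (cube ordering), matching `gridValues()`.
#' @export
gridPoints <- function(grid) {
  stopifnot(methods::is(grid, "DensityGrid"))
  ix <- seq_len(grid@counts[1L]) - 1L
  iy <- seq_len(grid@counts[2L]) - 1L
  iz <- seq_len(grid@counts[3L]) - 1L
  g <- expand.grid(z = iz, y = iy, x = ix)  # z fastest
  cbind(grid@origin[1L] + g$x * grid@step[1L],
        grid@origin[2L] + g$y * grid@step[2L],
        grid@origin[3L] + g$z * grid@step[3L])
}

#' Volume element of a DensityGrid
#' @param grid a [DensityGrid-class].
#' @return scalar voxel volume in Angstrom^3.
#' @export
voxelVolume <- function(grid) prod(grid@step)

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid: %d x %d x %d points, step (%.3f, %.3f, %.3f) A\n",
              object@counts[1L], object@counts[2L], object@counts[3L],
              object@step[1L], object@step[2L], object@step[3L]))
})

## -------------------------------------------------------- GroundStateResult

#' Converged ground-state energetics from an engine
#'
#' Energies are in hartree at the engine boundary. Polarization charges are
#' present whenever a continuum was active (empty in gas mode).
#'
#' @slot eTotal total electronic energy (hartree).
#' @slot epsHomo highest occupied orbital energy (hartree).
#' @slot epsLumo lowest unoccupied orbital energy (hartree).
#' @slot polPositions m x 3 matrix of cavity surface positions (Angstrom).
#' @slot polCharges numeric vector of apparent surface charges (e).
#' @slot density list holding at most one [DensityGrid-class].
#' @slot mode solvation tag of the run ("gas", "equilibrium", "nonequilibrium").
#' @aliases GroundStateResult
#' @export
setClass("GroundStateResult",
  representation(eTotal = "numeric", epsHomo = "numeric", epsLumo = "numeric",
                 polPositions = "matrix", polCharges = "numeric",
                 density = "list", mode = "character"),
  validity = function(object) {
    msg <- character()
    if (object@epsHomo > object@epsLumo + 1e-12)
      msg <- c(msg, "epsHomo must not exceed epsLumo for a converged result")
    if (nrow(object@polPositions) != length(object@polCharges))
      msg <- c(msg, "polarization positions/charges length mismatch")
    if (object@mode == "gas" && length(object@polCharges) > 0L)
      msg <- c(msg, "gas-mode result must carry no polarization charges")
    if (object@mode != "gas" && length(object@polCharges) == 0L)
      msg <- c(msg, "continuum result must carry polarization charges")
    if (length(msg)) msg else TRUE
  })

#' @param eTotal,epsHomo,epsLumo,polPositions,polCharges,density,mode see slots.
#' @rdname GroundStateResult-class
#' @export
GroundStateResult <- function(eTotal, epsHomo, epsLumo,
                              polPositions = matrix(numeric(), ncol = 3L),
                              polCharges = numeric(), density = NULL,
                              mode = "gas") {
  new("GroundStateResult", eTotal = eTotal, epsHomo = epsHomo,
      epsLumo = epsLumo,
      polPositions = matrix(as.numeric(polPositions), ncol = 3L),
      polCharges = as.numeric(polCharges),
      density = if (is.null(density)) list() else list(density), mode = mode)
}

setMethod("show", "GroundStateResult", function(object) {
  cat(sprintf(
    "GroundStateResult [%s]: E = %.6f Ha, epsHomo = %.4f Ha, epsLumo = %.4f Ha, %d surface charges\n",
    object@mode, object@eTotal, object@epsHomo, object@epsLumo,
    length(object@polCharges)))
})

## ------------------------------------------------------------ ExcitationSet

#' Set of electronic excitations
#'
#' Per-state excitation energies (eV, strictly positive and nondecreasing),
#' oscillator strengths (dimensionless, >= 0) and unrelaxed excited-state
#' dipole vectors (Debye).
#'
#' @slot energies numeric vector (eV), ascending.
#' @slot strengths numeric vector of oscillator strengths.
#' @slot dipoles n x 3 matrix of dipole vectors (Debye).
#' @aliases ExcitationSet
#' @export
setClass("ExcitationSet",
  representation(energies = "numeric", strengths = "numeric",
                 dipoles = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- length(object@energies)
    if (n < 1L) msg <- c(msg, "at least one state required")
    if (any(object@energies <= 0)) msg <- c(msg, "energies must be positive")
    if (is.unsorted(object@energies)) msg <- c(msg, "energies must be nondecreasing")
    if (length(object@strengths) != n || any(object@strengths < 0))
      msg <- c(msg, "oscillator strengths must be >= 0, one per state")
    if (nrow(object@dipoles) != n || ncol(object@dipoles) != 3L)
      msg <- c(msg, "dipoles must be an n x 3 matrix")
    if (length(msg)) msg else TRUE
  })

#' @param energies,strengths,dipoles see slots.
#' @rdname ExcitationSet-class
#' @examples
#' ExcitationSet(c(2.1, 2.8), c(0, 0.7), rbind(c(0, 1, 0), c(0, 14, 0)))
#' @export
ExcitationSet <- function(energies, strengths,
                          dipoles = matrix(0, length(energies), 3L)) {
  new("ExcitationSet", energies = as.numeric(energies),
      strengths = as.numeric(strengths),
      dipoles = matrix(as.numeric(dipoles), ncol = 3L))
}

setMethod("energies", "ExcitationSet", function(x) x@energies)
setMethod("oscillatorStrengths", "ExcitationSet", function(x) x@strengths)
setMethod("dipoles", "ExcitationSet", function(x) x@dipoles)
setMethod("nStates", "ExcitationSet", function(x) length(x@energies))

setMethod("show", "ExcitationSet", function(object) {
  cat(sprintf("ExcitationSet: %d states, %.3f - %.3f eV\n",
              nStates(object), min(object@energies), max(object@energies)))
})

## ---------------------------------------------------- IonizationQuantities

#' Scheme-resolved ionization quantities entering the J^2 loss
#'
#' Frontier-orbital energies and total-energy-difference ionization potentials
#' for the neutral (N) and anionic (N+1) states, each evaluated under the
#' solvation modes prescribed by the tuning scheme. All values in eV; orbital
#' energies carry their sign (negative for bound).
#'
#' @slot homoN epsilon_HOMO of the neutral (eV).
#' @slot ipN IP(N) = E(N-1) - E(N) (eV).
#' @slot homoN1 epsilon_HOMO of the anion (eV).
#' @slot ipN1 IP(N+1) = E(N) - E(N+1) (eV).
#' @slot lumoN epsilon_LUMO of the neutral (eV).
#' @slot eaN EA(N) = E(N+1) - E(N) (eV; electron-attachment convention).
#' @slot scheme tuning scheme tag ("GP", "PV", "SV" or "custom").
#' @slot gamma the gamma at which the quantities were computed (a0^-1).
#' @slot solvent solvent label (empty for gas).
#' @aliases IonizationQuantities
#' @export
setClass("IonizationQuantities",
  representation(homoN = "numeric", ipN = "numeric", homoN1 = "numeric",
                 ipN1 = "numeric", lumoN = "numeric", eaN = "numeric",
                 scheme = "character", gamma = "numeric",
                 solvent = "character"),
  validity = function(object) {
    vals <- c(object@homoN, object@ipN, object@homoN1, object@ipN1)
    if (!all(is.finite(vals))) "quantities must be finite" else TRUE
  })

#' @param homoN,ipN,homoN1,ipN1,lumoN,eaN,scheme,gamma,solvent see slots.
#' @rdname IonizationQuantities-class
#' @export
IonizationQuantities <- function(homoN, ipN, homoN1, ipN1,
                                 lumoN = NA_real_, eaN = NA_real_,
                                 scheme = "custom", gamma = NA_real_,
                                 solvent = "") {
  new("IonizationQuantities", homoN = homoN, ipN = ipN, homoN1 = homoN1,
      ipN1 = ipN1, lumoN = lumoN, eaN = eaN, scheme = scheme, gamma = gamma,
      solvent = solvent)
}

setMethod("show", "IonizationQuantities", function(object) {
  cat(sprintf(
    "IonizationQuantities [%s, gamma = %.3f]: homoN = %.3f, ipN = %.3f, homoN1 = %.3f, ipN1 = %.3f eV\n",
    object@scheme, object@gamma, object@homoN, object@ipN, object@homoN1,
    object@ipN1))
})

## ------------------------------------------------------ GammaScan / Tuning

#' J^2 values over a gamma grid
#'
#' @slot gamma strictly increasing grid of gamma values (a0^-1).
#' @slot j2 J^2 loss at each grid point (eV^2, >= 0).
#' @slot points list of per-point [IonizationQuantities-class] (may be empty
#'   for function-backed scans).
#' @aliases GammaScan
#' @export
setClass("GammaScan",
  representation(gamma = "numeric", j2 = "numeric", points = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@gamma) != length(object@j2))
      msg <- c(msg, "gamma and j2 must have matching length")
    if (is.unsorted(object@gamma, strictly = TRUE))
      msg <- c(msg, "gamma grid must be strictly increasing")
    if (any(object@j2 < -1e-12)) msg <- c(msg, "J^2 must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' @param gamma,j2,points see slots.
#' @rdname GammaScan-class
#' @export
GammaScan <- function(gamma, j2, points = list()) {
  new("GammaScan", gamma = as.numeric(gamma), j2 = as.numeric(j2),
      points = points)
}

#' Result of the two-round gamma search
#'
#' @slot gammaOpt selected optimum gamma (a0^-1), a round-2 grid point.
#' @slot j2Opt J^2 at the optimum (eV^2), the round-2 minimum.
#' @slot round1 coarse [GammaScan-class] (step 0.15).
#' @slot round2 fine [GammaScan-class] (step 0.02).
#' @slot scheme tuning scheme tag.
#' @slot variant loss variant tag ("full", "ip_only", "ea_form").
#' @aliases TuningResult
#' @export
setClass("TuningResult",
  representation(gammaOpt = "numeric", j2Opt = "numeric",
                 round1 = "GammaScan", round2 = "GammaScan",
                 scheme = "character", variant = "character"),
  validity = function(object) {
    msg <- character()
    if (!any(abs(object@round2@gamma - object@gammaOpt) < 1e-9))
      msg <- c(msg, "gammaOpt must lie on the round-2 grid")
    if (abs(object@j2Opt - min(object@round2@j2)) > 1e-9)
      msg <- c(msg, "j2Opt must be the round-2 minimum")
    if (length(msg)) msg else TRUE
  })

setMethod("gammaOpt", "TuningResult", function(x) x@gammaOpt)
setMethod("j2Opt", "TuningResult", function(x) x@j2Opt)

setMethod("show", "TuningResult", function(object) {
  cat(sprintf(
    "TuningResult [%s/%s]: gamma* = %.2f a0^-1, J^2 = %.4g eV^2 (%d + %d grid points)\n",
    object@scheme, object@variant, object@gammaOpt, object@j2Opt,
    length(object@round1@gamma), length(object@round2@gamma)))
})

## ---------------------------------------------------------------- Spectrum

#' Convolved absorption spectrum
#'
#' @slot energy strictly increasing energy grid (eV) spanning all state
#'   energies +/- 3 FWHM.
#' @slot intensity nonnegative intensity (arbitrary units).
#' @slot states the source [ExcitationSet-class].
#' @slot fwhm Gaussian full width at half maximum (eV).
#' @aliases Spectrum
#' @export
setClass("Spectrum",
  representation(energy = "numeric", intensity = "numeric",
                 states = "ExcitationSet", fwhm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@energy) != length(object@intensity))
      msg <- c(msg, "energy and intensity must have matching length")
    if (is.unsorted(object@energy, strictly = TRUE))
      msg <- c(msg, "energy grid must be strictly increasing")
    if (any(object@intensity < 0)) msg <- c(msg, "intensity must be >= 0")
    es <- energies(object@states)
    if (min(object@energy) > min(es) - 3 * object@fwhm + 1e-9 ||
        max(object@energy) < max(es) + 3 * object@fwhm - 1e-9)
      msg <- c(msg, "grid must span all state energies +/- 3 FWHM")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d grid points, %.3f - %.3f eV, FWHM %.2f eV\n",
              length(object@energy), min(object@energy), max(object@energy),
              object@fwhm))
})

## ---------------------------------------------------- FractionalChargeCurve

#' Fractional-charge energy and delocalization-error curves
#'
#' E(q) interpolates between the N-electron state (q = 0) and the N+1 anionic
#' state (q = 1); F(q) = E(q) - (Delta E) q vanishes identically for perfect
#' piecewise linearity (no delocalization error). Negative F corresponds to
#' delocalization error, positive to overlocalization.
#'
#' @slot q fractional-charge grid in [0, 1].
#' @slot E energy curve E(q) (eV).
#' @slot F residual curve F(q) (eV).
#' @slot deltaE Delta E = IP(N+1) (eV).
#' @slot epsLumoN epsilon_LUMO of the neutral (eV).
#' @slot epsHomoN1 epsilon_HOMO of the anion (eV).
#' @aliases FractionalChargeCurve
#' @export
setClass("FractionalChargeCurve",
  representation(q = "numeric", E = "numeric", F = "numeric",
                 deltaE = "numeric", epsLumoN = "numeric",
                 epsHomoN1 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@q) != length(object@E) ||
        length(object@q) != length(object@F))
      msg <- c(msg, "q, E and F must have matching length")
    if (any(object@q < 0 | object@q > 1))
      msg <- c(msg, "q must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FractionalChargeCurve", function(object) {
  cat(sprintf(
    "FractionalChargeCurve: %d points, deltaE = %.3f eV, max|F| = %.4f eV\n",
    length(object@q), object@deltaE, max(abs(object@F))))
})

## --------------------------------------------------------- HirshfeldReport

#' One-particle-picture compliance report
#'
#' Compares the per-atom Hirshfeld populations of the ionization density
#' difference against those of the squared HOMO; compliance requires a
#' squared Pearson correlation above 0.90.
#'
#' @slot popDeltaRho per-atom populations of the density difference (e).
#' @slot popHomoSq per-atom populations of |phi_HOMO|^2 (e).
#' @slot r2 squared Pearson correlation coefficient.
#' @slot compliant logical, `r2 > 0.90`.
#' @aliases HirshfeldReport
#' @export
setClass("HirshfeldReport",
  representation(popDeltaRho = "numeric", popHomoSq = "numeric",
                 r2 = "numeric", compliant = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@popDeltaRho) != length(object@popHomoSq))
      msg <- c(msg, "population vectors must have matching length")
    if (!is.finite(object@r2) || object@r2 < 0 || object@r2 > 1 + 1e-12)
      msg <- c(msg, "r2 must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "HirshfeldReport", function(object) {
  cat(sprintf("HirshfeldReport: %d atoms, R^2 = %.4f (%s)\n",
              length(object@popDeltaRho), object@r2,
              if (object@compliant) "compliant" else "non-compliant"))
})

## --------------------------------------------------------------- DimerScan

#' Donor-acceptor separation scan
#'
#' Monomer A stays at the origin; monomer B is translated along +z to each
#' separation. Separations are center-to-center distances in Angstrom.
#'
#' @slot monA,monB the recentered monomers ([Molecule-class]).
#' @slot separations strictly increasing separations (Angstrom).
#' @slot geometries list of dimer [Molecule-class] objects, one per separation.
#' @aliases DimerScan
#' @export
setClass("DimerScan",
  representation(monA = "Molecule", monB = "Molecule",
                 separations = "numeric", geometries = "list"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@separations, strictly = TRUE))
      msg <- c(msg, "separations must be strictly increasing")
    if (length(object@geometries) != length(object@separations))
      msg <- c(msg, "one geometry required per separation")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DimerScan", function(object) {
  cat(sprintf("DimerScan: %d geometries, R = %.2f - %.2f A\n",
              length(object@separations), min(object@separations),
              max(object@separations)))
})

## ------------------------------------------------------------ ErrorSummary

#' Benchmark error statistics
#'
#' @slot n number of records.
#' @slot mae mean absolute error (eV).
#' @slot msd mean signed deviation (eV).
#' @slot bySolvent optional per-solvent breakdown (data.frame with columns
#'   solvent, n, mae, msd).
#' @aliases ErrorSummary
#' @export
setClass("ErrorSummary",
  representation(n = "integer", mae = "numeric", msd = "numeric",
                 bySolvent = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@mae < 0) msg <- c(msg, "mae must be >= 0")
    if (object@mae < abs(object@msd) - 1e-12)
      msg <- c(msg, "mae must be >= |msd|")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ErrorSummary", function(object) {
  cat(sprintf("ErrorSummary: n = %d, MAE = %.4f eV, MSD = %+.4f eV\n",
              object@n, object@mae, object@msd))
})
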