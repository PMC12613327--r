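#' @include AllClasses.R engine-mock.R pcm.R
NULL

#' Koopmans residual loss J^2(gamma)
#'
#' The tuning objective
#' `J^2 = (eps_HOMO(N) + IP(N))^2 + (eps_HOMO(N+1) + IP(N+1))^2`
#' with orbital energies signed as orbital energies (negative for bound
#' states). Variants: `"ip_only"` keeps only the first (neutral) term;
#' `"ea_form"` replaces the second term with
#' `(eps_LUMO(N) + EA(N))^2`, `EA(N) = E(N+1) - E(N)`.
#'
#' @param q an [IonizationQuantities-class].
#' @param variant `"full"`, `"ip_only"` or `"ea_form"`.
#' @return scalar loss in eV^2.
#' @examples
#' q <- IonizationQuantities(homoN = -7, ipN = 6.8, homoN1 = -1, ipN1 = 1.1)
#' j2Loss(q)              # 0.04 + 0.01
#' j2Loss(q, "ip_only")   # 0.04
#' @export
j2Loss <- function(q, variant = c("full", "ip_only", "ea_form")) {
  stopifnot(methods::is(q, "IonizationQuantities"))
  variant <- match.arg(variant)
  t1 <- (q@homoN + q@ipN)^2
  if (variant == "ip_only") return(t1)
  if (variant == "ea_form") {
    if (!is.finite(q@lumoN) || !is.finite(q@eaN))
      stop("ea_form variant requires lumoN and eaN")
    return(t1 + (q@lumoN + q@eaN)^2)
  }
  t1 + (q@homoN1 + q@ipN1)^2
}

#' Scheme-specific ionization quantities
#'
#' Runs the charge-state calculations a tuning scheme prescribes and collects
#' the quantities entering [j2Loss()]:
#' \describe{
#'   \item{GP}{three gas-phase runs (N, N-1, N+1).}
#'   \item{PV}{three equilibrium-continuum runs at the static eps.}
#'   \item{SV}{one equilibrium run for the neutral; its polarization charges
#'     are partitioned ([partitionCharges()]) and the slow component frozen;
#'     the two ion runs use nonequilibrium solvation at eps_inf with the
#'     frozen field.}
#' }
#' HOMO energies come from the neutral (N) and anion (N+1) runs; IPs are
#' total-energy differences `IP(N) = E(N-1) - E(N)`,
#' `IP(N+1) = E(N) - E(N+1)`, each state under its scheme mode. Engine
#' energies (hartree) are converted to eV here.
#'
#' @param engine an engine object.
#' @param molecule a neutral [Molecule-class].
#' @param params a [RSHParams-class].
#' @param scheme `"GP"`, `"PV"` or `"SV"`.
#' @param solvent a [SolventSpec-class] (ignored by GP).
#' @return an [IonizationQuantities-class].
#' @export
ionizationQuantities <- function(engine, molecule, params,
                                 scheme = c("GP", "PV", "SV"),
                                 solvent = NULL) {
  scheme <- match.arg(scheme)
  if (netCharge(molecule) != 0L)
    stop("tuning starts from a neutral molecule")
  if (scheme != "GP" && is.null(solvent))
    stop(scheme, " scheme requires a solvent")
  cation <- setCharge(molecule, +1L)
  anion <- setCharge(molecule, -1L)
  run <- function(mol, mode, label) {
    tryCatch(runGroundState(engine, mol, params, mode),
             error = function(e) stop(sprintf(
               "engine failure [%s state, %s mode]: %s",
               label, mode@tag, conditionMessage(e)), call. = FALSE))
  }
  if (scheme == "GP") {
    modeN <- modeIon <- gasMode()
    resN <- run(molecule, modeN, "neutral")
  } else if (scheme == "PV") {
    modeN <- modeIon <- equilibriumMode(solvent@eps)
    resN <- run(molecule, modeN, "neutral")
  } else {
    modeN <- equilibriumMode(solvent@eps)
    resN <- run(molecule, modeN, "neutral")
    field <- freezeSlowField(resN, solvent@eps, solvent@epsInf,
                             provenance = sprintf(
                               "equilibrium neutral run, %s, gamma = %.4f",
                               solvent@name, params@gamma))
    modeIon <- nonequilibriumMode(solvent@epsInf, field)
  }
  resC <- run(cation, modeIon, "cation")
  resA <- run(anion, modeIon, "anion")
  ev <- function(x) x * HARTREE_EV
  IonizationQuantities(
    homoN = ev(resN@epsHomo),
    ipN = ev(resC@eTotal - resN@eTotal),
    homoN1 = ev(resA@epsHomo),
    ipN1 = ev(resN@eTotal - resA@eTotal),
    lumoN = ev(resN@epsLumo),
    eaN = ev(resA@eTotal - resN@eTotal),
    scheme = scheme, gamma = params@gamma,
    solvent = if (scheme == "GP") "" else solvent@name)
}

## Round-2 grid: [max(0, gamma1 - halfWidth), gamma1 + halfWidth] in steps of
## step, the lower edge clipped at zero (negative gamma is unphysical).
.round2Grid <- function(gamma1, halfWidth = 0.15, step = 0.02) {
  round(seq(max(0, gamma1 - halfWidth), gamma1 + halfWidth + 1e-12,
            by = step), 10)
}

#' Two-round grid search over gamma for an arbitrary loss function
#'
#' Round 1 evaluates `j2fun` on a coarse grid (default 0.00-0.60, step
#' 0.15 a0^-1) and takes its argmin gamma_1; round 2 refines on
#' `[max(0, gamma_1 - 0.15), gamma_1 + 0.15]` with step 0.02 (values clipped
#' at zero: negative gamma is unphysical). Exact ties resolve to the smaller
#' gamma. Grid points shared between rounds are evaluated once (cached).
#'
#' @param j2fun function gamma -> J^2 (eV^2).
#' @param round1 coarse grid (strictly increasing).
#' @param halfWidth,step round-2 window half-width and step (a0^-1).
#' @param scheme,variant tags recorded on the result.
#' @param pointFun optional function gamma -> [IonizationQuantities-class]
#'   stored per grid point.
#' @return a [TuningResult-class].
#' @examples
#' res <- gammaGridSearch(function(g) (g - 0.137)^2)
#' gammaOpt(res)   # 0.14
#' @export
gammaGridSearch <- function(j2fun, round1 = seq(0, 0.60, by = 0.15),
                            halfWidth = 0.15, step = 0.02,
                            scheme = "custom", variant = "full",
                            pointFun = NULL) {
  if (length(round1) < 1L) stop("round-1 grid must be nonempty")
  cache <- new.env(parent = emptyenv())
  evalAt <- function(g) {
    key <- sprintf("%.10f", g)
    if (!is.null(got <- get0(key, envir = cache))) return(got)
    val <- tryCatch(j2fun(g), error = function(e) {
      done <- ls(cache)
      stop(sprintf(
        "loss evaluation failed at gamma = %.4f (completed points: %s): %s",
        g, if (length(done)) paste(done, collapse = ", ") else "none",
        conditionMessage(e)), call. = FALSE)
    })
    assign(key, val, envir = cache)
    val
  }
  scanAt <- function(grid) {
    j2 <- vapply(grid, evalAt, numeric(1L))
    pts <- if (is.null(pointFun)) list() else lapply(grid, pointFun)
    GammaScan(grid, j2, pts)
  }
  s1 <- scanAt(round1)
  g1 <- s1@gamma[which.min(s1@j2)]   # first minimum = smallest gamma on ties
  s2 <- scanAt(.round2Grid(g1, halfWidth, step))
  iopt <- which.min(s2@j2)
  new("TuningResult", gammaOpt = s2@gamma[iopt], j2Opt = s2@j2[iopt],
      round1 = s1, round2 = s2, scheme = scheme, variant = variant)
}

#' Two-round optimal-gamma search for a molecule under a tuning scheme
#'
#' Wraps [ionizationQuantities()] and [j2Loss()] into the two-round grid
#' search of [gammaGridSearch()]. Scheme-level caching keys each gamma so
#' round 2 reuses overlapping round-1 points.
#'
#' @inheritParams ionizationQuantities
#' @param variant loss variant, see [j2Loss()].
#' @param alpha,beta short-range Fock fraction and long-range increment held
#'   fixed during the scan.
#' @param round1,halfWidth,step grid parameters, see [gammaGridSearch()].
#' @return a [TuningResult-class] with per-point
#'   [IonizationQuantities-class] in both scans.
#' @examples
#' eng <- mockEngine()
#' mol <- Molecule("C", matrix(0, 1, 3))
#' res <- twoRoundSearch(eng, mol, scheme = "GP")
#' gammaOpt(res)
#' @export
twoRoundSearch <- function(engine, molecule, scheme = c("GP", "PV", "SV"),
                           solvent = NULL,
                           variant = c("full", "ip_only", "ea_form"),
                           alpha = 0.2, beta = 0.8,
                           round1 = seq(0, 0.60, by = 0.15),
                           halfWidth = 0.15, step = 0.02) {
  scheme <- match.arg(scheme)
  variant <- match.arg(variant)
  qCache <- new.env(parent = emptyenv())
  qAt <- function(g) {
    key <- sprintf("%.10f", g)
    if (!is.null(got <- get0(key, envir = qCache))) return(got)
    q <- ionizationQuantities(engine, molecule,
                              RSHParams(alpha, beta, gamma = g),
                              scheme = scheme, solvent = solvent)
    assign(key, q, envir = qCache)
    q
  }
  gammaGridSearch(function(g) j2Loss(qAt(g), variant),
                  round1 = round1, halfWidth = halfWidth, step = step,
                  scheme = scheme, variant = variant, pointFun = qAt)
}

#' Screened-RSH beta rule
#'
#' Sets the long-range exact-exchange fraction so that
#' `alpha + beta = 1 / epsTarget`, mimicking dielectric screening of the
#' long-range exchange; `epsTarget` is the static or optical dielectric
#' constant depending on the screening variant desired. Gamma is left to the
#' caller.
#'
#' @param alpha short-range Fock fraction (must not exceed `1/epsTarget`).
#' @param epsTarget dielectric constant (>= 1).
#' @param gamma range-separation parameter carried through.
#' @return an [RSHParams-class] with `beta = 1/epsTarget - alpha`.
#' @examples
#' srshBeta(0.2, 2.0)   # beta = 0.3
#' @export
srshBeta <- function(alpha, epsTarget, gamma = 0.2) {
  if (epsTarget < 1) stop("epsTarget must be >= 1")
  if (alpha > 1 / epsTarget)
    stop(sprintf("alpha = %.3f exceeds 1/epsTarget = %.3f: negative beta not permitted",
                 alpha, 1 / epsTarget))
  RSHParams(alpha = alpha, beta = 1 / epsTarget - alpha, gamma = gamma)
}
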