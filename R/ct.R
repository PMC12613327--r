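#' @include AllClasses.R
NULL

#' Build a donor-acceptor separation scan
#'
#' Recenters both monomers (geometric center to the origin; input monomers
#' are conventionally laid out in the xOz plane) and translates monomer B
#' along +z to each separation `r_min, r_min + step, ..., r_max`, producing
#' `floor((r_max - r_min)/step) + 1` dimer geometries. The defaults (5-9
#' Angstrom, step 0.5) give the 9-conformer scan used for charge-transfer
#' asymptote analysis. Atoms of A and B closer than 0.7 Angstrom at the
#' smallest separation trigger a warning, not an error.
#'
#' @param monA,monB monomer [Molecule-class] objects.
#' @param rMin,rMax,step scan range and step (Angstrom); `step > 0`,
#'   `rMin <= rMax`.
#' @return a [DimerScan-class].
#' @examples
#' eth <- Molecule(c("C", "C"), rbind(c(-0.67, 0, 0), c(0.67, 0, 0)))
#' scan <- buildDimerScan(eth, eth)
#' length(scan@separations)   # 9
#' @export
buildDimerScan <- function(monA, monB, rMin = 5.0, rMax = 9.0, step = 0.5) {
  stopifnot(step > 0, rMin <= rMax)
  recenter <- function(m) {
    Molecule(elements(m), sweep(coords(m), 2L, colMeans(coords(m))),
             charge = netCharge(m), multiplicity = m@multiplicity)
  }
  monA <- recenter(monA)
  monB <- recenter(monB)
  seps <- rMin + step * seq(0L, floor((rMax - rMin) / step + 1e-9))
  geoms <- lapply(seps, function(R) {
    cb <- coords(monB)
    cb[, 3L] <- cb[, 3L] + R
    Molecule(c(elements(monA), elements(monB)), rbind(coords(monA), cb),
             charge = netCharge(monA) + netCharge(monB))
  })
  dmin <- min(as.matrix(stats::dist(coords(geoms[[1L]])))[
    seq_len(nAtoms(monA)), nAtoms(monA) + seq_len(nAtoms(monB))])
  if (dmin < 0.7)
    warning(sprintf(
      "atoms overlap at smallest separation (closest A-B pair %.2f A)", dmin))
  new("DimerScan", monA = monA, monB = monB, separations = seps,
      geometries = geoms)
}

#' Point-charge charge-transfer asymptote
#'
#' Reference CT excitation energy treating the electron and hole as a pair of
#' opposite unit point charges screened by the optical dielectric:
#' `IP + EA - 14.3996 / (epsInf * R)` (eV, Angstrom). At `epsInf = 1` this is
#' the Mulliken rule for vacuum CT excitations; as `R -> Inf` it tends to
#' `IP + EA`.
#'
#' @param ip donor ionization potential (eV), solution-phase with the cation
#'   under nonequilibrium solvation when a solvent is present.
#' @param ea acceptor electron-attachment energy `E(N+1) - E(N)` (eV), same
#'   convention.
#' @param R donor-acceptor separation (Angstrom, > 0).
#' @param epsInf optical dielectric constant (>= 1).
#' @return CT reference energy (eV).
#' @examples
#' ctEnergyPointCharge(10, 0, R = 14.3996, epsInf = 1)   # 9.0
#' @export
ctEnergyPointCharge <- function(ip, ea, R, epsInf = 1) {
  stopifnot(R > 0, epsInf >= 1)
  ip + ea - COULOMB_EV_ANG / (epsInf * R)
}

#' Atomic-charge charge-transfer asymptote
#'
#' Refines the point-charge reference by representing the donor cation and
#' acceptor anion with atomic charge distributions:
#' `IP + EA + sum_i sum_j 14.3996 q_i q_j / (epsInf r_ij)` over all A-B atom
#' pairs. Reduces exactly to [ctEnergyPointCharge()] for single opposite unit
#' charges and converges to it as the separation grows.
#'
#' @inheritParams ctEnergyPointCharge
#' @param chargesA,chargesB lists with elements `positions` (m x 3 matrix,
#'   Angstrom) and `charges` (e), e.g. from [readChargesCSV()].
#' @return CT reference energy (eV).
#' @export
ctEnergyAtomicCharges <- function(ip, ea, chargesA, chargesB, epsInf = 1) {
  stopifnot(epsInf >= 1)
  pa <- matrix(as.numeric(chargesA$positions), ncol = 3L)
  pb <- matrix(as.numeric(chargesB$positions), ncol = 3L)
  qa <- chargesA$charges
  qb <- chargesB$charges
  stopifnot(nrow(pa) == length(qa), nrow(pb) == length(qb))
  inter <- 0
  for (i in seq_along(qa)) {
    r <- sqrt((pb[, 1L] - pa[i, 1L])^2 + (pb[, 2L] - pa[i, 2L])^2 +
              (pb[, 3L] - pa[i, 3L])^2)
    if (any(r < 1e-6))
      stop(sprintf("singular atom pair: A atom %d within 1e-6 A of B atom %d",
                   i, which(r < 1e-6)[1L]))
    inter <- inter + sum(COULOMB_EV_ANG * qa[i] * qb / (epsInf * r))
  }
  ip + ea + inter
}

#' Select the charge-transfer state of an excitation set
#'
#' The CT state is the first (lowest-energy) state whose unrelaxed
#' excited-state dipole component along the chosen axis exceeds the threshold
#' in magnitude (default 12.5 D along y, the donor-acceptor axis convention
#' of the dimer scans being perpendicular to the molecular planes).
#'
#' @param states an [ExcitationSet-class].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param threshold dipole magnitude threshold (Debye).
#' @return 1-based state index, or `NA_integer_` if no state qualifies.
#' @examples
#' es <- ExcitationSet(c(2, 3, 4), c(1, 1, 1),
#'                     cbind(0, c(2, 30, 5), 0))
#' selectCtState(es)   # 2
#' @export
selectCtState <- function(states, axis = c("y", "x", "z"), threshold = 12.5) {
  stopifnot(methods::is(states, "ExcitationSet"))
  axis <- match.arg(axis)
  comp <- dipoles(states)[, match(axis, c("x", "y", "z"))]
  hit <- which(abs(comp) > threshold)
  if (length(hit)) hit[1L] else NA_integer_
}
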