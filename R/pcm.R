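#' @include AllClasses.R
NULL

#' Partition equilibrium polarization charges into fast and slow components
#'
#' Marcus-type partition of conductor-like PCM apparent surface charges: the
#' slow (nuclear/orientational) fraction is
#' `f_slow = (eps - eps_inf) / (eps - 1)` of the equilibrium charge at every
#' surface point, and the fast (electronic) component is the remainder.
#' Positions are unchanged; `q_fast + q_slow = q_eq` holds elementwise by
#' construction. At `eps = 1` (pure gas limit) `f_slow` is defined as 0.
#'
#' @param positions m x 3 matrix of surface positions (Angstrom).
#' @param charges equilibrium polarization charges (e), nonempty.
#' @param eps static dielectric constant (>= eps_inf).
#' @param epsInf optical dielectric constant (>= 1).
#' @return a list with numeric vectors `fast` and `slow`, the shared
#'   `positions`, and the scalar `fSlow`.
#' @examples
#' partitionCharges(matrix(0, 1, 3), 1.0, eps = 8.93, epsInf = 2.03)$slow
#' @export
partitionCharges <- function(positions, charges, eps, epsInf) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  if (length(charges) < 1L) stop("charges must be nonempty")
  if (!(epsInf >= 1 && eps >= epsInf))
    stop("require 1 <= epsInf <= eps")
  fSlow <- if (eps == 1) 0 else (eps - epsInf) / (eps - 1)
  slow <- fSlow * charges
  list(fast = charges - slow, slow = slow, positions = positions,
       fSlow = fSlow)
}

#' Freeze the slow component of an equilibrium run
#'
#' Convenience wrapper: partitions the polarization charges of an equilibrium
#' [GroundStateResult-class] and wraps the slow component as a
#' [FrozenSlowField-class] for subsequent nonequilibrium runs.
#'
#' @param result an equilibrium-mode [GroundStateResult-class].
#' @param eps,epsInf dielectric constants of the source solvent.
#' @param provenance text recorded on the field.
#' @return a [FrozenSlowField-class].
#' @export
freezeSlowField <- function(result, eps, epsInf,
                            provenance = "equilibrium neutral run") {
  stopifnot(methods::is(result, "GroundStateResult"))
  if (result@mode != "equilibrium")
    stop("slow field must come from an equilibrium run")
  p <- partitionCharges(result@polPositions, result@polCharges, eps, epsInf)
  FrozenSlowField(p$positions, p$slow, provenance = provenance)
}

#' Electrostatic potential of a frozen slow field
#'
#' Bare Coulomb potential of the slow point charges,
#' `V(r) = sum_i k q_i / |r - r_i|` with `k = 14.3996 eV Angstrom / e^2`,
#' i.e. the potential energy per unit positive test charge in eV.
#'
#' @param field a [FrozenSlowField-class].
#' @param points p x 3 matrix of evaluation points (Angstrom); none may fall
#'   within 1e-6 Angstrom of a source charge.
#' @return numeric vector of potentials (eV per unit charge), linear in the
#'   charge vector.
#' @export
slowFieldPotential <- function(field, points) {
  stopifnot(methods::is(field, "FrozenSlowField"))
  points <- matrix(as.numeric(points), ncol = 3L)
  if (length(field@charges) == 0L) return(rep(0, nrow(points)))
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt(rowSums(sweep(field@positions, 2L, points[i, ])^2))
    bad <- which(d < 1e-6)
    if (length(bad))
      stop(sprintf(
        "evaluation point %d coincides with source charge %d (r = %.2e A)",
        i, bad[1L], d[bad[1L]]))
    sum(COULOMB_EV_ANG * field@charges / d)
  }, numeric(1L))
}
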