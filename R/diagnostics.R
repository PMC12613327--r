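#' @include AllClasses.R
NULL

#' Fractional-charge energy curve and delocalization error
#'
#' Cubic-in-q interpolation of the energy between the N-electron state
#' (q = 0) and the N+1-electron anion (q = 1), built from three scalars:
#' `Delta E = IP(N+1)`, the neutral LUMO energy and the anion HOMO energy.
#' \deqn{E(q) = \Delta E\,q + [(\epsilon_{LUMO}(N) - \Delta E)(1-q) +
#'   (\Delta E - \epsilon_{HOMO}(N+1))q]\,q(1-q)}
#' The residual `F(q) = E(q) - Delta E * q` vanishes identically iff both
#' frontier energies satisfy Koopmans at the edges
#' (`eps_LUMO(N) = Delta E = eps_HOMO(N+1)`); its midpoint value has the
#' closed form `F(1/2) = (eps_LUMO(N) - eps_HOMO(N+1)) / 8`.
#'
#' @param ipN1 Delta E = IP(N+1) (eV).
#' @param epsLumoN neutral LUMO energy (eV).
#' @param epsHomoN1 anion HOMO energy (eV).
#' @param nPoints number of q samples (>= 3).
#' @return a [FractionalChargeCurve-class].
#' @examples
#' crv <- fractionalChargeCurve(1.0, epsLumoN = 1.0, epsHomoN1 = -3.0)
#' max(abs(crv@F[c(1, length(crv@q))]))  # endpoints exact
#' @export
fractionalChargeCurve <- function(ipN1, epsLumoN, epsHomoN1, nPoints = 101L) {
  stopifnot(is.finite(ipN1), is.finite(epsLumoN), is.finite(epsHomoN1),
            nPoints >= 3L)
  q <- seq(0, 1, length.out = as.integer(nPoints))
  dE <- ipN1
  bracket <- (epsLumoN - dE) * (1 - q) + (dE - epsHomoN1) * q
  Fq <- bracket * q * (1 - q)
  new("FractionalChargeCurve", q = q, E = dE * q + Fq, F = Fq,
      deltaE = dE, epsLumoN = epsLumoN, epsHomoN1 = epsHomoN1)
}

## ------------------------------------------------- free-atom radial profiles

## Synthetic spherically-averaged free-atom densities built from normalized
## Slater-type shells (Slater screening constants). Real tuned-functional
## densities are not redistributable; these stand in for the promolecule
## weights, whose ratios are what the Hirshfeld partition consumes.
.slaterShells <- list(
  H = data.frame(n = 1, nel = 1, zeta = 1.00),
  C = data.frame(n = c(1, 2), nel = c(2, 4), zeta = c(5.70, 3.25 / 2)),
  N = data.frame(n = c(1, 2), nel = c(2, 5), zeta = c(6.70, 3.90 / 2)),
  O = data.frame(n = c(1, 2), nel = c(2, 6), zeta = c(7.70, 4.55 / 2)),
  F = data.frame(n = c(1, 2), nel = c(2, 7), zeta = c(8.70, 5.20 / 2)),
  P = data.frame(n = c(1, 2, 3), nel = c(2, 8, 5),
                 zeta = c(14.70, 10.85 / 2, 4.80 / 3)),
  S = data.frame(n = c(1, 2, 3), nel = c(2, 8, 6),
                 zeta = c(15.70, 11.85 / 2, 5.45 / 3)),
  Cl = data.frame(n = c(1, 2, 3), nel = c(2, 8, 7),
                  zeta = c(16.70, 12.85 / 2, 6.10 / 3)))

## Density (e / Angstrom^3) of a synthetic free atom at radius r (Angstrom).
.slaterDensity <- function(element, r) {
  sh <- .slaterShells[[element]]
  if (is.null(sh))
    stop(sprintf("no free-atom profile for element '%s'", element))
  rb <- r / BOHR_ANG   # Slater exponents are in a0^-1
  rho <- 0
  for (i in seq_len(nrow(sh))) {
    n <- sh$n[i]; z <- sh$zeta[i]
    norm <- sh$nel[i] * (2 * z)^(2 * n + 1) / (4 * pi * factorial(2 * n))
    rho <- rho + norm * rb^(2 * n - 2) * exp(-2 * z * rb)
  }
  rho / BOHR_ANG^3
}

#' Free-atom radial density profiles for Hirshfeld weights
#'
#' Loads the packaged synthetic radial table (one spherically averaged
#' density per element, integrating to the atomic number) and returns
#' per-element interpolators. Profiles are tabulated on a log-radial grid and
#' interpolated log-log; radii beyond the table evaluate to zero. The table
#' (`inst/extdata/free_atom_profiles_synthetic.csv`) is swappable via `path`.
#'
#' @param elements character vector of element symbols to load.
#' @param path CSV with columns `element, r, rho` (Angstrom, e/Angstrom^3);
#'   defaults to the packaged synthetic table.
#' @return named list of functions `r -> rho` (vectorized).
#' @export
freeAtomProfiles <- function(elements,
                             path = system.file("extdata",
                               "free_atom_profiles_synthetic.csv",
                               package = "tuneRSH")) {
  tab <- utils::read.csv(path)
  elements <- unique(elements)
  missing <- setdiff(elements, unique(tab$element))
  if (length(missing))
    stop("no free-atom profile for element(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(elements, function(el) {
    sub <- tab[tab$element == el, ]
    lr <- log(sub$r); lrho <- log(pmax(sub$rho, 1e-300))
    rmin <- min(sub$r); rmax <- max(sub$r)
    function(r) {
      r <- pmax(r, rmin)
      v <- exp(stats::approx(lr, lrho, xout = log(r), rule = 2)$y)
      v[r > rmax] <- 0
      v
    }
  })
  names(out) <- elements
  out
}

## Normalize a profiles argument to a named list of functions.
.asProfileFuns <- function(profiles, elements) {
  missing <- setdiff(unique(elements), names(profiles))
  if (length(missing))
    stop("missing free-atom profile for element(s): ",
         paste(missing, collapse = ", "))
  lapply(profiles, function(p) {
    if (is.function(p)) return(p)
    stopifnot(is.data.frame(p), all(c("r", "rho") %in% names(p)))
    local({
      rr <- p$r; dd <- p$rho
      function(r) {
        out <- stats::approx(rr, dd, xout = pmin(pmax(r, min(rr)), max(rr)),
                             rule = 2)$y
        out[r > max(rr)] <- 0
        out
      }
    })
  })
}

#' Hirshfeld atomic populations on a rectangular grid
#'
#' Partitions a scalar field among atoms with promolecule stockholder
#' weights: `w_A(r) = rho_A^free(|r - R_A|) / sum_B rho_B^free(|r - R_B|)`,
#' evaluated where the promolecule density exceeds a floor (grid points below
#' it contribute nothing, avoiding 0/0). Populations are Riemann sums
#' `pop_A = sum_r w_A(r) rho(r) dV` over the cube-style grid — the
#' backend-agnostic counterpart of multicenter atomic quadrature.
#'
#' @param density a [DensityGrid-class] (values in e/Angstrom^3, or any
#'   scalar field such as a squared orbital).
#' @param elements character vector of atom element symbols.
#' @param positions n x 3 matrix of atom positions (Angstrom).
#' @param profiles named list of per-element radial densities (functions
#'   `r -> rho` or data.frames with columns r, rho); defaults to the packaged
#'   synthetic table via [freeAtomProfiles()].
#' @param floor promolecule density floor (e/Angstrom^3) below which a grid
#'   point is skipped.
#' @return numeric vector of per-atom populations (same units as the field
#'   integral).
#' @export
hirshfeldPopulations <- function(density, elements, positions,
                                 profiles = freeAtomProfiles(elements),
                                 floor = 1e-12) {
  stopifnot(methods::is(density, "DensityGrid"))
  positions <- matrix(as.numeric(positions), ncol = 3L)
  stopifnot(length(elements) == nrow(positions))
  funs <- .asProfileFuns(profiles, elements)
  pts <- gridPoints(density)
  nA <- length(elements)
  free <- matrix(0, nrow(pts), nA)
  for (a in seq_len(nA)) {
    d <- sqrt((pts[, 1L] - positions[a, 1L])^2 +
              (pts[, 2L] - positions[a, 2L])^2 +
              (pts[, 3L] - positions[a, 3L])^2)
    free[, a] <- funs[[elements[a]]](d)
  }
  promol <- rowSums(free)
  keep <- promol > floor
  w <- free[keep, , drop = FALSE] / promol[keep]
  colSums(w * gridValues(density)[keep]) * voxelVolume(density)
}

#' Per-atom multicenter quadrature size
#'
#' Utility mirroring atom-centered (radial x angular) quadrature bookkeeping:
#' the number of integration points assigned per atom, 32,550 for the common
#' 75 x 434 combination. The molecular total scales linearly with the atom
#' count at constant per-atom density.
#'
#' @param nRadial number of radial shells (default 75).
#' @param nAngular angular (Lebedev) points per shell (default 434).
#' @return integer points per atom.
#' @examples
#' beckeGridPointsPerAtom()   # 32550
#' @export
beckeGridPointsPerAtom <- function(nRadial = 75L, nAngular = 434L) {
  as.integer(nRadial) * as.integer(nAngular)
}

#' One-particle-picture compliance from Hirshfeld populations
#'
#' Squared Pearson correlation between the per-atom populations of the
#' ionization density difference `Delta rho = rho_N - rho_(N-1)` and of the
#' squared HOMO. A tuning result is considered physically meaningful when
#' `R^2 > 0.90`. The correlation is undefined when either vector is constant;
#' that case is an error.
#'
#' @param popDeltaRho,popHomoSq per-atom population vectors (equal length,
#'   >= 2 entries).
#' @param threshold compliance threshold on R^2 (default 0.90).
#' @return a [HirshfeldReport-class].
#' @examples
#' oneParticleR2(c(0.1, 0.5, 0.4), c(0.12, 0.48, 0.40))
#' @export
oneParticleR2 <- function(popDeltaRho, popHomoSq, threshold = 0.90) {
  stopifnot(length(popDeltaRho) == length(popHomoSq),
            length(popDeltaRho) >= 2L,
            all(is.finite(popDeltaRho)), all(is.finite(popHomoSq)))
  if (stats::sd(popDeltaRho) == 0 || stats::sd(popHomoSq) == 0)
    stop("Pearson correlation undefined: constant population vector")
  r2 <- stats::cor(popDeltaRho, popHomoSq)^2
  new("HirshfeldReport", popDeltaRho = as.numeric(popDeltaRho),
      popHomoSq = as.numeric(popHomoSq), r2 = r2,
      compliant = r2 > threshold)
}
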