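#' @include AllClasses.R solvents.R
NULL

#' Convolve an excitation set into an absorption spectrum
#'
#' Each state contributes a Gaussian centered at its excitation energy with
#' fixed full width at half maximum; by default the Gaussian *height* is
#' proportional to the oscillator strength (an area-proportional mode is
#' available behind `areaMode`). The energy grid spans all state energies
#' +/- 3 FWHM.
#'
#' @param states an [ExcitationSet-class].
#' @param fwhm Gaussian FWHM in eV (> 0; default 0.20).
#' @param gridStep energy grid step in eV (default 0.002, i.e. 100 points per
#'   FWHM, keeping peak positions stable to < 0.005 eV).
#' @param areaMode logical; if `TRUE`, Gaussian areas (not heights) are
#'   proportional to the oscillator strengths.
#' @return a [Spectrum-class]. All oscillator strengths zero gives a valid
#'   zero spectrum.
#' @examples
#' es <- ExcitationSet(3.1, 1.0)
#' sp <- convolveSpectrum(es)
#' sp@energy[which.max(sp@intensity)]   # 3.1
#' @export
convolveSpectrum <- function(states, fwhm = 0.20, gridStep = 0.002,
                             areaMode = FALSE) {
  stopifnot(methods::is(states, "ExcitationSet"), fwhm > 0, gridStep > 0)
  es <- energies(states)
  grid <- seq(min(es) - 3 * fwhm, max(es) + 3 * fwhm, by = gridStep)
  if (grid[length(grid)] < max(es) + 3 * fwhm)
    grid <- c(grid, grid[length(grid)] + gridStep)
  f <- oscillatorStrengths(states)
  if (areaMode) f <- f / (fwhm / 2 * sqrt(pi / log(2)))  # unit-height -> unit-area
  intensity <- rowSums(vapply(seq_along(es), function(i) {
    f[i] * exp(-4 * log(2) * (grid - es[i])^2 / fwhm^2)
  }, numeric(length(grid))))
  new("Spectrum", energy = grid, intensity = intensity, states = states,
      fwhm = fwhm)
}

## Per-state contributions to the intensity at a single energy.
.stateContributions <- function(spec, e) {
  es <- energies(spec@states)
  f <- oscillatorStrengths(spec@states)
  f * exp(-4 * log(2) * (e - es)^2 / spec@fwhm^2)
}

#' Locate and assign the first visible absorption peak
#'
#' Finds the lowest-energy local maximum of the convolved spectrum whose
#' height is at least `visibilityFraction` of the global maximum, and
#' assigns it to the state contributing the most intensity there. Dark
#' states (zero oscillator strength) contribute nothing and can never
#' dominate; if S1 is dark the peak falls to S2 or higher.
#'
#' @param spec a [Spectrum-class], not identically zero.
#' @param visibilityFraction minimum height of a countable local maximum,
#'   as a fraction of the global maximum (default 0.01).
#' @return a list with `energy` (eV), `dominantState` (1-based index into
#'   the source excitation set), and `contributions` (per-state intensity at
#'   the peak; sums to the peak intensity).
#' @export
firstVisiblePeak <- function(spec, visibilityFraction = 0.01) {
  stopifnot(methods::is(spec, "Spectrum"))
  y <- spec@intensity
  if (all(y == 0)) stop("spectrum is identically zero")
  n <- length(y)
  # interior local maxima plus plateaus' leading edge; include ends
  isMax <- c(y[1L] > y[2L],
             y[2:(n - 1L)] >= y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n],
             y[n] >= y[n - 1L])
  cand <- which(isMax & y >= visibilityFraction * max(y))
  if (!length(cand)) stop("no qualifying absorption maximum found")
  i <- cand[1L]
  contrib <- .stateContributions(spec, spec@energy[i])
  list(energy = spec@energy[i], dominantState = which.max(contrib),
       contributions = contrib)
}

#' Mean absolute and mean signed benchmark errors
#'
#' `MAE = mean |pred - exp|` captures both random and systematic error;
#' `MSD = mean (pred - exp)` isolates the systematic part. Always
#' `MAE >= |MSD|`. An optional per-solvent breakdown is computed when the
#' records carry a `solvent` column.
#'
#' @param records data.frame with columns `predicted` and `experimental`
#'   (eV) and optionally `solvent`; see [generateSyntheticBenchmark()].
#' @return an [ErrorSummary-class].
#' @examples
#' maeMsd(data.frame(predicted = c(2.1, 2.9), experimental = c(2.0, 3.0)))
#' @export
maeMsd <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("predicted", "experimental") %in% names(records)))
  if (nrow(records) < 1L) stop("at least one record required")
  err <- records$predicted - records$experimental
  bySolvent <- if ("solvent" %in% names(records)) {
    do.call(rbind, lapply(split(err, records$solvent), function(e)
      data.frame(n = length(e), mae = mean(abs(e)), msd = mean(e))))
  } else data.frame()
  if (nrow(bySolvent)) bySolvent <- cbind(solvent = rownames(bySolvent),
                                          bySolvent, row.names = NULL)
  new("ErrorSummary", n = nrow(records), mae = mean(abs(err)),
      msd = mean(err), bySolvent = bySolvent)
}

#' Generate a synthetic benchmark table
#'
#' Emulates a spectral benchmark set: experimental first-peak energies drawn
#' uniformly over the 1.4-5.1 eV span typical of solution UV/Vis datasets,
#' and predictions offset by Gaussian noise with a chosen systematic bias.
#' Reproducible under a fixed seed; the caller's RNG state is left untouched.
#'
#' @param n number of records.
#' @param bias systematic prediction offset (eV).
#' @param sd random error standard deviation (eV, >= 0).
#' @param seed integer seed.
#' @param solvents character vector of solvent names cycled over the records.
#' @return data.frame with columns `id`, `solvent`, `experimental`,
#'   `predicted` (eV).
#' @examples
#' b <- generateSyntheticBenchmark(4, bias = 0.56, sd = 0, seed = 1)
#' maeMsd(b)   # MAE = MSD = 0.56 exactly
#' @export
generateSyntheticBenchmark <- function(n, bias = 0, sd = 0.3, seed = 1L,
                                       solvents = solventTable()$name) {
  stopifnot(n >= 1L, sd >= 0)
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(as.integer(seed))
  expPeak <- stats::runif(n, 1.4, 5.1)
  data.frame(id = sprintf("S%04d", seq_len(n)),
             solvent = rep_len(solvents, n),
             experimental = expPeak,
             predicted = expPeak + stats::rnorm(n, mean = bias, sd = sd))
}

#' Convert between wavelength (nm) and photon energy (eV)
#'
#' `E[eV] = 1239.842 / lambda[nm]`; the transform is its own inverse.
#'
#' @param value positive wavelength(s) in nm or energy(ies) in eV.
#' @param from `"nm"` (convert to eV) or `"eV"` (convert to nm).
#' @return converted value(s).
#' @examples
#' wavelengthEnergy(300, "nm")   # 4.13 eV
#' @export
wavelengthEnergy <- function(value, from = c("nm", "eV")) {
  from <- match.arg(from)
  if (any(value <= 0)) stop("value must be positive")
  NM_EV / value
}

#' Read a benchmark CSV
#'
#' Schema: `id, solvent, exp_peak, exp_unit` with `exp_unit` either `eV` or
#' `nm` (nm entries are converted). Extra columns (e.g. `smiles`) pass
#' through untouched.
#'
#' @param path CSV path.
#' @return data.frame with an `experimental` column in eV.
#' @export
readBenchmarkCSV <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "solvent", "exp_peak", "exp_unit") %in% names(df)))
  ok <- df$exp_unit %in% c("eV", "nm")
  if (!all(ok)) stop("exp_unit must be 'eV' or 'nm'")
  df$experimental <- ifelse(df$exp_unit == "nm",
                            wavelengthEnergy(df$exp_peak, "nm"), df$exp_peak)
  df
}
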