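test_that("single-state convolution is a unit Gaussian with 0.20 eV FWHM", {
  sp <- convolveSpectrum(ExcitationSet(3.0, 1.0), fwhm = 0.20)
  imax <- which.max(sp@intensity)
  expect_equal(sp@energy[imax], 3.0, tolerance = 1e-9)
  expect_equal(max(sp@intensity), 1.0, tolerance = 1e-12)
  # half maximum at E0 +/- fwhm/2 to grid precision
  atHalf <- sp@intensity[abs(sp@energy - 3.10) < 1e-9]
  expect_equal(atHalf, 0.5, tolerance = 1e-9)
  atHalfLo <- sp@intensity[abs(sp@energy - 2.90) < 1e-9]
  expect_equal(atHalfLo, 0.5, tolerance = 1e-9)
  # grid spans +/- 3 FWHM
  expect_lte(min(sp@energy), 3.0 - 3 * 0.2)
  expect_gte(max(sp@energy), 3.0 + 3 * 0.2)
})

test_that("convolution is linear and superposes far-apart states", {
  es <- ExcitationSet(c(2.0, 4.0), c(0.6, 0.6))
  sp <- convolveSpectrum(es)
  locmax <- sp@energy[c(which.max(sp@intensity * (sp@energy < 3)),
                        which.max(sp@intensity * (sp@energy > 3)))]
  expect_equal(locmax, c(2.0, 4.0), tolerance = 1e-9)
  # doubling all oscillator strengths doubles the intensity everywhere
  sp2 <- convolveSpectrum(ExcitationSet(c(2.0, 4.0), c(1.2, 1.2)))
  expect_equal(sp2@intensity, 2 * sp@intensity)
  # all-dark set gives a valid zero spectrum
  dark <- convolveSpectrum(ExcitationSet(c(2, 3), c(0, 0)))
  expect_true(all(dark@intensity == 0))
})

test_that("a dark S1 never claims the first visible peak", {
  es <- ExcitationSet(c(2.1, 2.8), c(0, 0.7))
  peak <- firstVisiblePeak(convolveSpectrum(es))
  expect_equal(peak$energy, 2.8, tolerance = 1e-6)
  expect_identical(peak$dominantState, 2L)
  expect_identical(unname(peak$contributions[1]), 0)
  expect_error(firstVisiblePeak(convolveSpectrum(ExcitationSet(c(2, 3),
                                                               c(0, 0)))),
               "identically zero")
})

test_that("overlapping states resolve by a dense-grid oracle", {
  # two states 0.05 eV apart, f = (1.0, 0.2): one merged peak near state 1
  e1 <- 3.00; e2 <- 3.05; f1 <- 1.0; f2 <- 0.2; fwhm <- 0.20
  dense <- seq(2.5, 3.6, by = 1e-5)
  tot <- f1 * exp(-4 * log(2) * (dense - e1)^2 / fwhm^2) +
    f2 * exp(-4 * log(2) * (dense - e2)^2 / fwhm^2)
  oracleE <- dense[which.max(tot)]
  peak <- firstVisiblePeak(convolveSpectrum(ExcitationSet(c(e1, e2),
                                                          c(f1, f2))))
  expect_identical(peak$dominantState, 1L)
  expect_equal(peak$energy, oracleE, tolerance = 2e-3)
  expect_true(peak$energy > e1 && peak$energy < e2)
  expect_lt(peak$energy - e1, e2 - peak$energy)  # nearer the stronger state
  # contributions at the peak sum to the intensity there
  expect_equal(sum(peak$contributions),
               f1 * exp(-4 * log(2) * (peak$energy - e1)^2 / fwhm^2) +
                 f2 * exp(-4 * log(2) * (peak$energy - e2)^2 / fwhm^2))
})

test_that("peak position and assignment are invariant under f rescaling", {
  es <- ExcitationSet(c(2.2, 2.9, 3.4), c(0.3, 0.8, 0.1))
  esScaled <- ExcitationSet(c(2.2, 2.9, 3.4), 7.5 * c(0.3, 0.8, 0.1))
  p1 <- firstVisiblePeak(convolveSpectrum(es))
  p2 <- firstVisiblePeak(convolveSpectrum(esScaled))
  expect_identical(p1$energy, p2$energy)
  expect_identical(p1$dominantState, p2$dominantState)
})

test_that("MAE/MSD match hand arithmetic and satisfy the triangle bound", {
  r <- function(err) data.frame(predicted = 2 + err, experimental = 2)
  s <- maeMsd(r(c(0.1, -0.1)))
  expect_equal(s@mae, 0.1); expect_equal(s@msd, 0)
  s1 <- maeMsd(r(0.3))
  expect_equal(s1@mae, 0.3); expect_equal(s1@msd, 0.3)
  s2 <- maeMsd(r(c(0.2, -0.4, 0.5)))
  expect_equal(s2@mae, 1.1 / 3); expect_equal(s2@msd, 0.1)
  expect_error(maeMsd(data.frame(predicted = numeric(),
                                 experimental = numeric())), "at least one")
  # property: MAE >= |MSD| on random record sets
  set.seed(9)
  for (i in 1:10) {
    s3 <- maeMsd(r(rnorm(50, sd = runif(1, 0.01, 1))))
    expect_gte(s3@mae, abs(s3@msd))
  }
})

test_that("per-solvent breakdown aggregates errors within groups", {
  rec <- data.frame(predicted = c(2.2, 2.4, 3.4), experimental = c(2, 2, 3),
                    solvent = c("DCM", "DCM", "DMSO"))
  s <- maeMsd(rec)
  expect_identical(nrow(s@bySolvent), 2L)
  dcm <- s@bySolvent[s@bySolvent$solvent == "DCM", ]
  expect_equal(dcm$mae, 0.3); expect_equal(dcm$msd, 0.3)
})

test_that("solvent lookup returns printed dielectric pairs", {
  dcm <- solventLookup("DCM")
  expect_equal(dcm@eps, 8.93); expect_equal(dcm@epsInf, 2.03)
  dmf <- solventLookup("dmf")  # case-insensitive
  expect_equal(dmf@eps, 36.7); expect_equal(dmf@epsInf, 2.04)
  expect_equal(solventLookup("methanol")@epsInf, 1.77)
  expect_equal(solventLookup("toluene")@epsInf, 2.24)
  expect_error(solventLookup("water"), "known solvents")
  # all nine entries satisfy the dielectric ordering invariant
  tab <- solventTable()
  expect_identical(nrow(tab), 9L)
  expect_true(all(tab$epsInf >= 1 & tab$epsInf <= tab$eps))
  # overrides pass through
  expect_equal(solventLookup("DCM", eps = 9.1)@eps, 9.1)
})

test_that("synthetic benchmarks are reproducible and recover known errors", {
  a <- generateSyntheticBenchmark(50, bias = 0.2, sd = 0.1, seed = 7)
  b <- generateSyntheticBenchmark(50, bias = 0.2, sd = 0.1, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$experimental >= 1.4 & a$experimental <= 5.1))
  # degenerate noise: MAE = MSD = bias exactly
  s <- maeMsd(generateSyntheticBenchmark(25, bias = 0.56, sd = 0, seed = 1))
  expect_equal(s@mae, 0.56); expect_equal(s@msd, 0.56)
  # unbiased noise: MSD -> 0, MAE -> half-normal mean sd * sqrt(2/pi)
  big <- generateSyntheticBenchmark(1e4, bias = 0, sd = 0.3, seed = 123)
  sm <- maeMsd(big)
  seMsd <- 0.3 / sqrt(1e4)
  seMae <- 0.3 * sqrt(1 - 2 / pi) / sqrt(1e4)
  expect_lt(abs(sm@msd), 3 * seMsd)
  expect_lt(abs(sm@mae - 0.3 * sqrt(2 / pi)), 3 * seMae)
})

test_that("wavelength-energy conversion is exact and involutive", {
  expect_equal(wavelengthEnergy(300, "nm"), 4.1328, tolerance = 1e-4)
  expect_equal(wavelengthEnergy(1239.842, "nm"), 1.0)
  x <- c(250, 420, 800)
  expect_equal(wavelengthEnergy(wavelengthEnergy(x, "nm"), "eV"), x,
               tolerance = 1e-12)
  expect_error(wavelengthEnergy(-1), "positive")
})
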