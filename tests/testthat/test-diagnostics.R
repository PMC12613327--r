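test_that("fractional-charge residual has exact endpoints and midpoint form", {
  set.seed(3)
  for (i in 1:20) {
    dE <- runif(1, -2, 8)
    lumo <- runif(1, -6, 4)
    homo <- runif(1, -8, 2)
    crv <- fractionalChargeCurve(dE, lumo, homo, nPoints = 201)
    expect_identical(crv@F[1], 0)
    expect_identical(crv@F[201], 0)
    expect_identical(crv@E[1], 0)
    expect_equal(crv@E[201], dE)
    # closed form F(1/2) = (eps_LUMO(N) - eps_HOMO(N+1)) / 8
    expect_equal(crv@F[101], (lumo - homo) / 8)
  }
  # worked case: eps_LUMO = 1.0, eps_HOMO = -3.0 -> F(1/2) = 0.5 eV
  crv <- fractionalChargeCurve(1.0, 1.0, -3.0, nPoints = 11)
  expect_equal(crv@F[6], 0.5)
  # symmetric case eps_LUMO - dE = dE - eps_HOMO = c -> F(1/2) = c/4
  crv2 <- fractionalChargeCurve(2.0, 2.0 + 0.8, 2.0 - 0.8, nPoints = 21)
  expect_equal(crv2@F[11], 0.8 / 4)
})

test_that("residual vanishes identically iff both edges are Koopmans-compliant", {
  crv <- fractionalChargeCurve(1.7, 1.7, 1.7, nPoints = 101)
  expect_true(all(crv@F == 0))
  crv2 <- fractionalChargeCurve(1.7, 1.7 + 1e-3, 1.7, nPoints = 101)
  expect_gt(max(abs(crv2@F)), 0)
})

test_that("Hirshfeld weights form a partition of unity on the promolecule", {
  fix <- twoGaussianGrid(step = 0.25)
  # population sum equals the plain grid integral of the density
  pops <- hirshfeldPopulations(fix$grid, c("A", "B"), fix$positions,
                               profiles = fix$profiles)
  direct <- sum(gridValues(fix$grid)) * voxelVolume(fix$grid)
  expect_equal(sum(pops), direct, tolerance = 1e-10)
  # mirror-symmetric density about the midplane -> equal populations
  expect_equal(pops[1], pops[2], tolerance = 1e-9)
  # ... and conservation holds for an arbitrary field supported on the
  # promolecule (weights are only defined where the promolecule lives)
  set.seed(5)
  rnd <- DensityGrid(fix$grid@origin, fix$grid@step, fix$grid@counts,
                     gridValues(fix$grid) *
                       abs(rnorm(length(gridValues(fix$grid)))))
  popsRnd <- hirshfeldPopulations(rnd, c("A", "B"), fix$positions,
                                  profiles = fix$profiles)
  expect_equal(sum(popsRnd), sum(gridValues(rnd)) * voxelVolume(rnd),
               tolerance = 1e-8)
})

test_that("single-atom partition returns the full grid integral", {
  fix <- twoGaussianGrid(step = 0.25, nel = c(2, 0), sigma = c(0.7, 0.7))
  oneAtom <- hirshfeldPopulations(fix$grid, "A",
                                  fix$positions[1, , drop = FALSE],
                                  profiles = fix$profiles["A"])
  expect_equal(oneAtom,
               sum(gridValues(fix$grid)) * voxelVolume(fix$grid),
               tolerance = 1e-10)
  # Gaussian of 2 electrons integrates to ~2 on this box
  expect_equal(oneAtom, 2, tolerance = 1e-3)
})

test_that("populations converge under grid refinement", {
  coarse <- twoGaussianGrid(step = 0.25, nel = c(1.3, 0.7))
  fine <- twoGaussianGrid(step = 0.125, nel = c(1.3, 0.7))
  pc <- hirshfeldPopulations(coarse$grid, c("A", "B"), coarse$positions,
                             profiles = coarse$profiles)
  pf <- hirshfeldPopulations(fine$grid, c("A", "B"), fine$positions,
                             profiles = fine$profiles)
  expect_lt(max(abs(pc - pf)), 1e-3)
})

test_that("packaged synthetic free-atom profiles integrate to Z", {
  profs <- freeAtomProfiles(c("H", "C", "O"))
  for (el in c("H", "C", "O")) {
    f <- profs[[el]]
    z <- stats::integrate(function(r) f(r) * 4 * pi * r^2, 0, 11,
                          subdivisions = 500L)$value
    expect_equal(z, c(H = 1, C = 6, O = 8)[[el]], tolerance = 1e-2)
  }
  expect_error(freeAtomProfiles("Xx"), "Xx")
  expect_error(hirshfeldPopulations(twoGaussianGrid(step = 1)$grid,
                                    c("A", "Qq"),
                                    matrix(0, 2, 3),
                                    profiles = list(A = function(r) r)),
               "Qq")
})

test_that("per-atom quadrature arithmetic composes radial and angular counts", {
  expect_identical(beckeGridPointsPerAtom(75L, 434L), 32550L)
  expect_identical(beckeGridPointsPerAtom(), 32550L)
  expect_identical(beckeGridPointsPerAtom(10L, 50L), 500L)
})

test_that("one-particle R^2 agrees with the textbook correlation formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 10)
  rep <- oneParticleR2(x, y)
  expect_equal(rep@r2, pearsonByHand(x, y)^2)
  expect_false(rep@compliant)  # 0.7535 < 0.90
  # identical vectors and affine images are perfectly compliant
  expect_equal(oneParticleR2(x, x)@r2, 1)
  expect_equal(oneParticleR2(x, -2.5 * x + 3)@r2, 1)
  expect_true(oneParticleR2(x, -2.5 * x + 3)@compliant)
  expect_error(oneParticleR2(c(1, 1), c(1, 1)), "constant")
  expect_error(oneParticleR2(c(1, 1), c(1, 2)), "constant")
})
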