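test_that("molecule validity enforces atom count, finiteness and spin parity", {
  expect_error(Molecule(character(), matrix(numeric(), ncol = 3)),
               "at least one atom")
  expect_error(Molecule("C", matrix(c(0, NA, 0), 1)), "finite")
  # CH radical: 7 electrons cannot be a singlet
  expect_error(Molecule(c("C", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0)),
                        multiplicity = 1L), "inconsistent with multiplicity")
  # default multiplicity resolves parity automatically
  expect_identical(Molecule(c("C", "H"),
                            rbind(c(0, 0, 0), c(1.1, 0, 0)))@multiplicity, 2L)
  expect_identical(setCharge(diatomicFixture(), -1L)@multiplicity, 2L)
})

test_that("mock frontier quantities follow the affine model", {
  eng <- mockEngine()
  # gas, N state, gamma = 0.15: -eps_HOMO = 6.0 + 10.16 * 0.15
  q <- mockQuantities(eng, "N", 0.15, gasMode())
  expect_equal(q[["negHomo"]], 6.0 + 10.16 * 0.15)
  expect_equal(q[["ip"]], 7.33 + 1.31 * 0.15)
  # gas intercepts untouched at gamma = 0
  q0 <- mockQuantities(eng, "N+1", 0, gasMode())
  expect_equal(unname(q0), c(-0.50, 0.85))
})

test_that("mock dielectric scaling reproduces reference shifts and limits", {
  eng <- mockEngine()
  gasIp <- mockQuantities(eng, "N", 0, gasMode())[["ip"]]
  # equilibrium at the reference solvent: shift is exactly the printed value
  eqIp <- mockQuantities(eng, "N", 0, equilibriumMode(8.93))[["ip"]]
  expect_equal(eqIp - gasIp, -1.19)
  # nonequilibrium at epsInf = 2.03 rescales by the Pekar-factor ratio
  neqIp <- mockQuantities(eng, "N", 0, nonequilibriumMode(2.03))[["ip"]]
  expect_equal(neqIp - gasIp, -1.19 * (1.03 / 2.03) / (7.93 / 8.93))
  # shifts vanish as eps -> 1
  expect_equal(mockQuantities(eng, "N", 0, equilibriumMode(1 + 1e-9))[["ip"]],
               gasIp, tolerance = 1e-6)
})

test_that("mock -eps_HOMO rises with gamma and IP(N+1) falls", {
  eng <- mockEngine()
  grid <- seq(0, 0.6, by = 0.05)
  for (st in c("N", "N+1")) {
    nh <- vapply(grid, function(g)
      mockQuantities(eng, st, g, gasMode())[["negHomo"]], numeric(1))
    expect_true(all(diff(nh) > 0))
  }
  ip1 <- vapply(grid, function(g)
    mockQuantities(eng, "N+1", g, gasMode())[["ip"]], numeric(1))
  expect_true(all(diff(ip1) < 0))
})

test_that("ground-state runs are deterministic and mode-consistent", {
  eng <- mockEngine()
  mol <- ethyleneFixture()
  p <- RSHParams(gamma = 0.12)
  a <- runGroundState(eng, mol, p, equilibriumMode(8.93))
  b <- runGroundState(eng, mol, p, equilibriumMode(8.93))
  expect_identical(a, b)  # bitwise determinism contract
  gas <- runGroundState(eng, mol, p, gasMode())
  expect_length(gas@polCharges, 0)
  expect_gt(length(a@polCharges), 0)
  expect_lte(a@epsHomo, a@epsLumo)
  expect_error(runGroundState(eng, Molecule("U", matrix(0, 1, 3),
                                            multiplicity = 1L),
                              p, gasMode()),
               "unsupported element")
})

test_that("mock excited states pass the fixed table through", {
  eng <- mockEngine()
  mol <- diatomicFixture()
  p <- RSHParams()
  es <- runExcitedStates(eng, mol, p, gasMode(), nStates = 10L)
  expect_identical(length(energies(es)), 10L)
  expect_true(all(diff(energies(es)) >= 0))
  one <- runExcitedStates(eng, mol, p, gasMode(), nStates = 1L)
  expect_identical(length(energies(one)), 1L)
  expect_identical(energies(one), energies(es)[1])
  expect_error(runExcitedStates(eng, mol, p, gasMode(), nStates = 50L),
               "50 requested")
})

test_that("engine registry resolves mock and rejects unknown names", {
  expect_s4_class(getEngine("mock"), "MockEngine")
  expect_error(getEngine("orca"), "unknown engine")
  registerEngine("null-engine", function(...) mockEngine(...))
  expect_s4_class(getEngine("null-engine"), "MockEngine")
})

test_that("XYZ files round-trip geometry", {
  mol <- ethyleneFixture()
  path <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(mol, path, comment = "ethylene")
  back <- readXYZ(path)
  expect_identical(elements(back), elements(mol))
  expect_equal(coords(back), coords(mol), tolerance = 1e-7)
  expect_identical(netCharge(readXYZ(path, charge = -1L)), -1L)
})

test_that("cube files round-trip grids with Bohr/Angstrom conversion", {
  fix <- twoGaussianGrid(step = 0.5, half = 2)
  path <- withr::local_tempfile(fileext = ".cube")
  atoms <- data.frame(Z = c(1L, 1L), x = fix$positions[, 1],
                      y = fix$positions[, 2], z = fix$positions[, 3])
  writeCube(fix$grid, path, atoms = atoms)
  back <- readCube(path)
  expect_equal(back$grid@origin, fix$grid@origin, tolerance = 1e-5)
  expect_equal(back$grid@step, fix$grid@step, tolerance = 1e-5)
  expect_identical(back$grid@counts, fix$grid@counts)
  expect_equal(gridValues(back$grid), gridValues(fix$grid),
               tolerance = 1e-4)
  expect_equal(back$atoms$z, fix$positions[, 3], tolerance = 1e-5)
})
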