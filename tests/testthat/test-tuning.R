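test_that("J^2 loss matches direct arithmetic for all variants", {
  q0 <- IonizationQuantities(homoN = -7, ipN = 7, homoN1 = -1, ipN1 = 1)
  expect_identical(j2Loss(q0), 0)
  q <- IonizationQuantities(homoN = -7, ipN = 6.8, homoN1 = -1, ipN1 = 1.1,
                            lumoN = -1.0, eaN = 1.3)
  expect_equal(j2Loss(q), 0.04 + 0.01)
  expect_equal(j2Loss(q, "ip_only"), 0.04)
  expect_equal(j2Loss(q, "ea_form"), 0.04 + (-1.0 + 1.3)^2)
  expect_error(j2Loss(IonizationQuantities(-7, 7, -1, 1), "ea_form"),
               "requires lumoN")
})

test_that("scheme-resolved quantities obey mode rules and energy differences", {
  eng <- mockEngine()
  mol <- diatomicFixture()
  dcm <- solventLookup("DCM")
  p <- RSHParams(gamma = 0.15)
  # GP ignores the solvent entirely
  gp1 <- ionizationQuantities(eng, mol, p, "GP", dcm)
  gp2 <- ionizationQuantities(eng, mol, p, "GP", solventLookup("DMSO"))
  expect_equal(c(gp1@homoN, gp1@ipN, gp1@homoN1, gp1@ipN1),
               c(gp2@homoN, gp2@ipN, gp2@homoN1, gp2@ipN1))
  # gas crossings near gamma = 0.15 by construction: residuals small
  expect_lt(abs(gp1@homoN + gp1@ipN), 0.01)
  expect_lt(abs(gp1@homoN1 + gp1@ipN1), 0.01)
  # IP/EA sign relation: EA(N) = -IP(N+1)
  expect_equal(gp1@eaN, -gp1@ipN1)
  # tuning requires a neutral start and a solvent for solvated schemes
  expect_error(ionizationQuantities(eng, setCharge(mol, 1L), p, "GP"),
               "neutral")
  expect_error(ionizationQuantities(eng, mol, p, "SV"), "requires a solvent")
})

test_that("SV degenerates to PV exactly when eps equals epsInf", {
  eng <- mockEngine()
  mol <- ethyleneFixture()
  sv <- SolventSpec("hypothetical", eps = 2.03, epsInf = 2.03)
  for (g in c(0, 0.1, 0.3)) {
    p <- RSHParams(gamma = g)
    a <- ionizationQuantities(eng, mol, p, "SV", sv)
    b <- ionizationQuantities(eng, mol, p, "PV", sv)
    expect_identical(c(a@homoN, a@ipN, a@homoN1, a@ipN1, a@lumoN, a@eaN),
                     c(b@homoN, b@ipN, b@homoN1, b@ipN1, b@lumoN, b@eaN))
  }
})

test_that("two-round search refines a convex loss to the right grid point", {
  # analytic minimum at 0.137: nearest fine-grid point is 0.14
  res <- gammaGridSearch(function(g) 3 * (g - 0.137)^2 + 0.01)
  expect_identical(gammaOpt(res), 0.14)
  expect_equal(j2Opt(res), 3 * (0.14 - 0.137)^2 + 0.01)
  expect_identical(res@round1@gamma, seq(0, 0.60, by = 0.15))
  # constant loss: the tie rule selects the smallest gamma
  expect_identical(gammaOpt(gammaGridSearch(function(g) 1)), 0)
  # gammaOpt always lies on the round-2 grid
  expect_true(any(abs(res@round2@gamma - gammaOpt(res)) < 1e-12))
})

test_that("search reports completed points when the loss fails mid-scan", {
  flaky <- function(g) if (g > 0.4) stop("engine diverged") else (g - 0.1)^2
  expect_error(gammaGridSearch(flaky), "completed points")
})

test_that("two-round search matches an exhaustive fine-grid brute force", {
  # randomized unimodal landscapes; oracle = argmin over the full 0.02 grid
  set.seed(42)
  brute <- seq(0, 0.60, by = 0.02)
  for (i in 1:25) {
    m <- runif(1, 0, 0.6)
    a <- runif(1, 0.5, 30)
    c0 <- runif(1, 0, 0.1)
    f <- if (i %% 2 == 0) function(g) a * (g - m)^2 + c0
         else function(g) a * abs(g - m) + c0
    res <- gammaGridSearch(f)
    bf <- brute[which.min(vapply(brute, f, numeric(1)))]
    expect_lte(abs(gammaOpt(res) - bf), 0.02 + 1e-9)
    expect_identical(j2Opt(res), f(gammaOpt(res)))
  }
})

test_that("mock-model scheme ordering reproduces solvated-optimum compression", {
  eng <- mockEngine()
  mol <- diatomicFixture()
  dcm <- solventLookup("DCM")
  gGP <- gammaOpt(twoRoundSearch(eng, mol, "GP", dcm))
  gPV <- gammaOpt(twoRoundSearch(eng, mol, "PV", dcm))
  gSV <- gammaOpt(twoRoundSearch(eng, mol, "SV", dcm))
  expect_lt(gPV, gSV)
  expect_lt(gSV, gGP)
  expect_lte(gPV, 0.02)
  expect_true(gSV >= 0.04 && gSV <= 0.10)
  expect_true(gGP >= 0.12 && gGP <= 0.18)
})

test_that("loss variants move the optimum by at most one fine-grid step", {
  eng <- mockEngine()
  mol <- diatomicFixture()
  dcm <- solventLookup("DCM")
  for (s in c("GP", "PV", "SV")) {
    gFull <- gammaOpt(twoRoundSearch(eng, mol, s, dcm, variant = "full"))
    gIp <- gammaOpt(twoRoundSearch(eng, mol, s, dcm, variant = "ip_only"))
    expect_lte(abs(gFull - gIp), 0.02 + 1e-9)
  }
})

test_that("round-2 scan reuses cached round-1 evaluations", {
  calls <- new.env(); calls$n <- 0L
  f <- function(g) { calls$n <- calls$n + 1L; (g - 0.15)^2 }
  res <- gammaGridSearch(f)
  # 5 coarse + 16 fine points, of which 0.00, 0.15, 0.30 were already done
  overlap <- length(intersect(round(res@round1@gamma, 10),
                              round(res@round2@gamma, 10)))
  expect_identical(calls$n, length(res@round1@gamma) +
                     length(res@round2@gamma) - overlap)
  expect_gt(overlap, 0L)
})

test_that("SRSH beta rule enforces alpha + beta = 1/eps", {
  p <- srshBeta(0.2, 2.0)
  expect_equal(p@beta, 0.3)
  expect_equal(p@alpha + p@beta, 1 / 2.0)
  expect_equal(srshBeta(0.25, 1)@beta, 0.75)  # gas limit alpha + beta = 1
  expect_error(srshBeta(0.2, 8.93), "negative beta")
})
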