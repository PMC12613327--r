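# Shared fixtures: small molecules, a two-Gaussian density grid, and free-atom
# Gaussian profiles with known analytic integrals.

ethyleneFixture <- function() {
  Molecule(c("C", "C", "H", "H", "H", "H"),
           rbind(c(-0.667, 0, 0), c(0.667, 0, 0),
                 c(-1.23, 0, 0.92), c(-1.23, 0, -0.92),
                 c(1.23, 0, 0.92), c(1.23, 0, -0.92)))
}

diatomicFixture <- function() {
  Molecule(c("C", "C"), rbind(c(-0.67, 0, 0), c(0.67, 0, 0)))
}

# Normalized isotropic Gaussian density: integral nel, width sigma (Angstrom).
gaussianProfile <- function(nel, sigma) {
  force(nel); force(sigma)
  function(r) nel * exp(-r^2 / sigma^2) / (pi^1.5 * sigma^3)
}

# Rectangular grid holding the sum of two atomic Gaussians at +/- zSep/2 on z.
twoGaussianGrid <- function(step = 0.2, half = 4, zSep = 1.6,
                            nel = c(1, 1), sigma = c(0.7, 0.7)) {
  ax <- seq(-half, half, by = step)
  counts <- rep(length(ax), 3L)
  pos <- rbind(c(0, 0, -zSep / 2), c(0, 0, zSep / 2))
  g <- expand.grid(z = ax, y = ax, x = ax)  # z fastest, matching gridPoints()
  r1 <- sqrt(g$x^2 + g$y^2 + (g$z - pos[1, 3])^2)
  r2 <- sqrt(g$x^2 + g$y^2 + (g$z - pos[2, 3])^2)
  vals <- gaussianProfile(nel[1], sigma[1])(r1) +
    gaussianProfile(nel[2], sigma[2])(r2)
  list(grid = DensityGrid(rep(-half, 3), rep(step, 3), counts, vals),
       positions = pos,
       profiles = list(A = gaussianProfile(nel[1], sigma[1]),
                       B = gaussianProfile(nel[2], sigma[2])))
}

# Textbook Pearson correlation, independent of stats::cor.
pearsonByHand <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
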