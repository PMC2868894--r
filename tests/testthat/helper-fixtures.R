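# shared fixtures: one standard band, grid and twisted pair, plus a
# random-assembly generator for property tests

std_band <- function(eps_max = 1e4, fwhm = 2000, center = 350,
                     shape = "gaussian") {
  transition_band(center, eps_max, fwhm, shape)
}

std_grid <- function(band = std_band(), step = 20, margin = 4) {
  grid_for_bands(band, step = step, margin = margin)
}

# random chiral assembly of n oscillators sharing one band; positions are
# rejected-resampled until pairwise distances exceed 1 Angstrom
random_assembly <- function(n = 3L, band = std_band()) {
  repeat {
    pos <- matrix(stats::runif(3 * n, -8, 8), n, 3)
    if (n == 1L || min(stats::dist(pos)) > 1) break
  }
  ori <- matrix(stats::rnorm(3 * n), n, 3)
  ori <- ori / sqrt(rowSums(ori^2))
  oscillator_assembly(list(band), pos, ori, rep(1L, n), name = "random")
}

expect_near <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
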