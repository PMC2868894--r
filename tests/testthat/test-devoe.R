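# geometry, coupling, interaction matrix and the all-order engine

test_that("pair_geometry returns the separation vector and distance", {
  b <- std_band()
  asm <- oscillator_assembly(list(b),
                             rbind(c(0, 0, 0), c(0, 0, 10)),
                             rbind(c(1, 0, 0), c(0, 1, 0)),
                             c(1L, 1L))
  pg <- pair_geometry(asm, 1, 2)
  expect_equal(pg$r_vec, c(0, 0, 10))
  expect_equal(pg$distance, 10)
  pg_rev <- pair_geometry(asm, 2, 1)
  expect_equal(pg_rev$r_vec, -pg$r_vec)
  # the inter-moiety distance of the dimeric molecule's stable conformer
  asm2 <- make_twisted_pair(30, 14.5)
  expect_equal(pair_geometry(asm2, 1, 2)$distance, 14.5)
})

test_that("interaction_energy follows the point-dipole formula", {
  # kappa chosen as Angstrom^3 in cm^3 so distances read in Angstrom units
  kA <- 1e-24
  # parallel dipoles perpendicular to R: angular factor 1
  expect_equal(interaction_energy(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1), kA), 1)
  # collinear head-to-tail: 1 - 3 = -2
  expect_equal(interaction_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1), kA), -2)
  # symmetry and 1/R^3
  g1 <- interaction_energy(c(1, 0, 0), c(0.6, 0.8, 0), c(1, 2, 2), kA)
  g2 <- interaction_energy(c(0.6, 0.8, 0), c(1, 0, 0), c(-1, -2, -2), kA)
  expect_equal(g1, g2)
  expect_equal(interaction_energy(c(1, 0, 0), c(1, 0, 0), c(0, 0, 2), kA),
               1 / 8)
  expect_error(interaction_energy(c(1, 0, 0), c(1, 0, 0), c(0, 0, 0)),
               "zero separation")
})

test_that("interaction matrix: single oscillator, decoupled limit, 2x2 closed form", {
  a <- complex(real = c(2e-23, -1e-23), imaginary = c(1e-23, 3e-24))
  # single oscillator
  B1 <- build_interaction_matrix(a[1L], matrix(0, 1, 1))
  expect_equal(B1[1, 1], 1 / a[1L])
  # G = 0: A = B^-1 is diagonal with alpha on the diagonal
  B <- build_interaction_matrix(a, matrix(0, 2, 2))
  A <- solve(B)
  expect_equal(diag(A), a)
  expect_equal(A[1, 2], 0 + 0i)
  # 2x2 closed-form inverse: A12 = -G a1 a2 / (1 - G^2 a1 a2)
  G <- matrix(c(0, 3e21, 3e21, 0), 2, 2)
  A <- solve(build_interaction_matrix(a, G))
  g <- G[1, 2]
  closed12 <- -g * a[1L] * a[2L] / (1 - g^2 * a[1L] * a[2L])
  closed11 <- a[1L] / (1 - g^2 * a[1L] * a[2L])
  expect_equal(A[1, 2], closed12, tolerance = 1e-14)
  expect_equal(A[1, 1], closed11, tolerance = 1e-14)
})

test_that("CD vanishes for a single oscillator and any coplanar pair", {
  b <- std_band()
  g <- std_grid(b, step = 40, margin = 3)
  one <- oscillator_assembly(list(b), rbind(c(0, 0, 0)),
                             rbind(c(1, 0, 0)), 1L)
  expect_equal(max(abs(devoe_cd(one, g)$value)), 0)
  # coplanar: dihedral 0 and dihedral 180
  expect_equal(max(abs(devoe_cd(make_twisted_pair(0, 10, b), g)$value)), 0)
  expect_equal(max(abs(devoe_cd(make_twisted_pair(180, 10, b), g)$value)), 0)
  # coplanar but not perpendicular to R: all three vectors in the xz plane
  cop <- oscillator_assembly(list(b),
                             rbind(c(0, 0, 0), c(3, 0, 8)),
                             rbind(c(1, 0, 0), c(0.6, 0, 0.8)),
                             c(1L, 1L))
  expect_equal(max(abs(devoe_cd(cop, g)$value)), 0)
})

test_that("mirror images flip CD exactly and preserve absorption (100 random geometries)", {
  b <- std_band()
  g <- std_grid(b, step = 40, margin = 3)
  polar <- list(transition_polarizability(b, g))
  set.seed(42)
  worst_cd <- 0
  worst_abs <- 0
  for (i in 1:100) {
    asm <- random_assembly(n = sample(2:4, 1), band = b)
    mir <- reflect_assembly(asm, normal = stats::rnorm(3))
    cd <- devoe_cd(asm, g, polarizabilities = polar)
    cdm <- devoe_cd(mir, g, polarizabilities = polar)
    ab <- devoe_abs(asm, g, polarizabilities = polar)
    abm <- devoe_abs(mir, g, polarizabilities = polar)
    scale_cd <- max(abs(cd$value), 1e-300)
    worst_cd <- max(worst_cd, max(abs(cd$value + cdm$value)) / scale_cd)
    worst_abs <- max(worst_abs, max(abs(ab$value - abm$value)) / max(ab$value))
  }
  expect_lt(worst_cd, 1e-9)
  expect_lt(worst_abs, 1e-9)
})

test_that("couplet is conservative: net rotational strength below 1% of one branch", {
  b <- std_band() # fwhm 2000 at 350 nm -- an ordinary broad band
  g <- std_grid(b, step = 20, margin = 4)
  cd <- devoe_cd(make_twisted_pair(30, 10, b), g)
  bal <- rotational_strength_balance(cd)
  expect_lt(bal$ratio, 0.01)
  # also for a random 3-oscillator assembly
  set.seed(7)
  cd3 <- devoe_cd(random_assembly(3, b), g)
  bal3 <- rotational_strength_balance(cd3)
  expect_lt(bal3$ratio, 0.01)
})

test_that("absorption reduces to the input band when uncoupled and conserves intensity", {
  b <- std_band()
  g <- std_grid(b, step = 20, margin = 4)
  one <- oscillator_assembly(list(b), rbind(c(0, 0, 0)),
                             rbind(c(1, 0, 0)), 1L)
  ab1 <- devoe_abs(one, g)
  eps <- band_absorption(b, g)
  expect_lt(sqrt(mean((rev(ab1$value) - eps)^2)) / max(eps), 0.01)
  # two coupled identical oscillators: integral doubles within 2%
  ab2 <- devoe_abs(make_twisted_pair(30, 10, b), g)
  nu <- as.numeric(g)
  i1 <- sum(rev(ab1$value)) * attr(g, "step")
  i2 <- sum(rev(ab2$value)) * attr(g, "step")
  expect_near(i2 / (2 * i1), 1, 0.02)
})

test_that("zero-intensity oscillators are inert and all-zero assemblies give zero spectra", {
  b0 <- transition_band(350, 0, 2000)
  b <- std_band()
  g <- std_grid(b, step = 40, margin = 3)
  dead <- oscillator_assembly(list(b0), rbind(c(0, 0, 0), c(0, 0, 10)),
                              rbind(c(1, 0, 0), c(0, 1, 0)), c(1L, 1L))
  expect_equal(max(abs(devoe_cd(dead, g)$value)), 0)
  expect_equal(max(abs(devoe_abs(dead, g)$value)), 0)
  # a dead oscillator added to a live pair changes nothing
  live <- make_twisted_pair(30, 10, b)
  mixed <- oscillator_assembly(list(b, b0),
                               rbind(live$positions, c(5, 5, 5)),
                               rbind(live$orientations, c(0, 0, 1)),
                               c(1L, 1L, 2L))
  expect_equal(devoe_cd(mixed, g)$value, devoe_cd(live, g)$value)
})
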