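# extrema, isodichroic points, elongation profiles, two-basis decomposition

test_that("find_extrema locates a single gaussian band at its center", {
  wl <- seq(300, 400, 0.5)
  s <- cd_spectrum(wl, 5 * exp(-(wl - 350)^2 / (2 * 8^2)))
  ext <- find_extrema(s)
  expect_equal(nrow(ext), 1L)
  expect_near(ext$wavelength_nm, 350, 0.5)
  expect_equal(ext$sign, 1)
  # flat zero spectrum: empty result
  flat <- cd_spectrum(wl, numeric(length(wl)))
  expect_equal(nrow(find_extrema(flat)), 0L)
  expect_error(find_extrema(s, smooth_window = 1000), "window")
})

test_that("find_extrema is equivariant under wavelength-axis reversal", {
  wl <- seq(220, 400, 1)
  y <- 3 * exp(-(wl - 250)^2 / 60) - 2 * exp(-(wl - 320)^2 / 200) +
    exp(-(wl - 370)^2 / 80)
  fwd <- find_extrema(cd_spectrum(wl, y))
  bwd <- find_extrema(cd_spectrum(rev(wl), rev(y)))
  expect_equal(fwd$wavelength_nm, bwd$wavelength_nm, tolerance = 1e-9)
  expect_equal(fwd$value, bwd$value, tolerance = 1e-9)
})

test_that("the seven-band generator's extrema are recovered within 2 nm", {
  centers <- c(377, 342, 305, 270, 252, 235, 222)
  asm <- make_multiband_molecule()
  cd <- devoe_cd(asm, grid_for_bands(asm$bands, step = 20))
  # restrict to the observed window (the far-UV anchor lies outside it)
  w <- cd$wavelength_nm >= 210 & cd$wavelength_nm <= 400
  ext <- find_extrema(cd_spectrum(cd$wavelength_nm[w], cd$value[w]))
  expect_equal(nrow(ext), 7L)
  for (cc in centers) {
    expect_near(min(abs(ext$wavelength_nm - cc)), 0, 2)
  }
  # the two intensity families keep their designed signs
  sign_at <- function(cc) sign(ext$value[which.min(abs(ext$wavelength_nm - cc))])
  expect_equal(vapply(centers, sign_at, 0), c(-1, -1, 1, -1, 1, 1, -1))
})

test_that("find_isodichroic recovers constructed crossings and rejects degenerate input", {
  res <- make_solvent_series("two_state", 9, spec = generator_spec(1, 0))
  iso <- find_isodichroic(res$series)
  expect_equal(length(iso), 2L)
  step <- diff(res$series$wavelengths)[1L]
  expect_near(iso[1L], res$crossings_nm[1L], step)
  expect_near(iso[2L], res$crossings_nm[2L], step)
  # all members agree at the crossings (the defining property)
  for (cx in res$crossings_nm) {
    k <- which.min(abs(res$series$wavelengths - cx))
    expect_lt(diff(range(res$series$values[k, ])),
              1e-6 * max(abs(res$series$values)))
  }
  # identical members: degenerate, empty with warning
  wl <- res$series$wavelengths
  same <- spectrum_series(wl, c(0, 0.5, 1),
                          matrix(rep(res$basis_a$value, 3), ncol = 3))
  expect_warning(iso_same <- find_isodichroic(same), "degenerate")
  expect_equal(length(iso_same), 0L)
  # three-basis series: no common crossing at default tolerance
  res3 <- make_solvent_series("three_state", 9, spec = generator_spec(1, 0))
  expect_equal(length(find_isodichroic(res3$series)), 0L)
  # preconditions
  expect_error(find_isodichroic(spectrum_series(wl, c(0, 1),
                                                res$series$values[, c(1, 9)])),
               "3 members")
  varying <- spectrum_series(wl, c(0, 0.5, 1), res$series$values[, c(1, 5, 9)],
                             concentration_constant = FALSE)
  expect_error(find_isodichroic(varying), "constant")
})

test_that("elongation_profile extracts member values in mixing order", {
  res <- make_solvent_series("two_state", 9, spec = generator_spec(1, 0))
  prof <- elongation_profile(res$series, 342)
  expect_equal(prof$mixing, res$series$mixing)
  k <- which.min(abs(res$series$wavelengths - 342))
  expect_equal(prof$value, unname(res$series$values[k, ]))
  expect_error(elongation_profile(res$series, 500), "outside")
  # the steepest consecutive step brackets the switch at X_w = 0.9
  d <- abs(diff(prof$value))
  k_max <- which.max(d)
  expect_true(prof$mixing[k_max] <= 0.9 && prof$mixing[k_max + 1L] >= 0.9)
})

test_that("classify_profile distinguishes the two families", {
  expect_equal(classify_profile(data.frame(value = c(-8, -6, -3, -2))),
               "sign_preserving")
  expect_equal(classify_profile(data.frame(value = c(-3, -1, 2, 4))),
               "sign_inverting")
  expect_equal(classify_profile(data.frame(value = c(-0.01, 0.01, 0)),
                                deadband = 0.05),
               "indeterminate")
  expect_error(classify_profile(data.frame(value = c(1, 2))), "3 profile")
})

test_that("two_basis_fit: consistent series accepted with recovered coefficients", {
  # noiseless: exact coefficients, CONSISTENT
  res <- make_solvent_series("two_state", 9, spec = generator_spec(1, 0))
  fit <- two_basis_fit(res$series, res$basis_a, res$basis_b, noise_sigma = 0)
  expect_equal(fit$verdict, "CONSISTENT")
  expect_lt(max(abs(fit$coefficients[, "c_b"] - res$weights)), 0.01)
  expect_lt(max(abs(rowSums(fit$coefficients) - 1)), 0.01)
  # 2% noise: CONSISTENT, coefficients within 5%, residual <= 1.5 sigma
  resn <- make_solvent_series("two_state", 9, spec = generator_spec(3, 0.02))
  fitn <- two_basis_fit(resn$series, resn$basis_a, resn$basis_b,
                        noise_sigma = resn$noise_sigma_abs)
  expect_equal(fitn$verdict, "CONSISTENT")
  expect_lt(max(abs(fitn$coefficients[, "c_b"] - resn$weights)), 0.05)
  expect_lt(max(fitn$residual_rms), 1.5 * resn$noise_sigma_abs)
  # members identical to basis A
  wl <- res$series$wavelengths
  pure <- spectrum_series(wl, c(0, 0.5, 1),
                          matrix(rep(res$basis_a$value, 3), ncol = 3))
  fitp <- two_basis_fit(pure, res$basis_a, res$basis_b, noise_sigma = 0)
  expect_equal(unname(fitp$coefficients),
               matrix(rep(c(1, 0), each = 3), 3, 2), tolerance = 1e-8)
  expect_lt(max(fitp$residual_rms), 1e-8 * max(abs(res$basis_a$value)))
})

test_that("two_basis_fit rejects a hidden third component", {
  res3 <- make_solvent_series("three_state", 9, spec = generator_spec(1, 0))
  fit3 <- two_basis_fit(res3$series, res3$basis_a, res3$basis_b,
                        noise_sigma = 1e-3 * max(abs(res3$series$values)))
  expect_equal(fit3$verdict, "REJECT")
  # also under realistic noise
  res3n <- make_solvent_series("three_state", 9, spec = generator_spec(5, 0.02))
  fit3n <- two_basis_fit(res3n$series, res3n$basis_a, res3n$basis_b,
                         noise_sigma = res3n$noise_sigma_abs)
  expect_equal(fit3n$verdict, "REJECT")
})

test_that("two_basis_fit verdict is invariant to reordering and rescaling", {
  res <- make_solvent_series("two_state", 9, spec = generator_spec(2, 0.02))
  fit <- two_basis_fit(res$series, res$basis_a, res$basis_b,
                       noise_sigma = res$noise_sigma_abs)
  # reverse the member order
  rev_series <- spectrum_series(res$series$wavelengths,
                                rev(1 - res$series$mixing),
                                res$series$values[, 9:1])
  fit_rev <- two_basis_fit(rev_series, res$basis_a, res$basis_b,
                           noise_sigma = res$noise_sigma_abs)
  expect_equal(fit_rev$verdict, fit$verdict)
  expect_equal(fit_rev$residual_rms, rev(fit$residual_rms))
  # common rescaling of series, bases and noise
  sc <- 17
  wl <- res$series$wavelengths
  fit_sc <- two_basis_fit(
    spectrum_series(wl, res$series$mixing, sc * res$series$values),
    cd_spectrum(wl, sc * res$basis_a$value),
    cd_spectrum(wl, sc * res$basis_b$value),
    noise_sigma = sc * res$noise_sigma_abs
  )
  expect_equal(fit_sc$verdict, fit$verdict)
  expect_equal(fit_sc$coefficients, fit$coefficients, tolerance = 1e-9)
  # collinear bases are rejected
  expect_error(
    two_basis_fit(res$series, res$basis_a,
                  cd_spectrum(wl, 2 * res$basis_a$value), 0),
    "collinear"
  )
})

test_that("convex-constrained fit stays on the simplex", {
  res <- make_solvent_series("two_state", 9, spec = generator_spec(4, 0.02))
  fit <- two_basis_fit(res$series, res$basis_a, res$basis_b,
                       noise_sigma = res$noise_sigma_abs, convex = TRUE)
  expect_true(all(fit$coefficients >= 0))
  expect_equal(unname(rowSums(fit$coefficients)), rep(1, 9))
  expect_lt(max(abs(fit$coefficients[, "c_b"] - res$weights)), 0.05)
})
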