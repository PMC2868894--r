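# band shapes, epsilon -> alpha'' conversion, Kramers-Kronig transform

test_that("band_absorption peak and width match the band definition", {
  for (shape in c("gaussian", "lorentzian")) {
    b <- std_band(shape = shape)
    g <- std_grid(b)
    eps <- band_absorption(b, g)
    nu <- as.numeric(g)
    k <- which.min(abs(nu - b$center_wavenumber))
    expect_equal(eps[k], b$eps_max)
    # FWHM read back from the curve, within one grid step
    above <- nu[eps >= b$eps_max / 2]
    expect_near(diff(range(above)), b$fwhm_cm, 2 * attr(g, "step"))
  }
})

test_that("lorentzian band has larger integrated area than gaussian", {
  b_g <- std_band(shape = "gaussian")
  b_l <- std_band(shape = "lorentzian")
  g <- grid_for_bands(b_g, step = 10, margin = 12)
  area_g <- sum(band_absorption(b_g, g)) * attr(g, "step")
  area_l <- sum(band_absorption(b_l, g)) * attr(g, "step")
  expect_gt(area_l, area_g)
  # closed-form oracle over the truncated window [-W, W]:
  # gaussian: eps*fwhm/2*sqrt(pi/ln2) (tail loss negligible at 12 fwhm);
  # lorentzian: 2*eps*gamma*atan(W/gamma)
  W <- 12 * std_band()$fwhm_cm
  gam <- std_band()$fwhm_cm / 2
  area_l_closed <- 2 * gam * atan(W / gam)
  area_g_closed <- std_band()$fwhm_cm / 2 * sqrt(pi / log(2))
  expect_near(area_l / area_g, area_l_closed / area_g_closed, 0.005)
})

test_that("uncovered grid raises a coverage error", {
  b <- std_band()
  g <- frequency_grid(b$center_wavenumber - 1000, b$center_wavenumber + 1000, 20)
  expect_error(band_absorption(b, g), "does not cover")
})

test_that("alpha_im_from_epsilon is the pointwise eps/nu map", {
  g <- std_grid()
  nu <- as.numeric(g)
  expect_equal(alpha_im_from_epsilon(numeric(length(nu)), g),
               numeric(length(nu)))
  eps <- band_absorption(std_band(), g)
  a1 <- alpha_im_from_epsilon(eps, g)
  expect_equal(alpha_im_from_epsilon(2 * eps, g), 2 * a1)
  # linear ramp eps = c * nu gives a constant alpha'' = k * c
  k <- 3.7e-23
  expect_equal(alpha_im_from_epsilon(5 * nu, g, conversion_constant = k),
               rep(k * 5, length(nu)))
  expect_error(alpha_im_from_epsilon(-eps, g), "nonnegative")
})

test_that("KK transform of a lorentzian matches the closed form", {
  nu0 <- 28571
  gam <- 500 # HWHM; fwhm 1000
  g <- frequency_grid(nu0 - 8000, nu0 + 8000, 20)
  nu <- as.numeric(g)
  ai <- gam^2 / ((nu - nu0)^2 + gam^2)
  ctr <- abs(nu - nu0) <= 1.5 * 2 * gam # central 3 x FWHM
  # resonance mode vs single-pole dispersion
  ar <- suppressWarnings(kk_real_from_imag(ai, g, mode = "resonance"))
  closed <- gam * (nu0 - nu) / ((nu - nu0)^2 + gam^2)
  expect_lt(max(abs(ar - closed)[ctr]) / max(abs(closed)), 0.01)
  # causal mode vs two-pole dispersion
  arc <- suppressWarnings(kk_real_from_imag(ai, g, mode = "causal"))
  closed2 <- closed + gam * (nu0 + nu) / ((nu + nu0)^2 + gam^2)
  expect_lt(max(abs(arc - closed2)[ctr]) / max(abs(closed2)), 0.01)
  # sign pattern: positive on the long-wavelength (low-nu) side
  expect_true(all(arc[nu < nu0 - attr(g, "step")] > 0))
  expect_true(all(arc[nu > nu0 + 5 * attr(g, "step")] < 0))
})

test_that("alpha' vanishes at the center of a symmetric gaussian band", {
  nu0 <- 28571
  sig <- 850
  g <- frequency_grid(nu0 - 6000, nu0 + 6000, 20)
  nu <- as.numeric(g)
  ai <- exp(-(nu - nu0)^2 / (2 * sig^2))
  ar <- kk_real_from_imag(ai, g, mode = "resonance")
  k <- which.min(abs(nu - nu0))
  expect_lt(abs(ar[k]), 1e-3 * max(abs(ar)))
  # causal mode crosses zero within one grid step of the center
  arc <- kk_real_from_imag(ai, g, mode = "causal")
  cross <- nu[which(diff(sign(arc)) != 0)]
  expect_lt(min(abs(cross - nu0)), attr(g, "step") + 1e-9)
})

test_that("KK transform is linear and scales exactly", {
  nu0 <- 28571
  g <- frequency_grid(nu0 - 6000, nu0 + 6000, 40)
  nu <- as.numeric(g)
  f1 <- exp(-(nu - nu0 + 500)^2 / (2 * 600^2))
  f2 <- exp(-(nu - nu0 - 800)^2 / (2 * 400^2))
  for (mode in c("causal", "resonance")) {
    t1 <- kk_real_from_imag(f1, g, mode = mode)
    t2 <- kk_real_from_imag(f2, g, mode = mode)
    t12 <- kk_real_from_imag(2 * f1 + 3 * f2, g, mode = mode)
    expect_equal(t12, 2 * t1 + 3 * t2, tolerance = 1e-12)
    expect_equal(kk_real_from_imag(5 * f1, g, mode = mode), 5 * t1,
                 tolerance = 1e-12)
  }
})

test_that("KK transform converges under grid refinement", {
  nu0 <- 28571
  sig <- 850
  mk <- function(step) {
    g <- frequency_grid(nu0 - 6000, nu0 + 6000, step)
    nu <- as.numeric(g)
    list(g = g, ar = kk_real_from_imag(exp(-(nu - nu0)^2 / (2 * sig^2)), g))
  }
  coarse <- mk(40)
  fine <- mk(20)
  on_coarse <- stats::approx(as.numeric(fine$g), fine$ar,
                             xout = as.numeric(coarse$g))$y
  rms <- sqrt(mean((coarse$ar - on_coarse)^2)) / max(abs(fine$ar))
  expect_lt(rms, 0.005)
})

test_that("insufficient tail decay warns, severe truncation errors", {
  nu0 <- 28571
  g <- frequency_grid(nu0 - 2000, nu0 + 2000, 20)
  nu <- as.numeric(g)
  wide <- exp(-(nu - nu0)^2 / (2 * 1500^2)) # ~0.41 at the edges
  expect_error(kk_real_from_imag(wide, g), "does not decay")
  mid <- exp(-(nu - nu0)^2 / (2 * 800^2)) # ~0.04 at the edges
  expect_warning(kk_real_from_imag(mid, g), "truncated")
})

test_that("transition_polarizability has nonnegative alpha'' and one sign change", {
  p <- transition_polarizability(std_band(), std_grid())
  expect_true(all(p$alpha_imag >= 0))
  s <- sign(p$alpha_real)
  changes <- sum(diff(s[s != 0]) != 0)
  expect_equal(changes, 1)
  k <- which(diff(sign(p$alpha_real)) != 0)
  expect_near(as.numeric(p$grid)[k], std_band()$center_wavenumber,
              3 * attr(p$grid, "step"))
})
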