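#' Seeded synthetic-data generators
#'
#' Every input the pipeline consumes can be generated here with known
#' ground truth: twisted two-chromophore assemblies, multi-band "dimeric"
#' molecules, solvent-mixture spectrum series with or without common
#' isodichroic crossings, and noisy first-order mutarotation traces.
#' All stochastic output requires an explicit seed; the same seed gives
#' bit-identical output, and the ground truth never depends on the seed.
#' Noise is additive i.i.d. Gaussian on the ordinate (chart-recorder
#' noise).
#'
#' @name synthetic_data
NULL

#' Generator settings
#'
#' @param seed integer seed, mandatory for any stochastic output
#' @param noise_sigma noise standard deviation as a fraction of the
#'   signal amplitude (>= 0); default 0.01
#' @param grid_nm wavelength grid as `c(from, to, step)` in nm
#' @return object of class `generator_spec`
#' @export
generator_spec <- function(seed, noise_sigma = 0.01,
                           grid_nm = c(210, 400, 1)) {
  stopifnot(is.numeric(seed), length(seed) == 1L, noise_sigma >= 0,
            length(grid_nm) == 3L, grid_nm[2L] > grid_nm[1L],
            grid_nm[3L] > 0)
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 grid_nm = grid_nm),
            class = "generator_spec")
}

# run code with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

grid_points_nm <- function(spec) {
  seq(spec$grid_nm[1L], spec$grid_nm[2L], by = spec$grid_nm[3L])
}

#' Twisted pair of identical chromophores
#'
#' Two identical oscillators at (0,0,0) and (0,0,separation), both
#' perpendicular to the separation axis, the second rotated about it by
#' the dihedral angle.  Dihedral 0 is the coplanar (CD-silent)
#' arrangement; +theta and -theta are mirror images.  The default
#' separation matches the inter-moiety distance of a biaryl-linked
#' colchicinoid dimer (about 14.5 Angstrom).
#'
#' @param dihedral_deg twist angle about the separation axis, degrees
#' @param separation center-to-center distance, Angstrom (> 0.5)
#' @param band shared [transition_band()]
#' @return [oscillator_assembly()]
#' @export
make_twisted_pair <- function(dihedral_deg, separation = 14.5,
                              band = transition_band(260, 1e4, 2000)) {
  stopifnot(separation > 0.5)
  th <- dihedral_deg * pi / 180
  oscillator_assembly(
    bands = list(band),
    positions = rbind(c(0, 0, 0), c(0, 0, separation)),
    orientations = rbind(c(1, 0, 0), c(cos(th), sin(th), 0)),
    band_index = c(1L, 1L),
    name = sprintf("twisted_pair_%+.1fdeg", dihedral_deg)
  )
}

#' Multi-band "dimeric" molecule
#'
#' One pair of identical oscillators per transition.  All in-window
#' oscillators are parallel, so their mutual cross terms vanish (parallel
#' transition moments have zero vector product) and within each pair the
#' degenerate couplet vanishes too.  Chirality enters through one intense
#' far-UV "anchor" transition (default 190 nm, emulating the strong
#' high-energy bands these chromophores carry below 200 nm) whose
#' orientation is skewed against the stack: each visible band then
#' acquires a monosignate non-degenerate cross term proportional to
#' \eqn{\epsilon_i(\lambda)\,\alpha'_{anchor}(\lambda)}, peaked at (very
#' near) its own band center because the anchor's dispersion is smooth
#' and slowly varying across the whole window.  The sign of each feature
#' is set by which side of the anchor the band's pair sits on.
#'
#' The default centers are the seven extrema wavelengths of the
#' biisocolchicide series (377, 342, 305, 270, 252, 235, 222 nm), with
#' the strong/weak intensity pattern and sign pattern of its two band
#' families.  Setting `anchor = FALSE` instead builds plain twisted pairs
#' stacked along z (a single band then reduces to
#' [make_twisted_pair()]).
#'
#' @param centers_nm band centers, nm
#' @param intensities eps_max per band, M^-1 cm^-1 (zero allowed: such
#'   oscillators are inert)
#' @param widths_cm FWHM per band, cm^-1
#' @param signs desired sign of each band's CD feature (+1/-1)
#' @param anchor logical; include the far-UV anchor transition
#' @param anchor_band [transition_band()] of the anchor
#' @param pair_spacing z offset within a pair, Angstrom
#' @param base_distance minimum pair-to-anchor distance, Angstrom
#' @param twist_deg twist used when `anchor = FALSE`
#' @return [oscillator_assembly()]
#' @export
make_multiband_molecule <- function(centers_nm = c(377, 342, 305, 270, 252, 235, 222),
                                    intensities = c(1e4, 1e4, 2.5e3, 2.5e3, 2.5e3, 1e4, 2.5e3),
                                    widths_cm = rep(600, length(centers_nm)),
                                    signs = c(-1, -1, 1, -1, 1, 1, -1),
                                    anchor = TRUE,
                                    anchor_band = transition_band(190, 5e4, 3000),
                                    pair_spacing = 5,
                                    base_distance = 6,
                                    twist_deg = 30) {
  n <- length(centers_nm)
  if (length(intensities) != n || length(widths_cm) != n) {
    stop("centers, intensities and widths must have equal length")
  }
  signs <- rep_len(signs, n)
  bands <- Map(transition_band, centers_nm, intensities, widths_cm)
  if (!anchor) {
    pos <- NULL; ori <- NULL; idx <- integer(0)
    for (k in seq_len(n)) {
      z0 <- (k - 1L) * (pair_spacing + 4)
      th <- twist_deg * pi / 180
      pos <- rbind(pos, c(0, 0, z0), c(0, 0, z0 + pair_spacing))
      ori <- rbind(ori, c(1, 0, 0), c(cos(th), sin(th), 0))
      idx <- c(idx, k, k)
    }
    return(oscillator_assembly(bands, pos, ori, idx,
                               name = "multiband_molecule"))
  }
  # strong bands are placed farther from the anchor than weak ones so
  # that all features come out with comparable amplitude (cross term
  # scales as eps_i / R^2)
  strong <- intensities >= stats::median(intensities)
  pos <- NULL; ori <- NULL; idx <- integer(0)
  up <- 0L; dn <- 0L
  for (k in seq_len(n)) {
    step_k <- if (strong[k]) 8 else 3
    if (signs[k] > 0) {
      up <- up + 1L
      z0 <- base_distance + up * step_k
    } else {
      dn <- dn + 1L
      z0 <- -(base_distance + dn * step_k) - pair_spacing
    }
    pos <- rbind(pos, c(0, 0, z0), c(0, 0, z0 + pair_spacing))
    ori <- rbind(ori, c(1, 0, 0), c(1, 0, 0))
    idx <- c(idx, k, k)
  }
  # anchor: skewed 45 degrees so it both couples (G != 0) and twists
  # (e_i x e_a != 0) against the parallel stack
  bands <- c(bands, list(anchor_band))
  pos <- rbind(pos, c(0, 0, 0))
  ori <- rbind(ori, c(1, 1, 0) / sqrt(2))
  idx <- c(idx, n + 1L)
  oscillator_assembly(bands, pos, ori, idx, name = "multiband_molecule")
}

# internal: seven-band elongation basis emulating the water end state of
# the MeCN/H2O series (signs/magnitudes in chart mm)
solvent_basis_a <- function(wl) {
  centers <- c(377, 342, 305, 270, 252, 235, 222)
  amps <- c(-8, -9, 2, -1.5, 1.5, 12, -6)
  widths <- c(12, 12, 8, 7, 6, 8, 6) # nm
  v <- numeric(length(wl))
  for (k in seq_along(centers)) {
    v <- v + amps[k] * exp(-(wl - centers[k])^2 / (2 * (widths[k] / 2.355)^2))
  }
  v
}

# difference spectrum with exact zeros at the requested crossing
# wavelengths; smooth spectral envelope, non-vanishing at the grid edges
solvent_basis_diff <- function(wl, crossings_nm = c(280, 320), amp = 4) {
  stopifnot(length(crossings_nm) == 2L)
  q <- (wl - crossings_nm[1L]) * (wl - crossings_nm[2L])
  env <- exp(-((wl - mean(crossings_nm)) / 60)^2)
  d <- q * env
  amp * d / max(abs(d))
}

#' Solvent-mixture spectrum series with ground truth
#'
#' Members are mixtures of two (or three) basis spectra with the weight of
#' the "hydrogen-bonded" basis following a logistic switch in the water
#' mole fraction, centered at `switch_center` (default 0.9, where the real
#' system shows its swift elongation change).  The default steepness puts
#' 90% of the weight change within a mole-fraction window of 0.05.  In
#' `two_state` mode the two bases cross at exactly the constructed
#' isodichroic wavelengths; `three_state` adds a hidden third component at
#' 20% relative amplitude, peaked mid-switch, which destroys both the
#' common crossings and two-basis representability.
#'
#' @param mode `"two_state"` or `"three_state"`
#' @param n_members number of compositions (>= 3; default 9)
#' @param switch_center logistic center in X_w
#' @param switch_steepness logistic scale; default 0.05/log(19^2) so the
#'   5%-95% rise spans 0.05 in X_w
#' @param spec [generator_spec()] (seed + noise level + grid)
#' @param crossings_nm designed isodichroic wavelengths (two_state)
#' @return list with `series` ([spectrum_series()]), and ground truth:
#'   `weights` (per-member hidden weight of basis B), `basis_a`,
#'   `basis_b`, `crossings_nm` (NULL for three_state), `third_weight`
#' @export
make_solvent_series <- function(mode = c("two_state", "three_state"),
                                n_members = 9,
                                switch_center = 0.9,
                                switch_steepness = 0.05 / (2 * log(19)),
                                spec = generator_spec(1),
                                crossings_nm = c(280, 320)) {
  mode <- match.arg(mode)
  stopifnot(n_members >= 3L)
  wl <- grid_points_nm(spec)
  a <- solvent_basis_a(wl)
  d <- solvent_basis_diff(wl, crossings_nm,
                          amp = 0.4 * max(abs(a)))
  b <- a + d
  # compositions: denser near the switch, as a titration would be run
  xw <- sort(unique(c(
    seq(0, 1, length.out = max(3L, n_members - 3L)),
    switch_center + c(-0.04, 0, 0.04)
  )))
  xw <- xw[xw >= 0 & xw <= 1]
  if (length(xw) > n_members) {
    keep <- unique(round(seq(1, length(xw), length.out = n_members)))
    xw <- xw[keep]
  }
  w <- 1 / (1 + exp(-(xw - switch_center) / switch_steepness))
  vals <- outer(a, 1 - w) + outer(b, w)
  third <- NULL
  if (mode == "three_state") {
    cshape <- exp(-((wl - 300) / 25)^2)
    third <- 0.2 * max(abs(a)) * 4 * w * (1 - w)
    vals <- vals + outer(cshape, third)
  }
  amp <- max(abs(vals))
  sigma <- spec$noise_sigma * amp
  if (sigma > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(length(vals), 0, sigma),
                              nrow(vals), ncol(vals)))
    vals <- vals + noise
  }
  list(
    series = spectrum_series(wl, xw, vals, concentration_constant = TRUE),
    weights = w,
    basis_a = cd_spectrum(wl, a, label = "basis_A(Xw=0)", unit = "elongation_mm"),
    basis_b = cd_spectrum(wl, b, label = "basis_B(Xw=1)", unit = "elongation_mm"),
    crossings_nm = if (mode == "two_state") sort(crossings_nm) else NULL,
    third_weight = third,
    noise_sigma_abs = sigma
  )
}

#' Noisy mutarotation trace with ground truth
#'
#' Exact single-exponential relaxation of the minor-atropisomer fraction
#' plus seeded Gaussian noise.  Defaults emulate the chloroform-to-ethanol
#' jump of the biisocolchicide system: the minor fraction relaxes from
#' 17% to 5%, essentially complete within ~45 min.
#'
#' @param k_obs observed relaxation rate, min^-1
#' @param start_fraction_minor,eq_fraction_minor initial and equilibrium
#'   minor-state fractions
#' @param state_cd values of the per-state signal at the monitored
#'   wavelength, `c(major =, minor =)` (chart mm)
#' @param time_span total duration, min
#' @param n_points number of samples (>= 4)
#' @param spec [generator_spec()]
#' @param wavelength_nm monitored wavelength (metadata)
#' @return list with `trace` ([kinetics_trace()]) and ground truth
#'   `k_obs`, `asymptote`, `initial_value`, `noise_sigma_abs`
#' @export
make_mutarotation_trace <- function(k_obs = 0.1,
                                    start_fraction_minor = 0.17,
                                    eq_fraction_minor = 0.05,
                                    state_cd = c(major = -17, minor = -3),
                                    time_span = 60,
                                    n_points = 100,
                                    spec = generator_spec(1),
                                    wavelength_nm = 350) {
  stopifnot(k_obs > 0, n_points >= 4L)
  times <- seq(0, time_span, length.out = n_points)
  xb <- eq_fraction_minor +
    (start_fraction_minor - eq_fraction_minor) * exp(-k_obs * times)
  y <- (1 - xb) * state_cd[["major"]] + xb * state_cd[["minor"]]
  y0 <- y[1L]
  yinf <- (1 - eq_fraction_minor) * state_cd[["major"]] +
    eq_fraction_minor * state_cd[["minor"]]
  amp <- abs(y0 - yinf)
  sigma <- spec$noise_sigma * amp
  if (sigma > 0) {
    y <- y + with_seed(spec$seed, stats::rnorm(n_points, 0, sigma))
  }
  list(
    trace = kinetics_trace(times, y, wavelength_nm),
    k_obs = k_obs,
    asymptote = yinf,
    initial_value = y0,
    noise_sigma_abs = sigma
  )
}
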