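#' Two-state atropisomer thermodynamics and mutarotation kinetics
#'
#' A hindered-rotation pair (major conformer `a`, minor conformer `b`)
#' interconverting by first-order kinetics.  Populations and the free
#' energy difference are linked by the Boltzmann relation
#' \deqn{\Delta G = -RT \ln(x_b / x_a), \qquad
#'       x_b = 1 / (1 + e^{\Delta G / RT})}
#' with R = 1.987e-3 kcal mol^-1 K^-1 and T defaulting to 300 K.  The
#' observable "mutarotation" is the relaxation of the CD signal as a
#' non-equilibrium mixture (e.g. an HPLC-isolated minor atropisomer)
#' returns to equilibrium.
#'
#' @name ensemble_thermo_kinetics
NULL

GAS_CONSTANT_KCAL <- 1.987e-3

#' Free energy difference from a two-state population
#'
#' @param fraction_minor,fraction_major state populations, each in (0,1),
#'   summing to 1
#' @param temperature K (default 300)
#' @return delta G in kcal/mol, positive when the minor state is less
#'   stable
#' @examples
#' delta_g_from_populations(0.05, 0.95) # ~1.76 kcal/mol
#' @export
delta_g_from_populations <- function(fraction_minor, fraction_major,
                                     temperature = 300) {
  stopifnot(temperature > 0)
  if (fraction_minor <= 0 || fraction_minor >= 1 ||
      fraction_major <= 0 || fraction_major >= 1) {
    stop("fractions must lie strictly inside (0,1)")
  }
  if (abs(fraction_minor + fraction_major - 1) > 1e-8) {
    stop("fractions must sum to 1")
  }
  -GAS_CONSTANT_KCAL * temperature * log(fraction_minor / fraction_major)
}

#' Populations from a free energy difference
#'
#' Inverse of [delta_g_from_populations()]; round-trips to 1e-10.
#'
#' @param delta_g kcal/mol (positive favors the major state)
#' @param temperature K
#' @return named numeric vector `c(fraction_major=, fraction_minor=)`
#' @export
populations_from_delta_g <- function(delta_g, temperature = 300) {
  stopifnot(temperature > 0)
  x_minor <- 1 / (1 + exp(delta_g / (GAS_CONSTANT_KCAL * temperature)))
  c(fraction_major = 1 - x_minor, fraction_minor = x_minor)
}

#' Two-state atropisomer system
#'
#' @param fraction_minor equilibrium population of the minor state (0,1)
#' @param temperature K
#' @param k_forward minor -> major rate constant, min^-1
#' @param spectra optional list of two [cd_spectrum()]s,
#'   `list(major =, minor =)`, on a common wavelength grid
#' @return object of class `atropisomer_system`
#' @export
atropisomer_system <- function(fraction_minor, temperature = 300,
                               k_forward = NULL, spectra = NULL) {
  stopifnot(fraction_minor > 0, fraction_minor < 1)
  if (!is.null(spectra)) {
    stopifnot(is.list(spectra), all(c("major", "minor") %in% names(spectra)))
    if (!isTRUE(all.equal(spectra$major$wavelength_nm,
                          spectra$minor$wavelength_nm))) {
      stop("per-state spectra must share a wavelength grid")
    }
  }
  dg <- delta_g_from_populations(fraction_minor, 1 - fraction_minor,
                                 temperature)
  structure(
    list(fraction_minor = fraction_minor,
         fraction_major = 1 - fraction_minor,
         temperature = temperature,
         delta_g = dg,
         k_forward = k_forward,
         spectra = spectra),
    class = "atropisomer_system"
  )
}

#' @export
print.atropisomer_system <- function(x, ...) {
  cat(sprintf(
    "<atropisomer_system> %.1f/%.1f%% at %g K, dG = %.3f kcal/mol%s\n",
    100 * x$fraction_minor, 100 * x$fraction_major, x$temperature,
    x$delta_g,
    if (is.null(x$k_forward)) "" else sprintf(", k_f = %.3g min^-1", x$k_forward)
  ))
  invisible(x)
}

#' Population-weighted ensemble spectrum
#'
#' @param spectra list of [cd_spectrum()] on one common grid
#' @param fractions numeric weights summing to 1
#' @return [cd_spectrum()]
#' @export
ensemble_spectrum <- function(spectra, fractions) {
  stopifnot(length(spectra) == length(fractions), length(spectra) >= 1L)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  wl <- spectra[[1L]]$wavelength_nm
  for (s in spectra[-1L]) {
    if (!isTRUE(all.equal(s$wavelength_nm, wl))) {
      stop("spectra are on different wavelength grids; resample first")
    }
  }
  v <- Reduce(`+`, Map(function(s, f) f * s$value, spectra, fractions))
  cd_spectrum(wl, v, label = "ensemble", unit = attr(spectra[[1L]], "unit"))
}

# observed relaxation rate: k_f (minor->major) plus the back reaction
# fixed by detailed balance at the equilibrium populations
k_observed <- function(system) {
  stopifnot(!is.null(system$k_forward), system$k_forward > 0)
  k_f <- system$k_forward
  k_r <- k_f * system$fraction_minor / system$fraction_major
  k_f + k_r
}

#' First-order relaxation of the minor-state population
#'
#' \eqn{x_b(t) = x_b^{eq} + (x_b(0) - x_b^{eq}) e^{-k_{obs} t}} with
#' \eqn{k_{obs} = k_f + k_r} and \eqn{k_r = k_f\, x_b^{eq}/x_a^{eq}}
#' (detailed balance).  Total population is conserved identically.
#'
#' @param system [atropisomer_system()] with `k_forward` set
#' @param initial_fraction_minor x_b at t = 0
#' @param times numeric vector, min
#' @return data.frame with columns `time`, `fraction_minor`,
#'   `fraction_major`
#' @export
relaxation_solution <- function(system, initial_fraction_minor, times) {
  stopifnot(initial_fraction_minor >= 0, initial_fraction_minor <= 1)
  k_obs <- k_observed(system)
  xb <- system$fraction_minor +
    (initial_fraction_minor - system$fraction_minor) * exp(-k_obs * times)
  data.frame(time = times, fraction_minor = xb, fraction_major = 1 - xb)
}

#' Kinetics trace container
#'
#' @param times min, strictly increasing, >= 4 points
#' @param cd_value signal at one wavelength (elongation mm or
#'   delta-epsilon)
#' @param wavelength_nm monitored wavelength
#' @param temperature K
#' @param unit ordinate unit tag
#' @export
kinetics_trace <- function(times, cd_value, wavelength_nm,
                           temperature = 274, unit = "elongation_mm") {
  stopifnot(length(times) == length(cd_value), length(times) >= 4L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    data.frame(time = times, cd_value = cd_value),
    class = c("kinetics_trace", "data.frame"),
    wavelength_nm = wavelength_nm, temperature = temperature, unit = unit
  )
}

#' @export
print.kinetics_trace <- function(x, ...) {
  cat(sprintf(
    "<kinetics_trace> %d points over %.1f min at %.0f nm [%s]\n",
    nrow(x), max(x$time) - min(x$time), attr(x, "wavelength_nm"),
    attr(x, "unit")
  ))
  invisible(x)
}

#' CD time trace of a relaxing atropisomer mixture
#'
#' \eqn{CD(t) = x_a(t)\,CD_a(\lambda) + x_b(t)\,CD_b(\lambda)}; the trace
#' extrapolates at infinite time to the equilibrium-ensemble dichroism.
#' The initial slope is \eqn{(CD_a - CD_b)(\lambda)\, k_{obs}\,(x_b(0) -
#' x_b^{eq})}.
#'
#' @inheritParams relaxation_solution
#' @param wavelength_nm monitored wavelength; must lie inside the grid of
#'   the per-state spectra
#' @return [kinetics_trace()]
#' @export
cd_time_trace <- function(system, initial_fraction_minor, wavelength_nm,
                          times) {
  if (is.null(system$spectra)) stop("per-state spectra are not set")
  cda <- spectrum_value_at(system$spectra$major, wavelength_nm)
  cdb <- spectrum_value_at(system$spectra$minor, wavelength_nm)
  x <- relaxation_solution(system, initial_fraction_minor, times)
  kinetics_trace(times, x$fraction_major * cda + x$fraction_minor * cdb,
                 wavelength_nm, unit = attr(system$spectra$major, "unit"))
}

#' Fit a single-exponential relaxation
#'
#' Unweighted least-squares fit of \eqn{y(t) = y_\infty + (y_0 - y_\infty)
#' e^{-k t}}, with analytic starting values from a log-linearized pass.
#' Returns the observed rate, the asymptote, the fitted initial value, the
#' initial rate \eqn{k_{obs}(y_0 - y_\infty)} and the residual RMS.
#'
#' @param trace [kinetics_trace()] (or data.frame with `time`, `cd_value`)
#' @return list with `k_obs`, `asymptote`, `initial_value`,
#'   `initial_rate`, `residual_rms`, `fit` (the nls object)
#' @export
fit_relaxation <- function(trace) {
  t <- trace$time
  y <- trace$cd_value
  if (length(t) < 4L) stop("need at least 4 time points")
  amp <- diff(range(y))
  if (amp <= 1e-12 * max(abs(y), 1)) {
    stop("constant trace: relaxation rate not identifiable")
  }
  # log-linearized initial guesses; asymptote guessed slightly beyond the
  # last observation in the direction of approach
  y_inf0 <- y[length(y)] + 0.05 * (y[length(y)] - y[1L])
  z <- y - y_inf0
  s0 <- sign(z[1L])
  usable <- s0 * z > amp * 1e-3
  k0 <- if (sum(usable) >= 2L) {
    max(-stats::coef(stats::lm(log(s0 * z[usable]) ~ t[usable]))[[2L]], 1e-6)
  } else {
    1 / max(t)
  }
  fit <- tryCatch(
    stats::nls(y ~ yinf + (y0 - yinf) * exp(-k * t),
               start = list(yinf = y_inf0, y0 = y[1L], k = k0),
               # scaleOffset keeps the relative-offset criterion finite on
               # (near-)zero-residual data
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1)),
    error = function(e) {
      stop("relaxation fit did not converge: ", conditionMessage(e),
           sprintf(" (starts: yinf=%.3g, y0=%.3g, k=%.3g)", y_inf0, y[1L], k0))
    }
  )
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  list(
    k_obs = unname(cf[["k"]]),
    asymptote = unname(cf[["yinf"]]),
    initial_value = unname(cf[["y0"]]),
    initial_rate = unname(cf[["k"]] * (cf[["y0"]] - cf[["yinf"]])),
    residual_rms = sqrt(mean(res^2)),
    fit = fit
  )
}
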