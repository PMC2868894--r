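#' Electronic transition band
#'
#' One electrically allowed electronic transition, described by its
#' absorption band: center wavelength (nm), peak molar absorptivity
#' (M^-1 cm^-1), full width at half maximum in wavenumbers (cm^-1, i.e.
#' constant in energy, not wavelength -- line shapes are energy-domain
#' objects), and a line-shape family.
#'
#' @param center_nm band center wavelength, nm (> 0)
#' @param eps_max peak molar absorptivity, M^-1 cm^-1 (>= 0)
#' @param fwhm_cm full width at half maximum, cm^-1 (> 0)
#' @param shape `"gaussian"` or `"lorentzian"`
#' @return object of class `transition_band`
#' @examples
#' transition_band(350, 1e4, 2000)
#' @export
transition_band <- function(center_nm, eps_max, fwhm_cm,
                            shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(
    is.numeric(center_nm), length(center_nm) == 1L, center_nm > 0,
    is.numeric(eps_max), length(eps_max) == 1L, eps_max >= 0,
    is.numeric(fwhm_cm), length(fwhm_cm) == 1L, fwhm_cm > 0
  )
  structure(
    list(
      center_nm = center_nm,
      center_wavenumber = nm_to_wavenumber(center_nm),
      eps_max = eps_max,
      fwhm_cm = fwhm_cm,
      shape = shape
    ),
    class = "transition_band"
  )
}

#' @export
print.transition_band <- function(x, ...) {
  cat(sprintf(
    "<transition_band> %s, center %.1f nm (%.0f cm^-1), eps_max %.3g, fwhm %.0f cm^-1\n",
    x$shape, x$center_nm, x$center_wavenumber, x$eps_max, x$fwhm_cm
  ))
  invisible(x)
}

#' Uniform wavenumber grid
#'
#' Strictly increasing, uniformly spaced wavenumber axis.  Spectral
#' operations (band shapes, Kramers-Kronig, the coupled-oscillator engine)
#' all run on such a grid; conversion to nm happens only at the interfaces.
#'
#' @param from,to grid limits, cm^-1 (0 < from < to)
#' @param step grid spacing, cm^-1 (> 0)
#' @return object of class `frequency_grid` (numeric wavenumbers with
#'   attributes)
#' @export
frequency_grid <- function(from, to, step) {
  stopifnot(from > 0, to > from, step > 0)
  nu <- seq(from, to, by = step)
  if (length(nu) < 16L) {
    stop("frequency_grid needs at least 16 points; got ", length(nu))
  }
  structure(nu, class = "frequency_grid", step = step)
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf(
    "<frequency_grid> %d points, %.1f..%.1f cm^-1 (step %.2f), %.1f..%.1f nm\n",
    length(x), min(x), max(x), attr(x, "step"),
    wavenumber_to_nm(max(x)), wavenumber_to_nm(min(x))
  ))
  invisible(x)
}

#' Grid covering a set of bands
#'
#' Builds a [frequency_grid()] that spans all band centers with at least
#' `margin` times each band's FWHM on both sides (default 3, the coverage
#' the Kramers-Kronig quadrature assumes).
#'
#' @param bands list of [transition_band()]
#' @param step grid spacing, cm^-1
#' @param margin coverage margin in units of FWHM (>= 3 recommended)
#' @export
grid_for_bands <- function(bands, step = 20, margin = 3) {
  bands <- as_band_list(bands)
  lo <- min(vapply(bands, function(b) b$center_wavenumber - margin * b$fwhm_cm, 0))
  hi <- max(vapply(bands, function(b) b$center_wavenumber + margin * b$fwhm_cm, 0))
  lo <- max(lo, step)
  # snap the upper limit up so the margin is covered after seq() truncation
  hi <- lo + ceiling((hi - lo) / step) * step
  frequency_grid(lo, hi, step)
}

as_band_list <- function(bands) {
  if (inherits(bands, "transition_band")) bands <- list(bands)
  stopifnot(length(bands) >= 1L,
            all(vapply(bands, inherits, TRUE, "transition_band")))
  bands
}

# coverage check used by band_absorption and the KK pipeline
check_coverage <- function(band, grid, margin = 3) {
  lo <- band$center_wavenumber - margin * band$fwhm_cm
  hi <- band$center_wavenumber + margin * band$fwhm_cm
  if (min(grid) > lo || max(grid) < hi) {
    stop(sprintf(
      "grid [%.0f, %.0f] cm^-1 does not cover band at %.0f cm^-1 with %gx FWHM margin",
      min(grid), max(grid), band$center_wavenumber, margin
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Absorption band shape on a grid
#'
#' Evaluates the molar absorption curve \eqn{\epsilon(\nu)} of a single
#' transition.  The peak equals `eps_max` at the band center and the full
#' width at half maximum equals `fwhm_cm` (both exact properties of the
#' analytic shapes; on the grid they hold to within one grid step).
#'
#' @param band [transition_band()]
#' @param grid [frequency_grid()] covering the band (3x FWHM margin)
#' @return numeric vector, M^-1 cm^-1, one value per grid point
#' @export
band_absorption <- function(band, grid) {
  stopifnot(inherits(band, "transition_band"),
            inherits(grid, "frequency_grid"))
  check_coverage(band, grid)
  x <- as.numeric(grid) - band$center_wavenumber
  band$eps_max * lineshape_unit(x, band$fwhm_cm, band$shape)
}

# unit-peak line shape centered at 0 with the given FWHM
lineshape_unit <- function(x, fwhm, shape) {
  switch(shape,
    gaussian = {
      sigma <- fwhm / (2 * sqrt(2 * log(2)))
      exp(-x^2 / (2 * sigma^2))
    },
    lorentzian = {
      gamma <- fwhm / 2
      gamma^2 / (x^2 + gamma^2)
    },
    stop("unknown shape: ", shape)
  )
}

#' Imaginary polarizability from an absorption curve
#'
#' Pointwise \eqn{\alpha''(\nu) = k\, \epsilon(\nu)/\nu}.  With the default
#' conversion constant (see [devoe_constants()]) the result is a cgs
#' polarizability volume in cm^3 per molecule.
#'
#' @param eps numeric vector, molar absorptivity (>= 0)
#' @param grid [frequency_grid()] the curve lives on
#' @param conversion_constant scale factor k; default the cgs convention
#' @return numeric vector alpha'' on the grid, same length as `eps`
#' @export
alpha_im_from_epsilon <- function(eps, grid,
                                  conversion_constant = devoe_constants()$alpha_conversion) {
  stopifnot(inherits(grid, "frequency_grid"), length(eps) == length(grid))
  if (any(eps < 0)) stop("epsilon must be nonnegative")
  if (any(as.numeric(grid) <= 0)) stop("frequencies must be positive")
  conversion_constant * eps / as.numeric(grid)
}

#' Real polarizability by Kramers-Kronig transform
#'
#' Computes \eqn{\alpha'(\nu)} from \eqn{\alpha''(\nu)} by discrete
#' principal-value quadrature.  Two conventions are offered:
#' \describe{
#'   \item{`"causal"` (default)}{the full Kramers-Kronig relation
#'     \eqn{\alpha'(\nu) = (2/\pi)\, P\!\int_0^\infty \nu' \alpha''(\nu') /
#'     (\nu'^2 - \nu^2)\, d\nu'}, i.e. the Hilbert transform of the odd
#'     extension of \eqn{\alpha''}.  This is the response-function form: the
#'     resulting complex polarizability is analytic in the upper half
#'     plane, which in turn makes the coupled-oscillator CD exactly
#'     conservative (net rotational strength zero).  Its non-resonant term
#'     shifts the zero crossing of \eqn{\alpha'} off the band center by
#'     O(width^2/center), i.e. a few cm^-1 for typical electronic bands --
#'     within one grid step at practical resolutions.}
#'   \item{`"resonance"`}{the one-sided (rotating-wave) Hilbert transform
#'     \eqn{\alpha'(\nu) = (1/\pi) P\!\int \alpha''(\nu')/(\nu'-\nu) d\nu'};
#'     for a symmetric band this is exactly antisymmetric about the center,
#'     so \eqn{\alpha'} vanishes there identically.}
#' }
#' In either mode, for a single symmetric band \eqn{\alpha'} is positive on
#' the long-wavelength side of the center and negative on the
#' short-wavelength side.
#'
#' The quadrature subtracts the singularity
#' (\eqn{[\alpha''(\nu')-\alpha''(\nu)]/(\nu'-\nu)} is smooth) and adds the
#' analytic log end-correction, so accuracy is limited only by the grid
#' step and by truncation of the band tails.
#'
#' @param alpha_im numeric vector alpha'' on `grid`, nonnegative
#' @param grid [frequency_grid()]
#' @param mode `"causal"` or `"resonance"`
#' @param decay_tol maximum allowed ratio of alpha'' at the grid ends to
#'   its maximum before warning (default 0.01); ten times that is an error
#' @return numeric vector alpha' on the grid
#' @export
kk_real_from_imag <- function(alpha_im, grid,
                              mode = c("causal", "resonance"),
                              decay_tol = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "frequency_grid"), length(alpha_im) == length(grid))
  if (any(alpha_im < -1e-12 * max(abs(alpha_im)))) {
    stop("alpha'' must be nonnegative")
  }
  nu <- as.numeric(grid)
  m <- max(abs(alpha_im))
  if (m > 0) {
    edge <- max(abs(alpha_im[1L]), abs(alpha_im[length(alpha_im)])) / m
    if (edge > 10 * decay_tol) {
      stop(sprintf(
        "alpha'' does not decay at the grid ends (edge/max = %.2g); widen the grid", edge
      ))
    }
    if (edge > decay_tol) {
      warning(sprintf(
        "alpha'' decays only to %.2g of its maximum at the grid ends; KK transform is truncated",
        edge
      ))
    }
  }
  re <- hilbert_pv(alpha_im, nu)
  if (mode == "causal") {
    # mirror (negative-frequency) branch: alpha''(-nu) = -alpha''(nu);
    # no singularity for nu > 0, plain trapezoid
    h <- attr(grid, "step")
    re <- re + vapply(nu, function(v) {
      trapz(nu, alpha_im / (nu + v)) / pi
    }, 0)
    re
  } else {
    re
  }
}

# principal-value Hilbert transform (1/pi) P int f(nu')/(nu'-nu) dnu'
# on a uniform grid, singularity-subtracted with log end-correction
hilbert_pv <- function(f, nu) {
  n <- length(nu)
  h <- nu[2L] - nu[1L]
  out <- numeric(n)
  for (k in seq_len(n)) {
    d <- nu - nu[k]
    g <- numeric(n)
    g[-k] <- (f[-k] - f[k]) / d[-k]
    # smooth limit at the singular point: central finite difference
    g[k] <- if (k == 1L) {
      (f[2L] - f[1L]) / h
    } else if (k == n) {
      (f[n] - f[n - 1L]) / h
    } else {
      (f[k + 1L] - f[k - 1L]) / (2 * h)
    }
    s <- trapz(nu, g)
    # analytic PV of the subtracted constant over [nu_1, nu_n]
    if (k > 1L && k < n) {
      s <- s + f[k] * log((nu[n] - nu[k]) / (nu[k] - nu[1L]))
    }
    out[k] <- s / pi
  }
  out
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * (x[-1L] - x[-n])) / 2
}

#' Complex polarizability curve of one transition
#'
#' Convenience pipeline: band -> epsilon(nu) -> alpha''(nu) -> alpha'(nu).
#'
#' @inheritParams band_absorption
#' @inheritParams kk_real_from_imag
#' @param conversion_constant see [alpha_im_from_epsilon()]
#' @return object of class `polarizability_curve` with fields `grid`,
#'   `alpha_real`, `alpha_imag`, `band`
#' @export
transition_polarizability <- function(band, grid,
                                      conversion_constant = devoe_constants()$alpha_conversion,
                                      mode = "causal") {
  eps <- band_absorption(band, grid)
  ai <- alpha_im_from_epsilon(eps, grid, conversion_constant)
  ar <- kk_real_from_imag(ai, grid, mode = mode)
  polarizability_curve(grid, ar, ai, band = band)
}

#' @rdname transition_polarizability
#' @param alpha_real,alpha_imag numeric vectors on `grid`
#' @export
polarizability_curve <- function(grid, alpha_real, alpha_imag, band = NULL) {
  stopifnot(inherits(grid, "frequency_grid"),
            length(alpha_real) == length(grid),
            length(alpha_imag) == length(grid))
  structure(
    list(grid = grid, alpha_real = alpha_real, alpha_imag = alpha_imag,
         band = band),
    class = "polarizability_curve"
  )
}

#' @export
print.polarizability_curve <- function(x, ...) {
  cat(sprintf(
    "<polarizability_curve> %d points, max alpha'' %.3g, max |alpha'| %.3g\n",
    length(x$grid), max(x$alpha_imag), max(abs(x$alpha_real))
  ))
  invisible(x)
}
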