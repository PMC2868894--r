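#' Spectrum series over a mixing coordinate
#'
#' An ordered family of spectra on one wavelength grid, indexed by a
#' mixing coordinate (here the water mole fraction X_w of a binary solvent
#' mixture).  Isodichroic-point analysis is only meaningful at constant
#' solute molarity, so the constructor carries that flag.
#'
#' @param wavelengths common wavelength grid, nm
#' @param mixing strictly monotone vector of mixing coordinates in [0,1]
#' @param values numeric matrix, one column per member (rows =
#'   wavelengths)
#' @param concentration_constant logical; TRUE if all members are at the
#'   same solute molarity
#' @param unit ordinate unit tag
#' @return object of class `spectrum_series`
#' @export
spectrum_series <- function(wavelengths, mixing, values,
                            concentration_constant = TRUE,
                            unit = "elongation_mm") {
  values <- as.matrix(values)
  stopifnot(length(wavelengths) == nrow(values),
            length(mixing) == ncol(values),
            all(mixing >= 0), all(mixing <= 1))
  d <- diff(mixing)
  if (!(all(d > 0) || all(d < 0))) {
    stop("mixing coordinates must be strictly monotone")
  }
  o <- order(wavelengths)
  structure(
    list(wavelengths = wavelengths[o], mixing = mixing,
         values = values[o, , drop = FALSE],
         concentration_constant = isTRUE(concentration_constant),
         unit = unit),
    class = "spectrum_series"
  )
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf(
    "<spectrum_series> %d members (X = %.2f..%.2f), %d wavelengths %.0f..%.0f nm%s\n",
    length(x$mixing), min(x$mixing), max(x$mixing),
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    if (x$concentration_constant) ", constant concentration" else ""
  ))
  invisible(x)
}

#' Extrema of a spectrum
#'
#' Local maxima and minima surviving a moving-average smoothing and a
#' prominence threshold, with sub-grid placement by parabolic
#' interpolation through the three points around each extremum.
#'
#' @param spectrum [cd_spectrum()]
#' @param min_prominence minimum |value| (after smoothing) for an
#'   extremum to be reported; default 2% of the spectrum's max |value|
#' @param smooth_window moving-average window, odd, default 5
#' @return data.frame with columns `wavelength_nm`, `value`, `sign`
#'   (+1 maximum / -1 minimum of the signal)
#' @export
find_extrema <- function(spectrum, min_prominence = NULL, smooth_window = 5L) {
  y <- spectrum$value
  wl <- spectrum$wavelength_nm
  n <- length(y)
  if (n < 5L) stop("need at least 5 grid points")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window > n) stop("smoothing window larger than spectrum")
  if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
  ys <- if (smooth_window > 1L) {
    stats::filter(y, rep(1 / smooth_window, smooth_window), sides = 2)
  } else {
    y
  }
  ys <- as.numeric(ys)
  # pad the smoothed ends with the raw signal
  half <- smooth_window %/% 2L
  if (half > 0L) {
    ys[seq_len(half)] <- y[seq_len(half)]
    ys[(n - half + 1L):n] <- y[(n - half + 1L):n]
  }
  if (is.null(min_prominence)) min_prominence <- 0.02 * max(abs(ys))
  out <- list()
  for (k in 2L:(n - 1L)) {
    d1 <- ys[k] - ys[k - 1L]
    d2 <- ys[k + 1L] - ys[k]
    is_max <- d1 > 0 && d2 <= 0
    is_min <- d1 < 0 && d2 >= 0
    if ((is_max || is_min) && abs(ys[k]) > min_prominence) {
      # parabolic vertex through (k-1, k, k+1)
      denom <- ys[k - 1L] - 2 * ys[k] + ys[k + 1L]
      delta <- if (abs(denom) > 0) {
        0.5 * (ys[k - 1L] - ys[k + 1L]) / denom
      } else {
        0
      }
      delta <- max(min(delta, 1), -1)
      step <- if (delta >= 0) wl[min(k + 1L, n)] - wl[k] else wl[k] - wl[k - 1L]
      out[[length(out) + 1L]] <- data.frame(
        wavelength_nm = wl[k] + delta * abs(step) * sign(delta),
        value = ys[k] - 0.25 * (ys[k - 1L] - ys[k + 1L]) * delta,
        sign = if (is_max) 1 else -1
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(wavelength_nm = numeric(0), value = numeric(0),
                      sign = numeric(0)))
  }
  do.call(rbind, out)
}

#' Isodichroic points of a constant-concentration series
#'
#' Wavelengths at which all members of the series take (nearly) the same
#' value: the across-member range there is at most `agreement_tol` times
#' the largest across-member range anywhere.  Contiguous qualifying
#' wavelengths are merged and reported at their center of mass (weighted
#' by inverse range).  A series whose members are all identical is
#' degenerate (every wavelength would qualify) and returns an empty result
#' with a warning.
#'
#' @param series [spectrum_series()] with `concentration_constant` TRUE
#'   and at least 3 members
#' @param agreement_tol relative tolerance, default 0.02
#' @return numeric vector of wavelengths (nm), possibly empty
#' @export
find_isodichroic <- function(series, agreement_tol = 0.02) {
  stopifnot(inherits(series, "spectrum_series"))
  if (!series$concentration_constant) {
    stop("isodichroic analysis requires constant solute concentration")
  }
  if (length(series$mixing) < 3L) {
    stop("need at least 3 members for isodichroic detection")
  }
  rng <- apply(series$values, 1L, function(v) diff(range(v)))
  mx <- max(rng)
  scale <- max(abs(series$values))
  if (mx <= 1e-9 * scale) {
    warning("all members identical; isodichroic points are degenerate")
    return(numeric(0))
  }
  hit <- rng <= agreement_tol * mx
  if (!any(hit)) return(numeric(0))
  # merge contiguous runs
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  wl <- series$wavelengths
  out <- numeric(0)
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    w <- 1 / (rng[idx] + 1e-12 * mx)
    out <- c(out, sum(wl[idx] * w) / sum(w))
  }
  sort(out)
}

#' Elongation (or delta-epsilon) profile at one wavelength
#'
#' Signal of every member at the grid wavelength nearest the query, in
#' mixing-coordinate order.
#'
#' @param series [spectrum_series()]
#' @param wavelength_nm query wavelength, inside the grid range
#' @return data.frame with columns `mixing`, `value`
#' @export
elongation_profile <- function(series, wavelength_nm) {
  wl <- series$wavelengths
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl)) {
    stop(sprintf("wavelength %.1f nm outside series grid %.1f..%.1f",
                 wavelength_nm, min(wl), max(wl)))
  }
  k <- which.min(abs(wl - wavelength_nm))
  data.frame(mixing = series$mixing, value = series$values[k, ])
}

#' Classify an elongation profile
#'
#' A profile is `sign_inverting` when its extremes bracket zero beyond a
#' noise deadband, `sign_preserving` when it keeps one sign, and
#' `indeterminate` when it never leaves the deadband.
#'
#' @param profile data.frame from [elongation_profile()] (or any with a
#'   `value` column)
#' @param deadband absolute half-width of the zero band; default 2% of
#'   max |value|
#' @return one of `"sign_preserving"`, `"sign_inverting"`,
#'   `"indeterminate"`
#' @export
classify_profile <- function(profile, deadband = NULL) {
  v <- profile$value
  if (length(v) < 3L) stop("need at least 3 profile points")
  if (is.null(deadband)) deadband <- 0.02 * max(abs(v))
  lo <- min(v)
  hi <- max(v)
  if (hi <= deadband && lo >= -deadband) return("indeterminate")
  if (hi > deadband && lo < -deadband) return("sign_inverting")
  "sign_preserving"
}

#' Two-basis linear-combination test
#'
#' Fits every member of the series as \eqn{c_a A(\lambda) + c_b
#' B(\lambda)} by least squares and tests whether the residuals are
#' compatible with the stated noise level: the verdict is `"REJECT"` if
#' any member's residual RMS exceeds `rejection_factor * noise_sigma`
#' (with a machine-level floor so that noiseless round trips pass), else
#' `"CONSISTENT"`.  This is the test that decides whether a titration
#' family can be explained by two spectroscopic end states.
#'
#' @param series [spectrum_series()]
#' @param basis_a,basis_b [cd_spectrum()] on the series grid, linearly
#'   independent (angle >= 1 degree in function space)
#' @param noise_sigma known or estimated noise standard deviation of the
#'   member spectra (same unit as the series ordinate)
#' @param rejection_factor residual multiple that triggers rejection
#'   (default 3)
#' @param convex if TRUE, constrain c_a, c_b >= 0 and c_a + c_b = 1
#' @return list with `coefficients` (n_members x 2 matrix), `residual_rms`
#'   (per member), `verdict` (`"CONSISTENT"` or `"REJECT"`), `threshold`
#' @export
two_basis_fit <- function(series, basis_a, basis_b, noise_sigma,
                          rejection_factor = 3, convex = FALSE) {
  stopifnot(inherits(series, "spectrum_series"), noise_sigma >= 0)
  wl <- series$wavelengths
  if (!isTRUE(all.equal(basis_a$wavelength_nm, wl)) ||
      !isTRUE(all.equal(basis_b$wavelength_nm, wl))) {
    stop("bases must share the series wavelength grid")
  }
  a <- basis_a$value
  b <- basis_b$value
  cosang <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  if (cosang > cos(pi / 180)) {
    stop("basis spectra are collinear (angle < 1 degree); fit is ill-posed")
  }
  X <- cbind(a, b)
  n_mem <- ncol(series$values)
  coefs <- matrix(NA_real_, n_mem, 2L,
                  dimnames = list(NULL, c("c_a", "c_b")))
  rms <- numeric(n_mem)
  for (m in seq_len(n_mem)) {
    y <- series$values[, m]
    if (convex) {
      # 1-D problem in c_a on [0,1] with c_b = 1 - c_a
      d <- a - b
      ca <- sum((y - b) * d) / sum(d^2)
      ca <- min(max(ca, 0), 1)
      cf <- c(ca, 1 - ca)
    } else {
      cf <- stats::lm.fit(X, y)$coefficients
    }
    coefs[m, ] <- cf
    rms[m] <- sqrt(mean((y - X %*% cf)^2))
  }
  threshold <- max(rejection_factor * noise_sigma,
                   1e-8 * max(abs(series$values)))
  verdict <- if (any(rms > threshold)) "REJECT" else "CONSISTENT"
  list(coefficients = coefs, residual_rms = rms, verdict = verdict,
       threshold = threshold)
}
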