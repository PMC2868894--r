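#' CD (or absorption) spectrum container
#'
#' A spectrum is a sorted wavelength axis (nm) and an ordinate of equal
#' length: delta-epsilon in M^-1 cm^-1 for calculated CD, or any
#' documented unit (e.g. chart-recorder elongation in mm) for measured
#' data.  The unit is metadata and is never converted implicitly.
#'
#' @param wavelength_nm numeric vector, nm
#' @param values numeric vector, same length, finite
#' @param label free-text label
#' @param unit ordinate unit tag (default `"delta_epsilon"`)
#' @param solvent optional solvent tag
#' @return object of class `cd_spectrum` (a data.frame with columns
#'   `wavelength_nm`, `value` plus attributes)
#' @export
cd_spectrum <- function(wavelength_nm, values, label = "",
                        unit = "delta_epsilon", solvent = NULL) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(values),
            length(wavelength_nm) == length(values))
  if (!all(is.finite(wavelength_nm)) || !all(is.finite(values))) {
    stop("spectrum contains non-finite values")
  }
  o <- order(wavelength_nm)
  sorted_flag <- !identical(o, seq_along(wavelength_nm))
  out <- data.frame(wavelength_nm = wavelength_nm[o], value = values[o])
  structure(out,
            class = c("cd_spectrum", "data.frame"),
            label = label, unit = unit, solvent = solvent,
            resorted = sorted_flag)
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf(
    "<cd_spectrum> '%s' [%s]: %d points, %.1f..%.1f nm, range %.3g..%.3g\n",
    attr(x, "label"), attr(x, "unit"), nrow(x),
    min(x$wavelength_nm), max(x$wavelength_nm),
    min(x$value), max(x$value)
  ))
  invisible(x)
}

#' @export
plot.cd_spectrum <- function(x, ...) {
  plot(x$wavelength_nm, x$value, type = "l",
       xlab = "wavelength (nm)", ylab = attr(x, "unit"),
       main = attr(x, "label"), ...)
  abline(h = 0, col = "grey70")
  invisible(x)
}

#' Value of a spectrum at (nearest grid point to) a wavelength
#'
#' @param spectrum [cd_spectrum()]
#' @param wavelength_nm query wavelength; must lie within the grid range
#' @keywords internal
spectrum_value_at <- function(spectrum, wavelength_nm) {
  wl <- spectrum$wavelength_nm
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl)) {
    stop(sprintf("wavelength %.1f nm outside spectrum range %.1f..%.1f nm",
                 wavelength_nm, min(wl), max(wl)))
  }
  spectrum$value[which.min(abs(wl - wavelength_nm))]
}
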