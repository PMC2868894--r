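#' Spectrum and assembly file I/O
#'
#' Spectra travel as two-column CSV (`wavelength_nm,value`, with `#`
#' header comments carrying unit/label/solvent metadata) or as minimal
#' JCAMP-DX (`XYDATA=(XY..XY)` form only).  Assemblies and band sets are
#' JSON.  Wavelengths in files are always nm; wavenumbers are internal
#' only.
#'
#' @name cli_io
NULL

#' Write a spectrum
#'
#' @param spectrum [cd_spectrum()]
#' @param path output file
#' @param dialect `"csv_two_column"` or `"jcamp_dx"`
#' @export
write_spectrum <- function(spectrum, path,
                           dialect = c("csv_two_column", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv_two_column") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# label: %s", attr(spectrum, "label")),
      sprintf("# unit: %s", attr(spectrum, "unit")),
      if (!is.null(attr(spectrum, "solvent"))) {
        sprintf("# solvent: %s", attr(spectrum, "solvent"))
      },
      "wavelength_nm,value"
    ), con)
    # %.17g guarantees an exact double round trip
    writeLines(sprintf("%.17g,%.17g", spectrum$wavelength_nm,
                       spectrum$value), con)
  } else {
    lines <- c(
      sprintf("##TITLE=%s", attr(spectrum, "label")),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=CIRCULAR DICHROISM",
      "##XUNITS=NANOMETERS",
      sprintf("##YUNITS=%s", toupper(attr(spectrum, "unit"))),
      sprintf("##NPOINTS=%d", nrow(spectrum)),
      "##XYDATA=(XY..XY)",
      sprintf("%.6f, %.8g", spectrum$wavelength_nm, spectrum$value),
      "##END="
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a spectrum
#'
#' CSV round-trips bit-identically with [write_spectrum()].  Descending
#' wavelength axes are sorted ascending on read and flagged in the
#' `resorted` attribute.
#'
#' @param path input file
#' @param dialect `"csv_two_column"` or `"jcamp_dx"`
#' @return [cd_spectrum()]
#' @export
read_spectrum <- function(path, dialect = c("csv_two_column", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty spectrum file: ", path)
  if (dialect == "csv_two_column") {
    read_spectrum_csv(lines, path)
  } else {
    read_spectrum_jcamp(lines, path)
  }
}

read_spectrum_csv <- function(lines, path) {
  meta <- list(label = "", unit = NULL, solvent = NULL)
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(\\w+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no data rows in ", path)
  if (grepl("wavelength", body[1L], ignore.case = TRUE)) body <- body[-1L]
  if (length(body) == 0L) stop("no data rows in ", path)
  parts <- strsplit(body, ",")
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at data line %d of %s: '%s'",
                 bad[1L], path, body[bad[1L]]))
  }
  wl <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(wl) || anyNA(v)) {
    bad <- which(is.na(wl) | is.na(v))[1L]
    stop(sprintf("non-numeric value at data line %d of %s", bad, path))
  }
  if (is.null(meta$unit)) {
    warning("no unit in header of ", path, "; assuming delta_epsilon")
    meta$unit <- "delta_epsilon"
  }
  cd_spectrum(wl, v, label = meta$label, unit = meta$unit,
              solvent = meta$solvent)
}

read_spectrum_jcamp <- function(lines, path) {
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^##", key, "="), "", hit[1L])
  }
  start <- grep("^##XYDATA", lines)
  if (length(start) != 1L) {
    stop("not a minimal XYDATA JCAMP-DX file: ", path)
  }
  endl <- grep("^##END", lines)
  endl <- if (length(endl) > 0L) min(endl[endl > start]) else length(lines) + 1L
  body <- if (endl - 1L >= start + 1L) lines[(start + 1L):(endl - 1L)] else character(0)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no XY data in ", path)
  parts <- strsplit(trimws(body), "[,;[:space:]]+")
  xy <- lapply(parts, as.numeric)
  if (any(vapply(xy, function(p) length(p) < 2L || anyNA(p), TRUE))) {
    stop("malformed XY row in ", path)
  }
  wl <- vapply(xy, `[[`, 0, 1L)
  v <- vapply(xy, `[[`, 0, 2L)
  unit <- get_field("YUNITS") %||% "delta_epsilon"
  cd_spectrum(wl, v, label = get_field("TITLE") %||% "",
              unit = tolower(unit))
}

#' Write an assembly to JSON
#'
#' @param assembly [oscillator_assembly()]
#' @param path output file
#' @export
write_assembly <- function(assembly, path) {
  obj <- list(
    schema = "devoecd/assembly/1",
    name = assembly$name,
    bands = lapply(assembly$bands, function(b) {
      list(center_nm = b$center_nm, eps_max = b$eps_max,
           fwhm_cm = b$fwhm_cm, shape = b$shape)
    }),
    oscillators = lapply(seq_len(nrow(assembly$positions)), function(i) {
      list(position = assembly$positions[i, ],
           orientation = assembly$orientations[i, ],
           band = assembly$band_index[i])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an assembly from JSON
#'
#' Validates the schema field by field: band references must be in range,
#' orientations must be unit vectors within 1e-6 (they are renormalized),
#' unknown top-level keys are rejected.
#'
#' @param path JSON file written by [write_assembly()] or by hand
#' @return [oscillator_assembly()]
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  allowed <- c("schema", "name", "bands", "oscillators")
  extra <- setdiff(names(obj), allowed)
  if (length(extra) > 0L) {
    stop("unknown key(s) in assembly file: ", paste(extra, collapse = ", "))
  }
  if (is.null(obj$bands) || length(obj$bands) == 0L) {
    stop("assembly config error: field 'bands' missing or empty")
  }
  if (is.null(obj$oscillators) || length(obj$oscillators) == 0L) {
    stop("assembly config error: field 'oscillators' missing or empty")
  }
  bands <- lapply(obj$bands, function(b) {
    need <- c("center_nm", "eps_max", "fwhm_cm")
    miss <- setdiff(need, names(b))
    if (length(miss) > 0L) {
      stop("assembly config error: band missing field(s) ",
           paste(miss, collapse = ", "))
    }
    transition_band(b$center_nm, b$eps_max, b$fwhm_cm,
                    b$shape %||% "gaussian")
  })
  pos <- t(vapply(obj$oscillators, function(o) {
    if (is.null(o$position) || length(o$position) != 3L) {
      stop("assembly config error: oscillator field 'position' must be a 3-vector")
    }
    as.numeric(unlist(o$position))
  }, numeric(3L)))
  ori <- t(vapply(obj$oscillators, function(o) {
    if (is.null(o$orientation) || length(o$orientation) != 3L) {
      stop("assembly config error: oscillator field 'orientation' must be a 3-vector")
    }
    as.numeric(unlist(o$orientation))
  }, numeric(3L)))
  idx <- vapply(obj$oscillators, function(o) {
    if (is.null(o$band)) {
      stop("assembly config error: oscillator field 'band' missing")
    }
    as.integer(o$band)
  }, integer(1L))
  nrm <- sqrt(rowSums(ori^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    bad <- which(abs(nrm - 1) > 1e-6)[1L]
    stop(sprintf(
      "assembly config error: field 'orientation' of oscillator %d has norm %.4g (must be unit within 1e-6)",
      bad, nrm[bad]
    ))
  }
  if (any(idx < 1L | idx > length(bands))) {
    stop("assembly config error: field 'band' out of range 1..", length(bands))
  }
  oscillator_assembly(bands, pos, ori, idx,
                      name = obj$name %||% "assembly")
}

#' Write a spectrum series as CSV
#'
#' Wide table: first column `wavelength_nm`, one column `X_<mixing>` per
#' member.
#'
#' @param series [spectrum_series()]
#' @param path output file
#' @export
write_series <- function(series, path) {
  df <- data.frame(wavelength_nm = series$wavelengths,
                   series$values, check.names = FALSE)
  names(df)[-1L] <- sprintf("X_%g", series$mixing)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum series from CSV written by [write_series()]
#'
#' @param path input file
#' @param concentration_constant flag to attach (not stored in the CSV)
#' @export
read_series <- function(path, concentration_constant = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "wavelength_nm" || ncol(df) < 2L) {
    stop("not a series table (need wavelength_nm + member columns): ", path)
  }
  mixing <- as.numeric(sub("^X_", "", names(df)[-1L]))
  if (anyNA(mixing)) stop("member columns must be named X_<mole fraction>")
  spectrum_series(df[[1L]], mixing, as.matrix(df[, -1L, drop = FALSE]),
                  concentration_constant = concentration_constant)
}
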