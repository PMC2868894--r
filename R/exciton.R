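#' First-order exciton expressions
#'
#' Truncating the coupled response \eqn{A = B^{-1}} at first order in the
#' dipole-dipole coupling gives \eqn{A_{ij} \approx -\alpha_i G_{ij}
#' \alpha_j} for \eqn{i \ne j}.  Two classic limits follow:
#' \itemize{
#'   \item the degenerate couplet: two identical chromophores sharing one
#'     transition give \eqn{\Delta\epsilon \propto \nu^2\,
#'     \alpha'(\nu)\alpha''(\nu)\, G_{12}\, [R_{12}\cdot(e_1\times e_2)]},
#'     a bisignate band changing sign at the absorption maximum;
#'   \item the non-degenerate cross term: a second, non-overlapping
#'     transition contributes \eqn{\propto \nu^2 \alpha_1''(\nu)
#'     \alpha_2'(\nu)} in the band-1 region, positive (for positive
#'     geometric factor) when band 2 lies at shorter wavelength than band 1
#'     and negative when at longer wavelength, because \eqn{\alpha_2'}
#'     changes sign across its own band center.
#' }
#' Both operations are implemented as literal first-order truncations of
#' the full engine, so all convention constants are shared and full/first-
#' order comparisons are meaningful.
#'
#' @name exciton_firstorder
NULL

#' Degenerate exciton couplet, first order in the coupling
#'
#' @param assembly [oscillator_assembly()] with exactly two oscillators
#'   referring to the same band
#' @inheritParams devoe_cd
#' @return object of class `couplet_result`: list with `spectrum`
#'   ([cd_spectrum()]), `geometric_factor` (triple product
#'   \eqn{R_{12}\cdot(e_1\times e_2)}, Angstrom), `coupling` (G12, cm^-3)
#'   and `crossing_nm` (sign-change wavelength of the couplet, NA if none)
#' @export
couplet_firstorder <- function(assembly, grid = grid_for_bands(assembly$bands),
                               constants = devoe_constants(),
                               polarizabilities = NULL, kk_mode = "causal") {
  stopifnot(inherits(assembly, "oscillator_assembly"))
  if (n_oscillators(assembly) != 2L) {
    stop("couplet_firstorder needs exactly two oscillators")
  }
  if (assembly$band_index[1L] != assembly$band_index[2L]) {
    stop("oscillators refer to different bands; use nondegenerate_term")
  }
  polar <- polarizabilities %||%
    assembly_polarizabilities(assembly, grid, constants, kk_mode)
  p <- polar[[assembly$band_index[1L]]]
  cp <- assembly_coupling(assembly, constants$coupling_constant)
  g12 <- cp$G[1L, 2L]
  tp <- cp$triple[1L, 2L] # cm
  nu <- as.numeric(grid)
  # Im(A_12^(1)) = Im(-alpha^2 G12) = -2 alpha' alpha'' G12
  im_a12 <- -2 * p$alpha_real * p$alpha_imag * g12
  de <- constants$cd_constant * nu^2 * im_a12 * tp
  spec <- cd_spectrum(wavenumber_to_nm(nu), de, label = assembly$name)
  structure(
    list(spectrum = spec,
         geometric_factor = tp / .ANGSTROM_CM,
         coupling = g12,
         crossing_nm = sign_crossing_nm(spec)),
    class = "couplet_result"
  )
}

#' @export
print.couplet_result <- function(x, ...) {
  cat(sprintf(
    "<couplet_result> geometric factor %.4g A, G12 %.4g cm^-3, crossing %.1f nm\n",
    x$geometric_factor, x$coupling, x$crossing_nm
  ))
  invisible(x)
}

# wavelength of the sign change nearest the largest |value|; NA if none
sign_crossing_nm <- function(spec) {
  v <- spec$value
  wl <- spec$wavelength_nm
  s <- which(v[-1L] * v[-length(v)] < 0)
  if (length(s) == 0L) return(NA_real_)
  # linear interpolation at each crossing; pick the one flanked by the
  # largest amplitudes (the couplet node, not noise crossings)
  amp <- pmin(abs(v[s]), abs(v[s + 1L]))
  k <- s[which.max(amp)]
  wl[k] + (wl[k + 1L] - wl[k]) * abs(v[k]) / (abs(v[k]) + abs(v[k + 1L]))
}

#' Non-degenerate first-order cross term
#'
#' CD contribution in the region of band 1 from coupling to a second,
#' non-overlapping transition on the other moiety.  Bands must be
#' separated by at least three times the sum of their half-widths.
#'
#' @param band1,band2 [transition_band()]; band 1 hosts the reported CD
#' @param geometry list with `r_vec` (Angstrom, from oscillator 1 to 2)
#'   and unit orientations `e1`, `e2`; or an
#'   [oscillator_assembly()] with two oscillators where oscillator 1
#'   carries band 1
#' @inheritParams devoe_cd
#' @return [cd_spectrum()] of the cross-term contribution on `grid`
#' @export
nondegenerate_term <- function(band1, band2, geometry,
                               grid = grid_for_bands(list(band1, band2)),
                               constants = devoe_constants(),
                               kk_mode = "causal") {
  if (inherits(geometry, "oscillator_assembly")) {
    asm <- geometry
  } else {
    asm <- oscillator_assembly(
      bands = list(band1, band2),
      positions = rbind(c(0, 0, 0), geometry$r_vec),
      orientations = rbind(geometry$e1, geometry$e2),
      band_index = c(1L, 2L),
      name = "nondegenerate_pair"
    )
  }
  sep <- abs(band1$center_wavenumber - band2$center_wavenumber)
  halfsum <- (band1$fwhm_cm + band2$fwhm_cm) / 2
  if (sep < 3 * halfsum) {
    stop(sprintf(
      "bands overlap (separation %.0f cm^-1 < 3 x summed half-widths %.0f); the non-degenerate expansion does not apply",
      sep, 3 * halfsum
    ))
  }
  polar <- assembly_polarizabilities(asm, grid, constants, kk_mode)
  p1 <- polar[[asm$band_index[1L]]]
  p2 <- polar[[asm$band_index[2L]]]
  cp <- assembly_coupling(asm, constants$coupling_constant)
  g12 <- cp$G[1L, 2L]
  tp <- cp$triple[1L, 2L]
  nu <- as.numeric(grid)
  # Im(A_12^(1)) = -G12 (alpha1' alpha2'' + alpha1'' alpha2')
  im_a12 <- -g12 * (p1$alpha_real * p2$alpha_imag +
                      p1$alpha_imag * p2$alpha_real)
  de <- constants$cd_constant * nu^2 * im_a12 * tp
  cd_spectrum(wavenumber_to_nm(nu), de,
              label = paste0(asm$name, "_crossterm"))
}

#' Geometric factor of a two-oscillator arrangement
#'
#' The signed pseudoscalar that multiplies both first-order expressions:
#' \eqn{-\kappa\,[e_1\cdot e_2 - 3(e_1\cdot\hat R)(e_2\cdot\hat R)]
#' [R_{12}\cdot(e_1\times e_2)] / |R|^3} (units of G times Angstrom).  Its
#' sign fixes the sign of the couplet's long-wavelength branch and of the
#' non-degenerate term's short-wavelength rule.
#'
#' @inheritParams couplet_firstorder
#' @export
pair_geometric_factor <- function(assembly,
                                  constants = devoe_constants()) {
  cp <- assembly_coupling(assembly, constants$coupling_constant)
  -cp$G[1L, 2L] * cp$triple[1L, 2L] / .ANGSTROM_CM
}

#' Full-model vs first-order deviation
#'
#' Maximum pointwise deviation between the all-order CD and its
#' first-order truncation for a degenerate pair, normalized by the peak
#' amplitude of the full spectrum.  The dipole strength of the shared band
#' is scaled by `strength_scale` before comparing; the deviation is
#' O(|G alpha|^2), so it shrinks at least linearly (in fact quadratically)
#' as the strength is scaled down.
#'
#' @inheritParams couplet_firstorder
#' @param strength_scale multiplier applied to the band's eps_max
#' @return list with `deviation` (dimensionless), `max_g_alpha`
#'   (max |G12 alpha| over the grid, the expansion parameter)
#' @export
compare_full_vs_firstorder <- function(assembly,
                                       grid = grid_for_bands(assembly$bands),
                                       constants = devoe_constants(),
                                       strength_scale = 1,
                                       kk_mode = "causal") {
  if (n_oscillators(assembly) != 2L ||
      assembly$band_index[1L] != assembly$band_index[2L]) {
    stop("comparison defined for two identical oscillators")
  }
  b <- assembly$bands[[assembly$band_index[1L]]]
  bs <- transition_band(b$center_nm, b$eps_max * strength_scale,
                        b$fwhm_cm, b$shape)
  asm <- oscillator_assembly(list(bs), assembly$positions,
                             assembly$orientations,
                             rep(1L, 2L), assembly$name)
  polar <- assembly_polarizabilities(asm, grid, constants, kk_mode)
  full <- devoe_cd(asm, grid, constants, polarizabilities = polar)
  fo <- couplet_firstorder(asm, grid, constants,
                           polarizabilities = polar)$spectrum
  peak <- max(abs(full$value))
  cp <- assembly_coupling(asm, constants$coupling_constant)
  p <- polar[[1L]]
  mga <- max(Mod(complex(real = p$alpha_real, imaginary = p$alpha_imag))) *
    abs(cp$G[1L, 2L])
  if (peak == 0) {
    return(list(deviation = 0, max_g_alpha = mga))
  }
  list(deviation = max(abs(full$value - fo$value)) / peak,
       max_g_alpha = mga)
}
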