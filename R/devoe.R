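#' All-order coupled-oscillator (DeVoe) engine
#'
#' The molecule is a set of coupled classical oscillators.  At each
#' wavenumber the interaction matrix
#' \deqn{B_{ij} = \delta_{ij}/\alpha_i(\nu) + G_{ij}}
#' is inverted to give the coupled response \eqn{A = B^{-1}}, from which
#' \deqn{\Delta\epsilon(\nu) = c_{CD}\, \nu^2 \sum_{i<j}
#'   \mathrm{Im}\,A_{ij}(\nu)\; [R_{ij} \cdot (e_i \times e_j)]}
#' and
#' \deqn{\epsilon(\nu) = c_{abs}\, \nu \sum_{ij}
#'   \mathrm{Im}\,A_{ij}(\nu)\; (e_i \cdot e_j).}
#' The inversion is repeated at every grid point because the
#' polarizabilities are frequency dependent.  In the decoupled limit
#' (G = 0) the absorption reduces exactly to the sum of the input bands,
#' and a single oscillator or any coplanar pair gives identically zero CD.
#'
#' @name devoe_engine
NULL

# drop oscillators whose band carries no intensity (their polarizability
# is identically zero, so they are spectroscopically inert but would make
# 1/alpha singular); returns NULL if nothing is left
active_assembly <- function(assembly) {
  strength <- vapply(assembly$bands, function(b) b$eps_max, 0)
  keep <- strength[assembly$band_index] > 0
  if (!any(keep)) return(NULL)
  if (all(keep)) return(assembly)
  oscillator_assembly(
    bands = assembly$bands,
    positions = assembly$positions[keep, , drop = FALSE],
    orientations = assembly$orientations[keep, , drop = FALSE],
    band_index = assembly$band_index[keep],
    name = assembly$name
  )
}

# per-band complex polarizability curves for an assembly
assembly_polarizabilities <- function(assembly, grid,
                                      constants = devoe_constants(),
                                      mode = "causal") {
  lapply(assembly$bands, transition_polarizability, grid = grid,
         conversion_constant = constants$alpha_conversion, mode = mode)
}

#' Interaction matrix at one wavenumber
#'
#' Builds the complex symmetric matrix B with `1/alpha_i(nu)` on the
#' diagonal and `G_ij` off it.  Frequency points at which any
#' `|alpha_i(nu)|` falls below `alpha_floor` times that band's maximum are
#' signalled (the engine skips and interpolates over them); a condition
#' number above `cond_max` is an error.
#'
#' @param alpha complex vector, per-oscillator polarizability at this nu
#' @param G real symmetric coupling matrix, cm^-3
#' @param alpha_floor relative floor for |alpha| (default 1e-12)
#' @param alpha_scale per-oscillator maxima of |alpha| used for the floor;
#'   when omitted (0) the floor check is skipped
#' @return complex matrix B
#' @export
build_interaction_matrix <- function(alpha, G,
                                     alpha_floor = 1e-12,
                                     alpha_scale = 0) {
  n <- length(alpha)
  stopifnot(nrow(G) == n, ncol(G) == n)
  if (any(Mod(alpha) < alpha_floor * alpha_scale)) {
    stop(structure(
      class = c("devoe_skip_point", "error", "condition"),
      list(message = "polarizability below floor at this frequency",
           call = NULL)
    ))
  }
  B <- G + 0i
  diag(B) <- 1 / alpha
  B
}

# invert B with a condition check
invert_B <- function(B, cond_max = 1e12) {
  A <- tryCatch(solve(B), error = function(e) {
    stop("interaction matrix numerically singular: ", conditionMessage(e))
  })
  # cheap 1-norm condition estimate
  kap <- norm(as.matrix(Mod(B)), "1") * norm(as.matrix(Mod(A)), "1")
  if (!is.finite(kap) || kap > cond_max) {
    stop(sprintf("interaction matrix ill-conditioned (kappa ~ %.2g)", kap))
  }
  A
}

# core loop shared by devoe_cd and devoe_abs: returns per-frequency
# Im(A_ij) contracted with a weight matrix W (same shape as A)
devoe_sum <- function(assembly, polar, grid, W, constants, pairs_only) {
  nu <- as.numeric(grid)
  n <- n_oscillators(assembly)
  alpha_mat <- vapply(
    assembly$band_index,
    function(bi) complex(real = polar[[bi]]$alpha_real,
                         imaginary = polar[[bi]]$alpha_imag),
    complex(length(nu))
  )
  alpha_mat <- matrix(alpha_mat, nrow = length(nu))
  alpha_scale <- apply(Mod(alpha_mat), 2L, max)
  out <- rep(NA_real_, length(nu))
  for (k in seq_along(nu)) {
    res <- tryCatch({
      B <- build_interaction_matrix(alpha_mat[k, ], W$G,
                                    alpha_scale = alpha_scale)
      A <- invert_B(B)
      ImA <- Im(A)
      if (pairs_only) {
        s <- sum(ImA[upper.tri(ImA)] * W$M[upper.tri(W$M)])
      } else {
        s <- sum(ImA * W$M)
      }
      s
    }, devoe_skip_point = function(e) NA_real_)
    out[k] <- res
  }
  if (all(is.na(out))) stop("all frequency points skipped; empty spectrum")
  # interpolate over skipped points
  if (anyNA(out)) {
    ok <- !is.na(out)
    out <- stats::approx(nu[ok], out[ok], xout = nu, rule = 2)$y
  }
  out
}

#' Coupled-oscillator CD spectrum
#'
#' @param assembly [oscillator_assembly()]
#' @param grid [frequency_grid()]; defaults to [grid_for_bands()] of the
#'   assembly's bands
#' @param constants convention constants, see [devoe_constants()]
#' @param polarizabilities optional precomputed list of
#'   [polarizability_curve()] per band (recomputed if `NULL`)
#' @param kk_mode Kramers-Kronig convention, see [kk_real_from_imag()]
#' @return [cd_spectrum()] with delta-epsilon in M^-1 cm^-1, reported on
#'   the wavelength axis (ascending nm)
#' @examples
#' asm <- make_twisted_pair(30, 10, transition_band(350, 1e4, 2000))
#' cd <- devoe_cd(asm)
#' @export
devoe_cd <- function(assembly, grid = grid_for_bands(assembly$bands),
                     constants = devoe_constants(),
                     polarizabilities = NULL, kk_mode = "causal") {
  stopifnot(inherits(assembly, "oscillator_assembly"))
  nu <- as.numeric(grid)
  assembly <- active_assembly(assembly)
  if (is.null(assembly)) {
    return(cd_spectrum(wavenumber_to_nm(nu), numeric(length(nu)),
                       label = "empty"))
  }
  polar <- polarizabilities %||%
    assembly_polarizabilities(assembly, grid, constants, kk_mode)
  cp <- assembly_coupling(assembly, constants$coupling_constant)
  s <- devoe_sum(assembly, polar, grid,
                 W = list(G = cp$G, M = cp$triple),
                 constants = constants, pairs_only = TRUE)
  de <- constants$cd_constant * nu^2 * s
  cd_spectrum(wavenumber_to_nm(nu), de, label = assembly$name)
}

#' Coupled-oscillator absorption spectrum
#'
#' Companion observable to [devoe_cd()]; in the decoupled limit it
#' reproduces the summed input bands exactly.
#'
#' @inheritParams devoe_cd
#' @return [cd_spectrum()] with unit `"epsilon"` (M^-1 cm^-1)
#' @export
devoe_abs <- function(assembly, grid = grid_for_bands(assembly$bands),
                      constants = devoe_constants(),
                      polarizabilities = NULL, kk_mode = "causal") {
  stopifnot(inherits(assembly, "oscillator_assembly"))
  nu <- as.numeric(grid)
  assembly <- active_assembly(assembly)
  if (is.null(assembly)) {
    return(cd_spectrum(wavenumber_to_nm(nu), numeric(length(nu)),
                       label = "empty", unit = "epsilon"))
  }
  polar <- polarizabilities %||%
    assembly_polarizabilities(assembly, grid, constants, kk_mode)
  cp <- assembly_coupling(assembly, constants$coupling_constant)
  E <- assembly$orientations %*% t(assembly$orientations) # e_i . e_j
  s <- devoe_sum(assembly, polar, grid,
                 W = list(G = cp$G, M = E),
                 constants = constants, pairs_only = FALSE)
  eps <- constants$abs_constant * nu * s
  cd_spectrum(wavenumber_to_nm(nu), eps, label = assembly$name,
              unit = "epsilon")
}

#' Conservative-couplet diagnostic
#'
#' Computes \eqn{\int \Delta\epsilon(\nu)/\nu\, d\nu} over the spectrum
#' (proportional to the net rotational strength, which vanishes for
#' coupled electric-dipole oscillators) and the same integral over the
#' positive branch alone; returns both and their ratio.
#'
#' @param cd [cd_spectrum()] produced by [devoe_cd()]
#' @return list with `net`, `positive_branch`, `ratio`
#' @export
rotational_strength_balance <- function(cd) {
  nu <- rev(nm_to_wavenumber(cd$wavelength_nm)) # ascending nu
  de <- rev(cd$value)
  f <- de / nu
  net <- trapz(nu, f)
  pos <- trapz(nu, pmax(f, 0))
  if (pos == 0) {
    return(list(net = net, positive_branch = 0, ratio = 0))
  }
  list(net = net, positive_branch = pos, ratio = abs(net) / abs(pos))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
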