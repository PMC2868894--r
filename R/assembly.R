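#' Assembly of placed point-dipole oscillators
#'
#' A multichromophoric molecule is represented as a set of transition
#' bands and a set of placed, oriented unit point-dipoles, each referring
#' to one band.  Positions are in Angstrom in a right-handed Cartesian
#' frame; orientations are unit vectors.
#'
#' @param bands list of [transition_band()] (or a single band)
#' @param positions numeric matrix, one row per oscillator, columns x,y,z
#'   in Angstrom
#' @param orientations numeric matrix, same shape; each row a unit vector
#'   (renormalized if within 1e-6 of unit length, rejected otherwise)
#' @param band_index integer vector mapping each oscillator to a band
#' @param name label for the assembly
#' @return object of class `oscillator_assembly`
#' @examples
#' b <- transition_band(350, 1e4, 2000)
#' oscillator_assembly(
#'   bands = list(b),
#'   positions = rbind(c(0, 0, 0), c(0, 0, 14.5)),
#'   orientations = rbind(c(1, 0, 0), c(cos(pi / 6), sin(pi / 6), 0)),
#'   band_index = c(1, 1)
#' )
#' @export
oscillator_assembly <- function(bands, positions, orientations, band_index,
                                name = "assembly") {
  bands <- as_band_list(bands)
  positions <- rbind(positions)
  orientations <- rbind(orientations)
  n <- nrow(positions)
  stopifnot(n >= 1L, ncol(positions) == 3L,
            nrow(orientations) == n, ncol(orientations) == 3L,
            length(band_index) == n)
  band_index <- as.integer(band_index)
  if (any(band_index < 1L) || any(band_index > length(bands))) {
    stop("band_index out of range 1..", length(bands))
  }
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    bad <- which(abs(nrm - 1) > 1e-6)[1L]
    stop(sprintf("orientation %d has norm %.6g; must be unit within 1e-6",
                 bad, nrm[bad]))
  }
  orientations <- orientations / nrm
  if (n > 1L) {
    dmin <- min(stats::dist(positions))
    if (dmin <= 0.1) {
      stop(sprintf("oscillators closer than 0.1 Angstrom (min distance %.3g)", dmin))
    }
  }
  structure(
    list(bands = bands, positions = unname(positions),
         orientations = unname(orientations),
         band_index = band_index, name = name),
    class = "oscillator_assembly"
  )
}

#' @export
print.oscillator_assembly <- function(x, ...) {
  cat(sprintf("<oscillator_assembly> '%s': %d oscillators, %d bands\n",
              x$name, nrow(x$positions), length(x$bands)))
  invisible(x)
}

n_oscillators <- function(assembly) nrow(assembly$positions)

#' Pair geometry of two placed oscillators
#'
#' Separation vector, distance and unit direction from oscillator i to
#' oscillator j.  Antisymmetric: swapping i and j negates the vector.
#'
#' @param assembly [oscillator_assembly()]
#' @param i,j oscillator indices
#' @return list with `r_vec` (Angstrom), `distance` (Angstrom), `unit`
#' @export
pair_geometry <- function(assembly, i, j) {
  stopifnot(inherits(assembly, "oscillator_assembly"))
  r <- assembly$positions[j, ] - assembly$positions[i, ]
  d <- sqrt(sum(r^2))
  if (d == 0) stop("coincident oscillator positions")
  list(r_vec = r, distance = d, unit = r / d)
}

#' Point-dipole interaction energy
#'
#' \eqn{G_{ij} = \kappa\,[e_i \cdot e_j - 3 (e_i \cdot \hat R)(e_j \cdot
#' \hat R)] / |R_{ij}|^3}, the interaction between two unit point-dipoles.
#' Symmetric in i,j and decaying as 1/R^3.  With the default cgs
#' convention, R is converted from Angstrom to cm so that G has the unit
#' cm^-3 of an inverse polarizability volume.
#'
#' @param e_i,e_j unit orientation vectors
#' @param r_vec separation vector, Angstrom
#' @param coupling_constant overall factor kappa (default 1, cgs)
#' @return scalar G_ij in cm^-3
#' @export
interaction_energy <- function(e_i, e_j, r_vec,
                               coupling_constant = devoe_constants()$coupling_constant) {
  d <- sqrt(sum(r_vec^2))
  if (d == 0) stop("zero separation between oscillators")
  rhat <- r_vec / d
  ang <- sum(e_i * e_j) - 3 * sum(e_i * rhat) * sum(e_j * rhat)
  coupling_constant * ang / (d * .ANGSTROM_CM)^3
}

# full G matrix (cm^-3) and pseudoscalar triple products R_ij.(e_i x e_j)
# (cm) for an assembly; both symmetric/antisymmetric as appropriate
assembly_coupling <- function(assembly,
                              coupling_constant = devoe_constants()$coupling_constant) {
  n <- n_oscillators(assembly)
  G <- matrix(0, n, n)
  Tm <- matrix(0, n, n) # triple products, antisymmetric
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pg <- pair_geometry(assembly, i, j)
        ei <- assembly$orientations[i, ]
        ej <- assembly$orientations[j, ]
        G[i, j] <- G[j, i] <- interaction_energy(ei, ej, pg$r_vec,
                                                 coupling_constant)
        tp <- sum(pg$r_vec * cross3(ei, ej)) * .ANGSTROM_CM
        Tm[i, j] <- tp
        Tm[j, i] <- -tp
      }
    }
  }
  list(G = G, triple = Tm)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Mirror image of an assembly
#'
#' Reflects positions and orientations through the plane with the given
#' normal (default xy-plane).  CD of the mirrored assembly is the pointwise
#' negative of the original; absorption is unchanged.
#'
#' @param assembly [oscillator_assembly()]
#' @param normal reflection-plane normal (default z)
#' @export
reflect_assembly <- function(assembly, normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  refl <- function(m) m - 2 * (m %*% normal) %*% t(normal)
  oscillator_assembly(
    bands = assembly$bands,
    positions = refl(assembly$positions),
    orientations = refl(assembly$orientations),
    band_index = assembly$band_index,
    name = paste0(assembly$name, "_mirror")
  )
}
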