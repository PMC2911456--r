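# Component geometry: polar coordinates -> vectors, ideal bond lengths and
# ideal inter-component angles, and the geometric compatibility test that
# gates bimolecular reactions.

#' Convert a polar component definition to a Cartesian vector
#'
#' Components are placed relative to the center of their elementary molecule
#' by a length `d` and two polar angles: `theta` is measured from the +z pole,
#' `phi` from +x in the equatorial plane.
#'
#' @param d component length (\eqn{\ge 0}).
#' @param theta polar angle in radians, in `[0, pi]`.
#' @param phi azimuth in radians, in `[0, 2*pi)`.
#' @return numeric 3-vector of length `d`.
#' @export
component_vector <- function(d, theta, phi) {
  stopifnot(d >= 0)
  c(d * sin(theta) * cos(phi), d * sin(theta) * sin(phi), d * cos(theta))
}

#' Ideal angle between two components of one species
#'
#' The angle that two component vectors of a single elementary molecule span;
#' it is not specified in the input but derived from the polar coordinates,
#' and serves as the rest angle of the harmonic angular force and as the
#' reference for the angular tolerance test.
#'
#' @param species a species definition (as found in a compiled system's
#'   `species` list, or any list with a `cvec` 3 x ncomp matrix).
#' @param comp_j,comp_k component indices (`comp_j != comp_k`).
#' @return angle in radians in `[0, pi]`.
#' @export
ideal_angle <- function(species, comp_j, comp_k) {
  stopifnot(comp_j != comp_k)
  u <- species$cvec[, comp_j]
  v <- species$cvec[, comp_k]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("ideal_angle: zero-length component vector; angle undefined")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Ideal bond length of a component pair
#'
#' A bond is the straight connection of the two component vectors, so its
#' rest length is the sum of the two component lengths.
#'
#' @param d_a,d_b component lengths.
#' @return `d_a + d_b`.
#' @export
ideal_bond_length <- function(d_a, d_b) d_a + d_b

# Pairwise ideal-angle table for one species (ncomp x ncomp, NA on diagonal).
ideal_angle_table <- function(species) {
  nc <- ncol(species$cvec)
  a <- matrix(NA_real_, nc, nc)
  if (nc >= 2) {
    for (j in seq_len(nc - 1)) for (k in (j + 1):nc) {
      ok <- sqrt(sum(species$cvec[, j]^2)) > 1e-12 &&
        sqrt(sum(species$cvec[, k]^2)) > 1e-12
      a[j, k] <- a[k, j] <- if (ok) ideal_angle(species, j, k) else NA_real_
    }
  }
  a
}

# Minimum-image displacement x_j - x_i under the active boundary conditions.
mi_delta <- function(xi, xj, box, periodic) {
  d <- xj - xi
  w <- periodic & is.finite(box)
  d[w] <- d[w] - box[w] * round(d[w] / box[w])
  d
}

#' Geometric compatibility of a candidate reaction pair
#'
#' Implements the reactive-volume test: a bimolecular reaction between
#' molecules `i` and `j` acting on components `ci` and `cj` is allowed iff
#' (1) their center distance deviates from the ideal bond length
#' `d_i,ci + d_j,cj` by at most `t_dist`, and (2) for every molecule of the
#' pair that already has bonds, the angle between the direction to each bonded
#' partner and the direction to the candidate partner deviates by at most
#' `t_ang` from the ideal angle between the bonded component and the reacting
#' component. Unbound molecules carry no rotational orientation and impose no
#' angular condition; both conditions must hold from both sides ("mutual
#' reactive volumes").
#'
#' @param rx a reactor object.
#' @param sys a compiled system.
#' @param i,j molecule indices.
#' @param ci,cj component indices of the reacting components.
#' @return `TRUE` if the pair is geometrically compatible.
#' @export
check_geometric_compatibility <- function(rx, sys, i, j, ci, cj) {
  fl <- sys$flat
  compat_cpp(rx$pos, rx$bond_to, rx$species, fl$comp_d, fl$ncomp,
             fl$t_dist, fl$t_ang_comp, fl$alpha,
             sys$config$box, sys$config$periodic,
             as.integer(i), as.integer(j), as.integer(ci), as.integer(cj))
}

#' Monte-Carlo estimate of a reactive volume
#'
#' Estimates the volume of the region in which a reaction partner may lie,
#' given the ideal bond length and the tolerances, and optionally the
#' directions of existing bonds of the anchoring molecule (each with the ideal
#' angle it must keep to the new bond). For an unbound molecule the region is
#' the closed-form spherical shell `4/3*pi*((d0+t)^3 - (max(d0-t,0))^3)`.
#'
#' @param d0 ideal bond length.
#' @param t_dist distance tolerance.
#' @param t_ang angular tolerance (radians).
#' @param bond_dirs optional matrix (nbond x 3) of unit directions to existing
#'   bonded partners.
#' @param alphas ideal angles (radians) between each existing bond's component
#'   and the reacting component; length `nrow(bond_dirs)`.
#' @param n number of Monte-Carlo samples.
#' @return estimated volume.
#' @export
reactive_volume <- function(d0, t_dist, t_ang, bond_dirs = NULL, alphas = NULL,
                            n = 200000L) {
  if (t_dist <= 0) stop("reactive_volume: zero distance tolerance gives an empty reactive volume")
  rmin <- max(d0 - t_dist, 0)
  rmax <- d0 + t_dist
  shell <- 4 / 3 * pi * (rmax^3 - rmin^3)
  if (is.null(bond_dirs) || nrow(bond_dirs) == 0L) return(shell)
  # sample uniformly in the shell, test angular conditions
  u <- runif(n)
  r <- (rmin^3 + u * (rmax^3 - rmin^3))^(1 / 3)
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  dir <- cbind(s * cos(phi), s * sin(phi), z)
  ok <- rep(TRUE, n)
  for (b in seq_len(nrow(bond_dirs))) {
    cosang <- dir %*% bond_dirs[b, ]
    ang <- acos(pmax(-1, pmin(1, cosang)))
    ok <- ok & abs(ang - alphas[b]) <= t_ang
  }
  shell * mean(ok)
}
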