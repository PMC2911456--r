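# Analytic force/energy terms of the force field, exposed for inspection and
# testing; the MD step evaluates the same expressions in compiled code (the
# test suite cross-checks both against numerical gradients).

#' Harmonic bond energy and force
#'
#' `E = K_d (d - d0)^2` (harmonic convention without the 1/2 factor); the
#' returned force magnitude is `-dE/dd` along the bond axis (positive =
#' pushing the partners apart).
#'
#' @param d current distance (`>= 0`).
#' @param d0 rest length.
#' @param K_d spring constant (energy/length^2).
#' @return list with `energy` and `force`.
#' @export
bond_energy_force <- function(d, d0, K_d) {
  stopifnot(all(d >= 0))
  list(energy = K_d * (d - d0)^2, force = -2 * K_d * (d - d0))
}

#' Harmonic angle energy and forces
#'
#' For the angle at the central molecule `x_j` spanned by `x_i` and `x_k`:
#' `E = K_alpha (alpha - alpha_ideal)^2`. Forces are the negative gradient;
#' they sum to zero and exert no net torque. A central molecule with n bonded
#' neighbors contributes one such term per neighbor pair (n(n-1)/2 terms).
#' Near-collinear configurations get a bounded force (the lever arm is
#' clamped).
#'
#' @param x_i,x_j,x_k positions (3-vectors), `x_j` central.
#' @param alpha_ideal rest angle (radians).
#' @param K_alpha spring constant (energy/radian^2).
#' @return list with `energy`, `f_i`, `f_j`, `f_k`.
#' @export
angle_energy_forces <- function(x_i, x_j, x_k, alpha_ideal, K_alpha) {
  rij <- x_i - x_j; rkj <- x_k - x_j
  dij <- sqrt(sum(rij^2)); dkj <- sqrt(sum(rkj^2))
  stopifnot(dij > 0, dkj > 0)
  cosv <- max(-1, min(1, sum(rij * rkj) / (dij * dkj)))
  theta <- acos(cosv)
  sinv <- max(sqrt(1 - cosv^2), 1e-4)
  dE <- 2 * K_alpha * (theta - alpha_ideal)
  coef <- dE / sinv    # d(theta)/d(cos) contributes a second minus sign
  f_i <- coef * (rkj / dkj - cosv * rij / dij) / dij
  f_k <- coef * (rij / dij - cosv * rkj / dkj) / dkj
  list(energy = K_alpha * (theta - alpha_ideal)^2,
       f_i = f_i, f_j = -(f_i + f_k), f_k = f_k)
}

#' Soft-sphere repulsion energy and force
#'
#' `E = A (1 + cos(pi r / r_c))` for `r < r_c`, zero beyond the cutoff; the
#' cutoff is the sum of the two radii, so molecules repel once they move
#' closer together than their radii allow.
#'
#' @param r center distance (`>= 0`).
#' @param r_c cutoff distance (sum of radii).
#' @param A maximal potential height.
#' @return list with `energy` and `force` (repulsive, along the axis).
#' @export
soft_repulsion <- function(r, r_c, A) {
  stopifnot(all(r >= 0), r_c > 0)
  inside <- r < r_c
  e <- ifelse(inside, A * (1 + cos(pi * r / r_c)), 0)
  f <- ifelse(inside, A * pi / r_c * sin(pi * r / r_c), 0)
  list(energy = e, force = f)
}

#' One Langevin velocity-Verlet step (low-level)
#'
#' Advances positions/velocities of a bare particle system by `n_steps`
#' steps under the given bonded terms and thermostat; used directly by
#' dynamics tests, while [run_simulation()] drives the same kernel with
#' reactions interleaved. Friction is parameterized per particle by the damp
#' time `damp = m D / (k_B T)` so a free particle's long-time diffusion
#' equals `D`; random and viscous forces obey the fluctuation-dissipation
#' relation at temperature `T`.
#'
#' @param state list with `pos`, `vel`, `force` (n x 3 matrices).
#' @param mass,damp per-particle vectors.
#' @param dt time step; @param temperature thermostat temperature.
#' @param box,periodic boundary description.
#' @param bonds,bond_d0,K_d,angles,angle_a0,K_alpha bonded terms (may be
#'   empty).
#' @param radius,A_rep soft-sphere parameters.
#' @param frozen,rigid per-particle flags / group ids.
#' @param n_steps sub-steps to advance.
#' @return updated `state` (plus `energy`, `ok`).
#' @export
langevin_step <- function(state, mass, damp, dt, temperature,
                          box, periodic = rep(TRUE, 3),
                          bonds = matrix(integer(0), 0, 2),
                          bond_d0 = numeric(0), K_d = 0,
                          angles = matrix(integer(0), 0, 3),
                          angle_a0 = numeric(0), K_alpha = 0,
                          radius = rep(0, nrow(state$pos)), A_rep = 0,
                          frozen = rep(FALSE, nrow(state$pos)),
                          rigid = rep(0L, nrow(state$pos)),
                          n_steps = 1L) {
  n <- nrow(state$pos)
  if (is.null(state$force)) {
    f <- compute_forces_cpp(state$pos, bonds, bond_d0, K_d, angles, angle_a0,
                            K_alpha, radius, A_rep, as.numeric(box),
                            as.logical(periodic), as.integer(rigid))
    state$force <- f$force
  }
  res <- md_step_cpp(state$pos, state$vel, state$force,
                     rep_len(mass, n), rep_len(damp, n),
                     as.logical(frozen), as.integer(rigid),
                     bonds, bond_d0, K_d, angles, angle_a0, K_alpha,
                     rep_len(radius, n), A_rep,
                     as.numeric(box), as.logical(periodic),
                     dt, temperature, as.integer(n_steps))
  if (!res$ok) stop("langevin_step: non-finite state", call. = FALSE)
  list(pos = res$pos, vel = res$vel, force = res$force, energy = res$energy,
       ok = res$ok)
}
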