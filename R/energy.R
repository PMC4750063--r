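#' Pair spontaneous curvature between two particles
#'
#' Implements the curvature-offset rules of the model: the full side curvature
#' `C_side` acts between particles of different rods, half of it between a rod
#' particle and a membrane particle, and the isotropic membrane curvature
#' `C_0` between two membrane particles. Pairs within the same rod are
#' handled by the chain bond/angle terms and are excluded from the pair
#' bending/tilt potential; for them the function returns `NA`.
#'
#' @param i,j Particle indices (1-based).
#' @param state A `particle_state`.
#' @param params A [membrane_params()] object.
#' @return The curvature offset (1/sigma), or `NA` for same-rod pairs.
#' @export
pair_spontaneous_curvature <- function(i, j, state, params) {
  n <- nrow(state)
  if (any(c(i, j) < 1) || any(c(i, j) > n) || i == j) {
    stop("particle indices out of range or equal", call. = FALSE)
  }
  ri <- state$rod[i]
  rj <- state$rod[j]
  if (!is.na(ri) && !is.na(rj)) {
    if (ri == rj) return(NA_real_)
    return(params$C_side)
  }
  if (!is.na(ri) || !is.na(rj)) return(params$C_side / 2)
  params$C_0
}

#' Local density entering the multibody attraction
#'
#' `rho_i = sum_j w(r_ij)` with the compact C1 weight that is 1 up to `r_att`
#' and ramps to 0 at `r_cut`. Non-bonded pairs within the same rod are
#' excluded, which prevents a rod from self-attracting into a collapsed coil.
#'
#' @param state A `particle_state`.
#' @param params A [membrane_params()] object.
#' @return Numeric vector of local densities, one per particle.
#' @export
local_density <- function(state, params) {
  m <- state_matrices(state, params)
  as.numeric(local_density_cpp(m$pos, m$rodid, m$box, unclass(params)))
}

#' Total potential energy with per-term breakdown
#'
#' The energy is the sum of the truncated-shifted exponential repulsion, the
#' saturating multibody attraction, the orientation tilt and bending pair
#' potentials (the latter carrying the pair spontaneous-curvature offset), and
#' the harmonic bond/angle chain terms whose preferred turning angle per joint
#' encodes `C_rod`.
#'
#' @param state A `particle_state`.
#' @param params A [membrane_params()] object.
#' @return A list with `total` (kT) and `terms`, a tibble of the six
#'   contributions.
#' @export
potential_energy <- function(state, params) {
  validate_state(state)
  m <- state_matrices(state, params)
  r <- forces_cpp(m$pos, m$ori, m$rodid, m$bonds, m$angles, m$box,
                  unclass(params), FALSE)
  terms <- tibble::tibble(
    term = c("repulsion", "attraction", "tilt", "bend", "bond", "angle"),
    energy = c(r$e_rep, r$e_att, r$e_tilt, r$e_bend, r$e_bond, r$e_angle))
  list(total = r$energy, terms = terms)
}

#' Forces and orientation torques
#'
#' Analytic gradients of the potential: `force = -dU/dr` per particle, and
#' the orientation torque about the unit sphere. `ugrad` is the raw gradient
#' `dU/du`; `torque = -(u x ugrad)` drives the rotational dynamics, and the
#' tangent-plane force on the orientation is `-(I - u u^T) ugrad`.
#'
#' @param state A `particle_state`.
#' @param params A [membrane_params()] object.
#' @return A tibble with per-particle force components `fx, fy, fz`,
#'   tangent-plane orientation gradient components `gx, gy, gz`
#'   (already projected orthogonal to `u`), and torque components
#'   `tx, ty, tz`.
#' @export
forces_and_torques <- function(state, params) {
  validate_state(state)
  m <- state_matrices(state, params)
  r <- forces_cpp(m$pos, m$ori, m$rodid, m$bonds, m$angles, m$box,
                  unclass(params), TRUE)
  G <- r$ugrad
  u <- m$ori
  proj <- G - u * rowSums(G * u) # tangent-plane component of dU/du
  tq <- cbind(u[, 2] * G[, 3] - u[, 3] * G[, 2],
              u[, 3] * G[, 1] - u[, 1] * G[, 3],
              u[, 1] * G[, 2] - u[, 2] * G[, 1])
  tibble::tibble(
    fx = r$forces[, 1], fy = r$forces[, 2], fz = r$forces[, 3],
    gx = -proj[, 1], gy = -proj[, 2], gz = -proj[, 3],
    tx = -tq[, 1], ty = -tq[, 2], tz = -tq[, 3])
}
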