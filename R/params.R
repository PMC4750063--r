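#' Model parameters for the rod-membrane model
#'
#' Bundles every interaction constant of the meshless membrane / curved-rod
#' model together with the thermostat and timestep settings. Lengths are in
#' units of the particle diameter `sigma`, energies in units of the thermal
#' energy `kT`.
#'
#' The defaults are the package's calibrated parameter set: the tensionless
#' bare membrane assembled with them has bending rigidity kappa close to 15 kT
#' (see `estimate_kappa()` and `calibrate_bending()`).
#'
#' @param sigma Particle diameter, the length unit.
#' @param eps_rep Strength of the short-ranged exponential repulsion (kT).
#' @param eps_att Strength of the saturating multibody attraction (kT).
#' @param rho_star Local-density saturation threshold of the attraction.
#' @param k_tilt Tilt pair-potential coefficient (kT).
#' @param k_bend Bending pair-potential coefficient (kT).
#' @param C_0 Isotropic spontaneous curvature of the bare membrane (1/sigma).
#' @param C_rod Rod spontaneous curvature along the rod axis (1/sigma).
#' @param C_side Rod spontaneous curvature perpendicular to the rod axis
#'   (1/sigma). Applied in full between particles of different rods and at
#'   half strength between a rod particle and a neighbouring membrane particle.
#' @param N_sg Number of particles per rod.
#' @param r_rod Rod contour length (sigma); the bond length is
#'   `r_rod / (N_sg - 1)`.
#' @param k_bond Harmonic bond stiffness of the rod chain (kT/sigma^2).
#' @param k_angle Harmonic stiffness of the chain turning term that carries
#'   `C_rod` (kT).
#' @param r_cut Interaction cutoff (sigma).
#' @param r_att Start of the C1 cosine ramp of the compact weight function;
#'   the weight is 1 below `r_att` and 0 beyond `r_cut`.
#' @param kT Thermal energy, the energy unit.
#' @param zeta Translational Langevin friction.
#' @param zeta_r Rotational Langevin friction for the orientation vectors.
#' @param dt Integration timestep.
#' @param m Particle mass.
#' @param inertia Moment of inertia of the orientation degree of freedom.
#' @return An object of class `membrane_params` (a named list).
#' @export
#' @examples
#' p <- membrane_params(C_rod = 0.4, C_side = 0.1)
#' rod_equilibrium_geometry(p)
membrane_params <- function(sigma = 1, eps_rep = 4, eps_att = 4, rho_star = 6,
                            k_tilt = 10, k_bend = 16.5, C_0 = 0,
                            C_rod = 0, C_side = 0,
                            N_sg = 10L, r_rod = 10, k_bond = 100, k_angle = 100,
                            r_cut = 2.1, r_att = 1.9,
                            kT = 1, zeta = 1, zeta_r = 1, dt = 0.002,
                            m = 1, inertia = 1) {
  p <- list(sigma = sigma, eps_rep = eps_rep, eps_att = eps_att,
            rho_star = rho_star, k_tilt = k_tilt, k_bend = k_bend,
            C_0 = C_0, C_rod = C_rod, C_side = C_side,
            N_sg = as.integer(N_sg), r_rod = r_rod,
            k_bond = k_bond, k_angle = k_angle,
            r_cut = r_cut, r_att = r_att,
            kT = kT, zeta = zeta, zeta_r = zeta_r, dt = dt,
            m = m, inertia = inertia)
  p$bond_length <- r_rod / (p$N_sg - 1)
  class(p) <- "membrane_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(p$sigma > 0, p$r_cut > p$sigma, p$r_att < p$r_cut,
            p$N_sg >= 2L, p$bond_length > 0,
            p$kT >= 0, p$dt > 0, p$m > 0, p$inertia > 0)
  ks <- c("eps_rep", "eps_att", "k_tilt", "k_bend", "k_bond", "k_angle")
  if (any(unlist(p[ks]) < 0)) stop("stiffnesses must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params>\n")
  keys <- setdiff(names(x), "bond_length")
  cat(paste0("  ", format(keys), " = ", unlist(x[keys]), collapse = "\n"), "\n")
  cat(sprintf("  bond_length = %.6g (r_rod/(N_sg-1))\n", x$bond_length))
  invisible(x)
}

#' Equilibrium geometry of a free rod
#'
#' The rod chain has bond length `r_rod/(N_sg - 1)` and a preferred turning
#' angle of `C_rod * bond_length` per interior joint, so a relaxed free rod is
#' a circular arc of curvature `C_rod` and contour length `r_rod`.
#'
#' @param params A [membrane_params()] object.
#' @return A tibble with columns `bond_length` and `joint_angle` (radians).
#' @export
rod_equilibrium_geometry <- function(params) {
  stopifnot(inherits(params, "membrane_params"), params$N_sg >= 2L)
  tibble::tibble(bond_length = params$bond_length,
                 joint_angle = params$C_rod * params$bond_length)
}

#' Write / read model parameters as a flat key-value text file
#'
#' The configuration format is one `key = value` pair per line; `#` starts a
#' comment. All keys must be arguments of [membrane_params()]; unknown keys
#' are an error.
#'
#' @param params A [membrane_params()] object.
#' @param file Path of the configuration file.
#' @return `write_params()` returns `file` invisibly; `read_params()` returns
#'   a [membrane_params()] object.
#' @export
write_params <- function(params, file) {
  stopifnot(inherits(params, "membrane_params"))
  keys <- setdiff(names(params), "bond_length")
  lines <- sprintf("%s = %.17g", keys, unlist(params[keys]))
  writeLines(c("# rod-membrane model parameters", lines), file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  raw <- readLines(file)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  kv <- strsplit(raw, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed config line(s): ", paste(raw[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2)))
  known <- names(formals(membrane_params))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(vals)) stop("non-numeric parameter value in config", call. = FALSE)
  do.call(membrane_params, as.list(stats::setNames(vals, keys)))
}

#' Ensemble specification for the projected-area control
#'
#' At `gamma = 0` the Monte Carlo box moves realise the tensionless state; a
#' positive `gamma` favours expansion of the projected area.
#'
#' @param gamma Imposed surface tension (kT/sigma^2).
#' @param mode `"fixed_projected_area"` (no box moves) or `"constant_tension"`.
#' @param box_move_interval Integration steps between box-resize attempts.
#' @param box_move_amplitude Maximum relative change of the projected area per
#'   attempt; must be in (0, 0.05].
#' @return An `ensemble_spec` object.
#' @export
ensemble_spec <- function(gamma = 0, mode = c("constant_tension", "fixed_projected_area"),
                          box_move_interval = 20L, box_move_amplitude = 0.005) {
  mode <- match.arg(mode)
  stopifnot(box_move_amplitude > 0, box_move_amplitude <= 0.05,
            box_move_interval >= 1)
  structure(list(gamma = gamma, mode = mode,
                 box_move_interval = as.integer(box_move_interval),
                 box_move_amplitude = box_move_amplitude),
            class = "ensemble_spec")
}

#' Two-phase simulation protocol
#'
#' Rods are first equilibrated with both spontaneous curvatures switched off;
#' at t = 0 the curvatures are set to their production values.
#'
#' @param t_equil Equilibration duration, in time units of the integrator
#'   (or in tau if `tau` is supplied to [run_protocol()]).
#' @param t_prod Production duration.
#' @param frame_interval Interval between stored/analysed frames.
#' @param seed RNG seed; recorded in the run manifest.
#' @return A `protocol_spec` object.
#' @export
protocol_spec <- function(t_equil, t_prod, frame_interval, seed = 1L) {
  stopifnot(t_equil >= 0, t_prod >= 0, frame_interval > 0)
  structure(list(t_equil = t_equil, t_prod = t_prod,
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "protocol_spec")
}
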