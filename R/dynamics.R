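#' Advance the system by underdamped Langevin dynamics
#'
#' BAOAB splitting for positions and velocities, with the orientation vectors
#' carried by an analogous rotational scheme: angular velocities live in the
#' tangent plane of the unit sphere, torques are `-(u x dU/du)`, and the
#' orientation is rotated exactly about the angular-velocity axis, then
#' renormalised. With friction and noise switched off the scheme reduces to a
#' conservative velocity-Verlet-type integrator.
#'
#' @param state A `particle_state`.
#' @param params A [membrane_params()] object.
#' @param steps Number of timesteps.
#' @param seed RNG seed for the thermostat noise (same seed, same inputs:
#'   bit-identical trajectory on one platform).
#' @param ensemble An optional [ensemble_spec()]; in `constant_tension` mode
#'   Monte Carlo box moves on the projected area are interleaved.
#' @return The advanced `particle_state`, with attributes `energy`,
#'   `kinetic_temperature` and (for tension runs) `tension_acceptance`.
#' @export
langevin_run <- function(state, params, steps, seed = 1L, ensemble = NULL) {
  validate_state(state)
  m <- state_matrices(state, params)
  tension_on <- !is.null(ensemble) && ensemble$mode == "constant_tension"
  r <- run_langevin_cpp(m$pos, m$ori, m$vel, m$angv, m$rodid, m$bonds,
                        m$angles, m$box, unclass(params), as.integer(steps),
                        as.double(seed), tension_on,
                        if (tension_on) ensemble$gamma else 0,
                        if (tension_on) ensemble$box_move_interval else 1L,
                        if (tension_on) ensemble$box_move_amplitude else 0)
  if (isTRUE(r$nan_abort)) {
    bad <- state_from_matrices(state, r$pos, r$ori, r$vel, r$angv, r$box)
    dump <- tempfile("nan_frame_", fileext = ".xyz")
    try(write_trajectory(list(bad), dump, params), silent = TRUE)
    stop("non-finite energy during integration; diagnostic frame written to ",
         dump, call. = FALSE)
  }
  out <- state_from_matrices(state, r$pos, r$ori, r$vel, r$angv, r$box,
                             time = state_time(state) + steps * params$dt)
  attr(out, "energy") <- r$energy
  attr(out, "kinetic_temperature") <- 2 * r$ke_mean / (3 * nrow(state)) /
    params$kT
  if (tension_on) {
    attr(out, "tension_acceptance") <-
      if (r$tension_try > 0) r$tension_acc / r$tension_try else NA_real_
  }
  out
}

#' @rdname langevin_run
#' @export
langevin_step <- function(state, params, seed = 1L) {
  langevin_run(state, params, steps = 1L, seed = seed)
}

#' Single constant-tension Monte Carlo box move
#'
#' Proposes a change of the projected (x, y) area by an affine rescaling of
#' the in-plane coordinates (z untouched) and accepts it with the Metropolis
#' probability `min(1, exp(-(dU - gamma * dA) / kT))`. At `gamma = 0` this
#' realises the tensionless state.
#'
#' @param state A `particle_state` with a planar periodic geometry.
#' @param ensemble An [ensemble_spec()].
#' @param params A [membrane_params()] object.
#' @param seed RNG seed.
#' @return The (possibly rescaled) state, with attribute `accepted`.
#' @export
tension_move <- function(state, ensemble, params, seed = 1L) {
  per <- attr(state, "periodic")
  if (!per[1] || !per[2]) {
    stop("tension moves need a planar geometry periodic in x and y",
         call. = FALSE)
  }
  set.seed(seed)
  box <- state_box(state)
  A <- box[1] * box[2]
  dA <- stats::runif(1, -1, 1) * ensemble$box_move_amplitude * A
  s <- sqrt((A + dA) / A)
  U0 <- potential_energy(state, params)$total
  trial <- state
  trial$x <- trial$x * s
  trial$y <- trial$y * s
  attr(trial, "box") <- c(box[1] * s, box[2] * s, box[3])
  U1 <- potential_energy(trial, params)$total
  arg <- -(U1 - U0 - ensemble$gamma * dA) / params$kT
  accept <- is.finite(arg) && (arg >= 0 || stats::runif(1) < exp(arg))
  out <- if (accept) trial else state
  attr(out, "accepted") <- accept
  out
}

#' Run the two-phase tubulation protocol
#'
#' Phase one equilibrates the system with both rod spontaneous curvatures set
#' to zero; at t = 0 the curvatures are switched to their values in `params`
#' and the production phase is run, storing frames and per-frame observables.
#'
#' Durations in `protocol` are interpreted in units of tau = r_rod^2 / D when
#' `tau` is supplied; otherwise raw simulation time is used and a warning is
#' logged once.
#'
#' @param state Initial `particle_state` (typically from
#'   [build_flat_membrane()] + [seed_rods()] or [build_vesicle()]).
#' @param params Production [membrane_params()] (with the target `C_rod`,
#'   `C_side`).
#' @param protocol A [protocol_spec()].
#' @param ensemble An [ensemble_spec()] (default: tensionless).
#' @param tau The time unit r_rod^2/D in simulation time units, from
#'   [estimate_diffusion()]; `NULL` falls back to raw time.
#' @param geometry `"flat"` or `"vesicle"`, forwarded to the observables.
#' @param keep_frames Keep the full frames (otherwise only observables).
#' @param observables Compute per-frame cluster/tubule observables.
#' @param progress Print one status line per frame.
#' @return A `rod_protocol` object: list with `frames`, `obs` (tibble),
#'   `params`, `protocol`, `ensemble`, `tau`.
#' @export
run_protocol <- function(state, params, protocol, ensemble = ensemble_spec(),
                         tau = NULL, geometry = c("flat", "vesicle"),
                         keep_frames = TRUE, observables = TRUE,
                         progress = FALSE) {
  geometry <- match.arg(geometry)
  unit <- if (is.null(tau)) {
    warning("no tau calibration supplied; durations taken as raw simulation time",
            call. = FALSE)
    1
  } else {
    tau
  }
  dt <- params$dt
  steps_of <- function(t) max(0L, as.integer(round(t * unit / dt)))
  frame_steps <- max(1L, steps_of(protocol$frame_interval))
  equil_params <- params
  equil_params$C_rod <- 0
  equil_params$C_side <- 0

  chunk_seed <- function(k) (as.numeric(protocol$seed) * 1000003 + k) %% 2^31

  total_equil <- steps_of(protocol$t_equil)
  total_prod <- steps_of(protocol$t_prod)
  frames <- list()
  obs <- list()
  k <- 0L
  done <- 0L
  while (done < total_equil) {
    nstep <- min(frame_steps, total_equil - done)
    k <- k + 1L
    state <- langevin_run(state, equil_params, nstep, seed = chunk_seed(k),
                          ensemble = ensemble)
    done <- done + nstep
  }
  attr(state, "time") <- 0 # curvatures switch on at t = 0
  record <- function(st, idx) {
    t_tau <- state_time(st) / unit
    row <- tibble::tibble(frame = idx, time_tau = t_tau,
                          area = prod(state_box(st)[1:2]),
                          energy = attr(st, "energy") %||% NA_real_)
    if (observables && any(st$type == "rod")) {
      rep <- find_rod_clusters(st, params)
      perc <- percolation_check(rep)
      ch <- cluster_height(st, params, rep)
      tb <- detect_tubules(st, params, geometry = geometry)
      row$mean_cluster_size <- mean_cluster_size(rep)
      row$largest_cluster_frac <- max(rep$sizes$n) / rep$n_rod
      row$z_cl <- ch$z_cl
      row$percolating_x <- perc$x
      row$percolating_y <- perc$y
      row$n_tubules <- nrow(tb)
      row$max_tubule_length <- if (nrow(tb) > 0) max(tb$length) else 0
    }
    row
  }
  idx <- 0L
  obs[[length(obs) + 1]] <- record(state, idx)
  if (keep_frames) frames[[length(frames) + 1]] <- state
  done <- 0L
  while (done < total_prod) {
    nstep <- min(frame_steps, total_prod - done)
    k <- k + 1L
    state <- langevin_run(state, params, nstep, seed = chunk_seed(k),
                          ensemble = ensemble)
    done <- done + nstep
    idx <- idx + 1L
    obs[[length(obs) + 1]] <- record(state, idx)
    if (keep_frames) frames[[length(frames) + 1]] <- state
    if (progress) {
      message(sprintf("frame %d  t = %.2f tau", idx, state_time(state) / unit))
    }
  }
  structure(list(frames = frames, obs = dplyr::bind_rows(obs),
                 params = params, protocol = protocol, ensemble = ensemble,
                 tau = tau, final_state = state),
            class = "rod_protocol")
}

#' @export
print.rod_protocol <- function(x, ...) {
  cat(sprintf("<rod_protocol> %d frames, %.4g tau production\n",
              nrow(x$obs) - 1, max(x$obs$time_tau)))
  print(utils::tail(x$obs, 3))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
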