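p_dyn <- membrane_params()

test_that("zero temperature, zero force, zero velocity: state unchanged", {
  p0 <- membrane_params(kT = 0)
  one <- particle_state(tibble::tibble(type = "membrane", x = 15, y = 15,
                                       z = 15, ux = 0, uy = 0, uz = 1),
                        box = c(30, 30, 30))
  out <- langevin_run(one, p0, 50, seed = 1)
  expect_equal(out$x, one$x)
  expect_equal(out$z, one$z)
  expect_equal(out$uz, one$uz)
})

test_that("same seed and inputs give a bit-identical trajectory", {
  st <- small_mixed_state(membrane_params(C_rod = 0.4, C_side = -0.1))
  a <- langevin_run(st, p_dyn, 300, seed = 42)
  b <- langevin_run(st, p_dyn, 300, seed = 42)
  expect_identical(a$x, b$x)
  expect_identical(a$ux, b$ux)
  expect_identical(a$vx, b$vx)
  c <- langevin_run(st, p_dyn, 300, seed = 43)
  expect_false(identical(a$x, c$x))
})

test_that("kinetic temperature equilibrates to the thermostat target", {
  st <- build_flat_membrane(400, p_dyn, seed = 4)
  st <- langevin_run(st, p_dyn, 3000, seed = 5) # thermalise
  st <- langevin_run(st, p_dyn, 20000, seed = 6)
  expect_equal(attr(st, "kinetic_temperature"), 1, tolerance = 0.02)
})

test_that("with the thermostat off the integrator conserves energy", {
  p0 <- p_dyn
  st <- build_flat_membrane(100, p_dyn, seed = 8)
  st <- langevin_run(st, p_dyn, 1000, seed = 8) # draw velocities thermally
  p0$zeta <- 0; p0$zeta_r <- 0
  etot <- function(s) attr(s, "energy") +
    0.5 * sum(s$vx^2 + s$vy^2 + s$vz^2) +
    0.5 * sum(s$wx^2 + s$wy^2 + s$wz^2)
  s1 <- langevin_run(st, p0, 1, seed = 1)
  e0 <- etot(s1)
  s2 <- langevin_run(s1, p0, 1000, seed = 1)
  expect_lt(abs(etot(s2) - e0) / abs(e0), 1e-4)
})

test_that("tension moves: trivial acceptance and ideal-gas null", {
  # no interactions at all: every move is accepted, area random-walks with
  # zero mean drift under gamma = 0
  p_free <- membrane_params(eps_rep = 0, eps_att = 0, k_tilt = 0, k_bend = 0)
  st <- build_flat_membrane(64, p_free, seed = 2)
  ens <- ensemble_spec(gamma = 0, box_move_amplitude = 0.01)
  A0 <- prod(state_box(st)[1:2])
  dAs <- vapply(1:400, function(s) {
    out <- tension_move(st, ens, p_free, seed = s)
    expect_true(attr(out, "accepted"))
    prod(state_box(out)[1:2]) - A0
  }, numeric(1))
  expect_lt(abs(mean(dAs)) / stats::sd(dAs) * sqrt(length(dAs)), 3)
})

test_that("stationary projected area increases with imposed tension", {
  st0 <- build_flat_membrane(100, p_dyn, seed = 3)
  area_at <- function(gamma) {
    st <- langevin_run(st0, p_dyn, 12000, seed = 11,
                       ensemble = ensemble_spec(gamma = gamma))
    st <- langevin_run(st, p_dyn, 8000, seed = 12,
                       ensemble = ensemble_spec(gamma = gamma))
    prod(state_box(st)[1:2])
  }
  areas <- vapply(c(0, 2, 5), area_at, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("tension moves refuse non-planar geometries", {
  ves <- build_vesicle(64, 6, p_dyn)
  attr(ves, "periodic") <- c(FALSE, FALSE, FALSE)
  expect_error(tension_move(ves, ensemble_spec(), p_dyn), "planar")
})

test_that("protocol switches curvatures at t = 0 and reports frames", {
  p <- membrane_params(C_rod = 0.4, C_side = 0.1)
  st <- small_mixed_state(p)
  expect_warning(
    pr <- run_protocol(st, p, protocol_spec(t_equil = 0.2, t_prod = 0,
                                            frame_interval = 0.1, seed = 1),
                       observables = FALSE),
    "tau")
  expect_equal(nrow(pr$obs), 1) # only the t = 0 frame: no production
  expect_equal(pr$obs$time_tau, 0)
  pr2 <- run_protocol(st, p, protocol_spec(0.1, 0.3, 0.1, seed = 1),
                      tau = 1, observables = TRUE)
  expect_equal(nrow(pr2$obs), 4)
  expect_true(all(diff(pr2$obs$time_tau) > 0))
  expect_true(all(c("mean_cluster_size", "z_cl", "percolating_x",
                    "n_tubules") %in% names(pr2$obs)))
})
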