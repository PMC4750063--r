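test_that("striped array follows the normal-continuity relation and limits", {
  p <- array_params(phi_rod = 0.4, C_rod = 1, C_side = 0)
  # C_2 = phi C_1 / (1 - phi): at phi = 0.4, C_1 = 1 -> C_2 = 2/3
  C2 <- p$phi_rod * 1 / (1 - p$phi_rod)
  expect_equal(C2, 2 / 3)
  # with C_1 = C_rod and C_side = 0 only the bare-membrane term survives
  expect_equal(striped_energy(1, p),
               (1 - p$phi_rod) * p$kappa / 2 * C2^2)
  # bare-membrane term vanishes as phi^2 at small phi and fixed C_1
  phis <- c(1e-3, 2e-3, 4e-3)
  vals <- vapply(phis, function(ph) {
    q <- array_params(phi_rod = ph, C_rod = 0, C_side = 0)
    striped_energy(1, q) - ph * q$kappa_r1 / 2
  }, numeric(1))
  expect_equal(vals[2] / vals[1], 4, tolerance = 0.01)
  expect_equal(vals[3] / vals[2], 4, tolerance = 0.01)
  expect_error(array_params(phi_rod = 1.2), "phi_rod")
})

test_that("hexagonal constraints close: flat limit, domain edge, areas", {
  p <- array_params(phi_rod = 0.4, C_side = -1)
  g0 <- hex_constraints(0, p)
  expect_equal(g0$theta_2, pi / 3)
  expect_equal(g0$C_3, 0)
  expect_equal(g0$C_4, 0)
  # vertex cap angle closes at the maximum admissible C_1 = 2*pi/(3*r_rod)
  cmax <- 2 * pi / 3
  gedge <- hex_constraints(cmax * (1 - 1e-12), p)
  expect_lt(abs(gedge$theta_2), 1e-10)
  expect_error(hex_constraints(cmax, p), "C1")
  expect_error(hex_constraints(-0.1, p), "C1")
  # region areas close and region I carries exactly phi_rod
  for (phi in c(0.1, 0.25, 0.4, 0.5)) {
    q <- array_params(phi_rod = phi)
    g <- hex_constraints(seq(0, 2, by = 0.25), q)
    expect_true(all(abs(g$a_I + g$a_II + g$a_III - 1) < 1e-12))
    expect_true(all(abs(g$a_I - phi) < 1e-10))
  }
  expect_error(hex_constraints(0.5, array_params(phi_rod = 0.6)), "phi_rod")
})

test_that("hexagonal energy is smooth and reduces to the striped one flat", {
  p <- array_params(phi_rod = 0.4, C_side = 1)
  expect_equal(hex_energy(0, p), striped_energy(0, p))
  # finite-difference smoothness scan over the open domain
  c1 <- seq(0.01, 2.05, length.out = 400)
  f <- hex_energy(c1, p)
  d2 <- diff(diff(f))
  expect_lt(max(abs(d2)), 1e-3) # no kinks on a smooth quadratic-like curve
})

test_that("delta F: zero at flat, independent of C_rod and kappa_r1", {
  base <- array_params(phi_rod = 0.4, C_side = -1)
  dfb <- delta_F(base)
  expect_equal(dfb$dF[1], 0)
  for (crod in c(0, 2, 4)) {
    for (kr1 in c(20, 40, 400)) {
      p2 <- array_params(phi_rod = 0.4, C_side = -1, C_rod = crod,
                         kappa_r1 = kr1)
      df2 <- delta_F(p2, C1 = dfb$C_1)
      expect_identical(df2$dF, dfb$dF) # exact cancellation, bit-identical
    }
  }
})

test_that("sign structure: the network wins only for negative side curvature", {
  mins <- vapply(c(-1, 0, 1), function(cs) {
    attr(delta_F(array_params(phi_rod = 0.4, kappa = 15, kappa_r2 = 15,
                              C_side = cs)), "min_dF")
  }, numeric(1))
  expect_lt(mins[1], -1e-3)       # C_side = -1: branched network favoured
  expect_gte(mins[2], -1e-12)     # C_side = 0: never below zero
  expect_gte(mins[3], -1e-12)     # C_side = +1: never below zero
})

test_that("minimum depth matches the closed-form quadratic oracle", {
  # dF(C1) = alpha C1^2 + beta C1 with coefficients assembled independently
  # from the construction; minimum -beta^2/(4 alpha) at C1 = -beta/(2 alpha)
  quad_min <- function(phi, kap, kr2, cs) {
    Lh <- (1 + sqrt(1 - 2 * phi)) / (sqrt(3) * phi)
    L1 <- Lh - 1 / sqrt(3)
    g <- 1 / (sqrt(3) * L1)
    aII <- 1 / (3 * Lh^2)
    alpha <- phi * kr2 / 2 * g^2 + 4 * kap * aII - kap / 2 * phi^2 / (1 - phi)
    beta <- phi * kr2 * g * cs
    if (beta >= 0) 0 else -beta^2 / (4 * alpha)
  }
  for (phi in c(0.3, 0.4, 0.5)) {
    p <- array_params(phi_rod = phi, kappa = 15, kappa_r2 = 15, C_side = -1)
    expect_equal(attr(delta_F(p), "min_dF"), quad_min(phi, 15, 15, -1),
                 tolerance = 1e-8)
  }
  # the phi = 0.5 vs 0.4 minimum ratio implied by the construction
  r <- quad_min(0.5, 15, 15, -1) / quad_min(0.4, 15, 15, -1)
  expect_equal(attr(delta_F(array_params(phi_rod = 0.5, kappa = 15,
                                         kappa_r2 = 15, C_side = -1)), "min_dF") /
                 attr(delta_F(array_params(phi_rod = 0.4, kappa = 15,
                                           kappa_r2 = 15, C_side = -1)), "min_dF"),
               r, tolerance = 1e-6)
  expect_equal(r, 2, tolerance = 0.1) # about twice as deep at phi = 0.5
})

test_that("hexagon edge length grows as density falls; threshold bisection", {
  p <- array_params(phi_rod = 0.4)
  phis <- seq(0.05, 0.5, by = 0.05)
  Lh <- vapply(phis, function(ph)
    hex_constraints(0, array_params(phi_rod = ph))$L_h, numeric(1))
  expect_true(all(diff(Lh) < 0))
  r1 <- critical_network_density(p, onset_extent = 3)
  expect_true(r1$bounded)
  r2 <- critical_network_density(p, onset_extent = 3, tol = 1e-12)
  expect_equal(r1$phi_threshold, r2$phi_threshold, tolerance = 1e-6)
  # threshold consistency: L_h at the threshold equals the onset extent
  expect_equal(hex_constraints(0, array_params(
    phi_rod = r1$phi_threshold))$L_h, 3, tolerance = 1e-6)
  r3 <- critical_network_density(p, onset_extent = 0)
  expect_false(r3$bounded)
})
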