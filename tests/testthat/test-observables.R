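p_o <- membrane_params()

test_that("cluster partition equals the brute-force transitive closure", {
  for (seed in 1:4) {
    st <- random_rod_state(30, p_o, box = c(50, 50, 60), seed = seed,
                           z_sd = 1)
    rep <- find_rod_clusters(st, p_o)
    coms <- cbind(rep$coms$x, rep$coms$y, rep$coms$z)
    oracle <- brute_force_clusters(coms, attr(st, "box"), p_o$r_rod / 2)
    # identical partitions up to label permutation
    expect_equal(length(unique(oracle)), nrow(rep$sizes))
    tab <- table(rep$clusters$cluster, oracle)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  # threshold cases from the definition
  near <- make_fixture("known_clusters", p_o)$state # 0.4 r_rod apart
  expect_equal(nrow(find_rod_clusters(near, p_o)$sizes), 1)
  far <- make_fixture("known_clusters", p_o,
                      centers = rbind(c(10, 10, 0),
                                      c(10 + 0.6 * p_o$r_rod, 10, 0)))$state
  expect_equal(nrow(find_rod_clusters(far, p_o)$sizes), 2)
  one <- random_rod_state(1, p_o)
  expect_equal(find_rod_clusters(one, p_o)$sizes$n, 1)
  mem <- build_flat_membrane(64, p_o)
  expect_error(find_rod_clusters(mem, p_o), "no rods")
})

test_that("mean cluster size: both averaging conventions", {
  fake <- structure(list(sizes = tibble::tibble(n = c(4, 4, 2))),
                    class = "cluster_report")
  expect_equal(mean_cluster_size(fake), 3.6)
  expect_equal(mean_cluster_size(fake, "number"), 10 / 3)
  allone <- structure(list(sizes = tibble::tibble(n = rep(1, 7))),
                      class = "cluster_report")
  expect_equal(mean_cluster_size(allone), 1)
  single <- structure(list(sizes = tibble::tibble(n = 12)),
                      class = "cluster_report")
  expect_equal(mean_cluster_size(single), 12)
})

test_that("cluster height matches the direct formula", {
  # two-segment rod with segments at z = +h and -h: variance h^2
  p2 <- membrane_params(N_sg = 2, r_rod = 2)
  h <- 1.3
  st <- particle_state(
    tibble::tibble(type = "rod", rod = 1L, seg = 1:2,
                   x = c(10, 10), y = c(10, 10), z = c(-h, h),
                   ux = 1, uy = 0, uz = 0),
    box = c(30, 30, 30))
  ch <- cluster_height(st, p2)
  expect_equal(ch$per_cluster$variance, h^2)
  # coplanar cluster at any height has zero variance
  flat <- random_rod_state(5, p_o, seed = 3)
  flat$z <- flat$z * 0 + 4.2
  expect_equal(cluster_height(flat, p_o)$z_cl, 0)
  # direct-summation oracle on a network fixture with engineered heights
  st2 <- random_rod_state(12, p_o, box = c(35, 35, 60), seed = 6, z_sd = 2)
  rep <- find_rod_clusters(st2, p_o)
  ch2 <- cluster_height(st2, p_o, rep)
  vars <- vapply(split(rep$clusters$rod, rep$clusters$cluster), function(rods) {
    z <- st2$z[st2$rod %in% rods]
    mean((z - mean(z))^2)
  }, numeric(1))
  expect_equal(ch2$z_cl, sqrt(mean(vars)), tolerance = 1e-12)
  # invariance under rigid translations (in-plane and vertical)
  st3 <- st2
  st3$x <- (st3$x + 11) %% 35; st3$y <- (st3$y + 3) %% 35; st3$z <- st3$z + 5
  expect_equal(cluster_height(st3, p_o)$z_cl, ch2$z_cl, tolerance = 1e-9)
  expect_equal(mean_cluster_size(find_rod_clusters(st3, p_o)),
               mean_cluster_size(rep))
})

test_that("percolation flags: spanning fixtures and wrap invariance", {
  fh <- make_fixture("hex_network", p_o)
  rep <- find_rod_clusters(fh$state, p_o)
  perc <- percolation_check(rep)
  expect_true(perc$x && perc$y)
  fs <- make_fixture("striped_array", p_o)
  ps <- percolation_check(find_rod_clusters(fs$state, p_o))
  expect_true(ps$x)
  expect_false(ps$y)
  # an isolated compact cluster does not percolate
  pk <- percolation_check(find_rod_clusters(
    make_fixture("known_clusters", p_o)$state, p_o))
  expect_false(pk$x || pk$y)
  # invariance under the choice of primary image
  sh <- fs$state
  sh$x <- (sh$x + 17.3) %% attr(sh, "box")[1]
  sh$y <- (sh$y + 5.9) %% attr(sh, "box")[2]
  ps2 <- percolation_check(find_rod_clusters(sh, p_o))
  expect_identical(ps2[c("x", "y")], ps[c("x", "y")])
  # sparse random rods essentially never percolate
  hits <- 0
  for (s in 1:60) {
    st <- random_rod_state(8, p_o, box = c(60, 60, 60), seed = 100 + s)
    pc <- percolation_check(find_rod_clusters(st, p_o))
    hits <- hits + (pc$x || pc$y)
  }
  expect_lt(hits / 60, 0.05)
})

test_that("pathway classification applies the net/part/iso rules", {
  mk <- function(percx, percy, frac, ntub, t = seq(0, 98, by = 2)) {
    tibble::tibble(time_tau = t, percolating_x = percx, percolating_y = percy,
                   largest_cluster_frac = frac, n_tubules = ntub)
  }
  n <- 50
  # durable both-direction network with 0.9 coverage, protrusion at 60 tau
  net <- mk(rep(TRUE, n), rep(TRUE, n), rep(0.9, n),
            c(rep(0, 30), rep(2, 20)))
  expect_equal(classify_pathway(net), "net")
  # percolation for only 10 tau before fragmenting, then protrusion
  part <- mk(c(rep(TRUE, 5), rep(FALSE, n - 5)),
             c(rep(TRUE, 5), rep(FALSE, n - 5)),
             c(rep(0.9, 5), rep(0.2, n - 5)), c(rep(0, 30), rep(2, 20)))
  expect_equal(classify_pathway(part), "part")
  # percolating in one direction only: fails the full-network test
  part2 <- mk(rep(TRUE, n), rep(FALSE, n), rep(0.9, n),
              c(rep(0, 30), rep(2, 20)))
  expect_equal(classify_pathway(part2), "part")
  # no percolation at all before the protrusion
  iso <- mk(rep(FALSE, n), rep(FALSE, n), rep(0.15, n),
            c(rep(0, 30), rep(2, 20)))
  expect_equal(classify_pathway(iso), "iso")
  # short series with no protrusion cannot be classified
  und <- mk(rep(FALSE, 5), rep(FALSE, 5), rep(0.1, 5), rep(0, 5),
            t = seq(0, 8, by = 2))
  expect_equal(classify_pathway(und), "undetermined")
})

test_that("tubule detector recovers fixture count, radius and direction", {
  ft <- make_fixture("ideal_tubule", p_o, radius = 3, length = 20)
  tb <- detect_tubules(ft$state, p_o)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$R_tb, 3, tolerance = 0.2 / 3)
  # flat equilibrium sheet: no tubules
  sheet <- build_flat_membrane(400, p_o, seed = 2)
  expect_equal(nrow(detect_tubules(sheet, p_o)), 0)
  # two disjoint tubules with different radii
  ft2 <- make_fixture("ideal_tubule", p_o, radius = c(3, 4),
                      length = c(20, 18),
                      centers = rbind(c(11, 11), c(33, 33)))
  tb2 <- detect_tubules(ft2$state, p_o)
  expect_equal(nrow(tb2), 2)
  expect_equal(sort(tb2$R_tb), c(3, 4), tolerance = 0.1)
})

test_that("first protrusion time requires persistence", {
  t <- seq(0, 18, by = 2)
  expect_true(is.na(first_protrusion_time(rep(0, 10), t)))
  expect_equal(first_protrusion_time(c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1), t), 4)
  # a transient blip does not count
  expect_equal(first_protrusion_time(c(0, 1, 0, 0, 1, 1, 1, 1, 1, 1), t), 8)
})

test_that("kappa estimator recovers synthetic ground truth across rigidities", {
  for (k_in in c(10, 15, 30, 60)) {
    fr <- gen_height_frames(k_in, nframes = 250, seed = k_in)
    fit <- estimate_kappa(fr, p_o)
    expect_equal(fit$kappa, k_in, tolerance = 0.05)
  }
})

test_that("diffusion estimator: recovery, ballistic rejection, tau scaling", {
  fr <- gen_brownian_frames(D = 0.1, nframes = 150, npart = 2000, seed = 2)
  fit <- estimate_diffusion(fr, p_o, fit_window = c(0.02, 0.2))
  expect_equal(fit$D, 0.1, tolerance = 0.03)
  expect_equal(fit$tau, p_o$r_rod^2 / fit$D)
  # tau scales as r_rod^2 at fixed D
  p2 <- membrane_params(r_rod = 20, N_sg = 10)
  fit2 <- estimate_diffusion(fr, p2, fit_window = c(0.02, 0.2))
  expect_equal(fit2$tau / fit$tau, 4)
  # ballistic walkers have slope 2: must raise the no-linear-regime error
  ball <- lapply(1:40, function(f) {
    particle_state(tibble::tibble(type = "membrane",
                                  x = (seq(1, 30, length.out = 50) + 0.3 * f) %% 40,
                                  y = 20, z = 0, ux = 0, uy = 0, uz = 1),
                   box = c(40, 40, 60), time = f * 5)
  })
  expect_error(estimate_diffusion(ball, p_o), "diffusive")
})

test_that("critical tension bracketing with an injected trial", {
  # surrogate physics: tubulation iff gamma < 55, independent of seed
  runner <- function(gamma, seed) gamma < 55
  r <- measure_critical_tension(seq(0, 100, by = 10), runner, seeds = 3)
  expect_equal(r$gamma_star, 55, tolerance = 5)
  expect_lte(r$lower, 55)
  expect_gte(r$upper, 55)
  # refinement tightens the bracket around the same transition
  r2 <- measure_critical_tension(seq(0, 100, by = 10), runner, refine = 4)
  expect_equal(r2$gamma_star, 55, tolerance = 0.7)
  expect_error(measure_critical_tension(c(80, 90), runner), "bracket")
})
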