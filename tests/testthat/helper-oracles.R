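# Independent oracles and small fixtures used across the suite.

# brute-force transitive closure on rod centre-of-mass distances
brute_force_clusters <- function(coms, box, threshold) {
  n <- nrow(coms)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- coms[j, ] - coms[i, ]
      d <- d - box * round(d / box)
      adj[i, j] <- sqrt(sum(d^2)) < threshold
    }
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in which(adj[i, ])) {
        if (lab[j] != lab[i]) {
          m <- min(lab[i], lab[j])
          lab[lab == lab[i] | lab == lab[j]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# spectral generator for Gaussian height fields with known bending rigidity;
# continuum convention <|a_cell * FFT(h)|^2> = A * kT / (kappa q^4)
gen_height_frames <- function(kappa, L = 48, ncell = 24, nframes = 300,
                              seed = 1, kT = 1) {
  set.seed(seed)
  A <- L^2
  Ncell <- ncell^2
  acell <- A / Ncell
  qv <- 2 * pi / L * c(0:(ncell %/% 2), -((ncell - ncell %/% 2 - 1):1))
  q2 <- outer(qv^2, qv^2, `+`)
  s <- sqrt(A * kT / (kappa * q2^2 * acell^2 * Ncell))
  s[q2 == 0] <- 0
  xy <- expand.grid(x = (0:(ncell - 1) + 0.5) * L / ncell,
                    y = (0:(ncell - 1) + 0.5) * L / ncell)
  lapply(seq_len(nframes), function(f) {
    W <- stats::fft(matrix(stats::rnorm(Ncell), ncell))
    h <- Re(stats::fft(W * s, inverse = TRUE)) / Ncell
    particle_state(
      tibble::tibble(type = "membrane", x = xy$x, y = xy$y, z = as.vector(h),
                     ux = 0, uy = 0, uz = 1),
      box = c(L, L, 60), time = f)
  })
}

# 2D Brownian walkers with known diffusion coefficient, wrapped into the box
gen_brownian_frames <- function(D, nframes = 60, npart = 200, dt_frame = 5,
                                L = 40, seed = 1) {
  set.seed(seed)
  x <- stats::runif(npart, 0, L)
  y <- stats::runif(npart, 0, L)
  lapply(seq_len(nframes), function(f) {
    if (f > 1) {
      x <<- x + stats::rnorm(npart, 0, sqrt(2 * D * dt_frame))
      y <<- y + stats::rnorm(npart, 0, sqrt(2 * D * dt_frame))
    }
    particle_state(
      tibble::tibble(type = "membrane", x = x %% L, y = y %% L, z = 0,
                     ux = 0, uy = 0, uz = 1),
      box = c(L, L, 60), time = (f - 1) * dt_frame)
  })
}

# random rod-only state: n_rod straight rods at random in-plane positions
random_rod_state <- function(n_rod, params, box = c(40, 40, 60), seed = 1,
                             z_sd = 0) {
  set.seed(seed)
  coms <- cbind(stats::runif(n_rod, 0, box[1]), stats::runif(n_rod, 0, box[2]),
                stats::rnorm(n_rod, 0, z_sd))
  ang <- stats::runif(n_rod, 0, 2 * pi)
  dirs <- cbind(cos(ang), sin(ang), 0)
  chains <- lapply(seq_len(n_rod), function(r) {
    s <- (seq_len(params$N_sg) - (params$N_sg + 1) / 2) * params$bond_length
    tibble::tibble(type = "rod", rod = r, seg = seq_len(params$N_sg),
                   x = coms[r, 1] + s * dirs[r, 1],
                   y = coms[r, 2] + s * dirs[r, 2],
                   z = coms[r, 3],
                   ux = 0, uy = 0, uz = 1)
  })
  particle_state(dplyr::bind_rows(chains), box = box)
}

# small mixed membrane+rod system for gradient tests
small_mixed_state <- function(params, n = 100, n_rod = 2, seed = 3) {
  st <- build_flat_membrane(n, params, a0 = 1.45, seed = seed)
  seed_rods(st, n_rod, params, seed = seed + 1)
}

# central-difference gradient of the potential at particle i
numerical_force <- function(state, params, i, h = 1e-5) {
  out <- numeric(3)
  for (k in 1:3) {
    cc <- c("x", "y", "z")[k]
    s1 <- state; s1[[cc]][i] <- s1[[cc]][i] + h
    s2 <- state; s2[[cc]][i] <- s2[[cc]][i] - h
    out[k] <- -(potential_energy(s1, params)$total -
                  potential_energy(s2, params)$total) / (2 * h)
  }
  out
}
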