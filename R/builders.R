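#' Build a flat periodic membrane patch
#'
#' Places `n` membrane particles on a triangular lattice in the z = 0 plane at
#' a spacing that realises the requested area per particle, with orientations
#' along +z and a small positional jitter to break the lattice symmetry. The
#' box is periodic in x and y; the z extent is tall enough that protruding
#' tubules never reach their own periodic image.
#'
#' @param n Number of particles. Must factor into `nx * ny` columns/rows with
#'   `ny` even (the triangular lattice needs an even row count for
#'   periodicity).
#' @param params A [membrane_params()] object.
#' @param a0 Target area per particle (sigma^2). The default is the measured
#'   tensionless area per particle of the calibrated model.
#' @param lz Box height (sigma).
#' @param jitter Amplitude of the uniform positional jitter (sigma).
#' @param seed RNG seed for the jitter.
#' @return A `particle_state`.
#' @export
build_flat_membrane <- function(n, params, a0 = 1.75, lz = 60,
                                jitter = 0.01, seed = 1L) {
  a <- sqrt(2 * a0 / sqrt(3)) # lattice constant realising a0 exactly
  if (a < params$sigma) {
    stop("box too small: requested area per particle needs spacing < sigma",
         call. = FALSE)
  }
  facs <- divisor_pairs(n)
  facs <- facs[facs[, 2] %% 2 == 0, , drop = FALSE]
  if (nrow(facs) == 0) {
    stop("n has no nx * ny factorisation with even ny", call. = FALSE)
  }
  aspect <- facs[, 1] * a / (facs[, 2] * a * sqrt(3) / 2)
  best <- facs[which.min(abs(log(aspect))), ]
  nx <- best[1]; ny <- best[2]
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  x <- (ix + 0.5 * (iy %% 2)) * a
  y <- iy * a * sqrt(3) / 2
  set.seed(seed)
  jx <- stats::runif(n, -jitter, jitter)
  jy <- stats::runif(n, -jitter, jitter)
  jz <- stats::runif(n, -jitter, jitter)
  particle_state(
    tibble::tibble(type = "membrane",
                   x = x + jx, y = y + jy, z = jz,
                   ux = 0, uy = 0, uz = 1),
    box = c(nx * a, ny * a * sqrt(3) / 2, lz))
}

divisor_pairs <- function(n) {
  d <- seq_len(floor(sqrt(n)))
  d <- d[n %% d == 0]
  d <- sort(unique(c(d, n / d)))
  cbind(nx = n / d, ny = d)
}

#' Build a quasi-uniform spherical vesicle
#'
#' Distributes `n` particles on a Fibonacci lattice over a sphere of radius
#' `r_ves`, with orientations pointing radially outward. The solvent-free
#' model has no volume constraint, so the enclosed volume is free to change
#' during dynamics.
#'
#' @param n Number of particles.
#' @param r_ves Vesicle radius (sigma).
#' @param params A [membrane_params()] object.
#' @param jitter Amplitude of tangential jitter (sigma).
#' @param seed RNG seed.
#' @param box_pad Clearance between the vesicle and the box faces (sigma).
#' @return A `particle_state`.
#' @export
build_vesicle <- function(n, r_ves, params, jitter = 0.01, seed = 1L,
                          box_pad = 15) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  phi <- 2 * pi * i / golden
  cost <- 1 - 2 * i / n
  sint <- sqrt(pmax(0, 1 - cost^2))
  u <- cbind(sint * cos(phi), sint * sin(phi), cost)
  set.seed(seed)
  jit <- matrix(stats::runif(3 * n, -jitter, jitter), ncol = 3)
  jit <- jit - u * rowSums(jit * u) # keep the jitter tangential
  pos <- u * r_ves + jit
  L <- 2 * (r_ves + box_pad)
  particle_state(
    tibble::tibble(type = "membrane",
                   x = pos[, 1] + L / 2, y = pos[, 2] + L / 2,
                   z = pos[, 3] + L / 2,
                   ux = u[, 1], uy = u[, 2], uz = u[, 3]),
    box = c(L, L, L))
}

#' Convert membrane-particle runs into protein rods
#'
#' Selects `n_rod` non-overlapping, approximately straight runs of `N_sg`
#' adjacent in-surface particles and relabels them as rods, assigning rod ids
#' and segment order and leaving every particle position unchanged. The rod
#' area density is then exactly `phi_rod = n_rod * N_sg / n`.
#'
#' Rows are reordered so that each rod occupies consecutive rows in chain
#' order (membrane particles follow), which is the layout the chain topology
#' requires.
#'
#' @param state A `particle_state` with membrane particles only.
#' @param n_rod Number of rods to seed.
#' @param params A [membrane_params()] object.
#' @param seed RNG seed.
#' @param max_tries Placement attempts before giving up.
#' @return A `particle_state` with `n_rod * N_sg` rod particles.
#' @export
seed_rods <- function(state, n_rod, params, seed = 1L, max_tries = 200 * n_rod) {
  n <- nrow(state)
  n_sg <- params$N_sg
  if (n_rod * n_sg > n) stop("n_rod * N_sg exceeds particle count", call. = FALSE)
  box <- state_box(state)
  pos <- cbind(state$x, state$y, state$z)
  ori <- cbind(state$ux, state$uy, state$uz)
  ell <- params$bond_length
  # periodic spatial hash for nearest-neighbour queries
  cell <- 1.2 * params$sigma
  ncell <- pmax(1L, floor(box / cell))
  cello <- box / ncell
  cidx <- function(pm) { # matrix -> wrapped integer cell coords
    sapply(1:3, function(d) {
      as.integer(floor((pm[, d] %% box[d]) / cello[d])) %% ncell[d]
    })
  }
  hash <- split(seq_len(n), do.call(paste, as.data.frame(cidx(pos))))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lookup <- function(q) {
    base <- cidx(matrix(q, 1))
    kk <- unique(paste((base[1] + offs[, 1]) %% ncell[1],
                       (base[2] + offs[, 2]) %% ncell[2],
                       (base[3] + offs[, 3]) %% ncell[3]))
    unlist(hash[kk], use.names = FALSE)
  }
  claimed <- logical(n)
  set.seed(seed)
  rods <- vector("list", n_rod)
  placed <- 0L
  tries <- 0L
  while (placed < n_rod && tries < max_tries) {
    tries <- tries + 1L
    start <- sample.int(n, 1)
    if (claimed[start]) next
    u0 <- ori[start, ]
    # random in-surface direction at the start particle
    rnd <- stats::rnorm(3)
    d <- rnd - sum(rnd * u0) * u0
    d <- d / sqrt(sum(d^2))
    run <- integer(n_sg)
    run[1] <- start
    ok <- TRUE
    p_cur <- pos[start, ]
    d_cur <- d
    for (k in 2:n_sg) {
      target <- p_cur + ell * d_cur
      cand <- lookup(target %% box)
      cand <- cand[!claimed[cand] & !(cand %in% run)]
      if (length(cand) == 0) { ok <- FALSE; break }
      disp <- t(vapply(cand, function(j) min_image_disp(target, pos[j, ], box),
                       numeric(3)))
      dd <- sqrt(rowSums(disp^2))
      jbest <- cand[which.min(dd)]
      if (min(dd) > 0.75 * params$sigma) { ok <- FALSE; break }
      run[k] <- jbest
      step <- min_image_disp(p_cur, pos[jbest, ], box)
      u_loc <- ori[jbest, ]
      step <- step - sum(step * u_loc) * u_loc # stay in the local surface
      d_cur <- step / sqrt(sum(step^2))
      p_cur <- p_cur + min_image_disp(p_cur, pos[jbest, ], box)
    }
    if (!ok) next
    claimed[run] <- TRUE
    placed <- placed + 1L
    rods[[placed]] <- run
  }
  if (placed < n_rod) {
    stop(sprintf(paste("could only place %d of %d rods without overlap;",
                       "consider a lower phi_rod"), placed, n_rod),
         call. = FALSE)
  }
  rod_idx <- unlist(rods)
  state$rod <- NA_integer_
  state$seg <- NA_integer_
  state$type[rod_idx] <- "rod"
  state$rod[rod_idx] <- rep(seq_len(n_rod), each = n_sg)
  state$seg[rod_idx] <- rep(seq_len(n_sg), times = n_rod)
  ord <- order(!is.na(state$rod) * -1L, state$rod, state$seg)
  out <- state[ord, ]
  attributes(out)[c("box", "periodic", "time")] <-
    attributes(state)[c("box", "periodic", "time")]
  class(out) <- class(state)
  out
}

#' Hand-constructed fixture configurations with known ground truth
#'
#' Builds configurations whose cluster decomposition, percolation flags or
#' tubule geometry are known by construction, for validating the observables.
#'
#' Kinds:
#' * `ideal_tubule`: a flat patch with one or more cylindrical protrusions of
#'   known radius and length.
#' * `hex_network`: rods on a six-coordinated (triangular) lattice whose
#'   nearest-neighbour spacing is below the clustering threshold, spanning
#'   the periodic box in both directions.
#' * `striped_array`: parallel rows of rods; each row spans x only.
#' * `known_clusters`: rods at caller-specified centres of mass (default: two
#'   rods closer than the clustering threshold).
#'
#' @param kind Fixture kind.
#' @param params A [membrane_params()] object.
#' @param radius,length Tubule radius/length (sigma), for `ideal_tubule`.
#' @param centers Matrix of tubule (x, y) centres or rod centres of mass
#'   (x, y, z); defaults per kind.
#' @param lattice Rod centre spacing (sigma) for the lattice fixtures.
#' @param n_rows Number of rows for `striped_array`.
#' @param box_xy Lateral box size (sigma) for the rod-only fixtures.
#' @param seed RNG seed for the patch jitter.
#' @return A list with `state` and `truth` (a list of ground-truth values).
#' @export
make_fixture <- function(kind = c("ideal_tubule", "hex_network",
                                  "striped_array", "known_clusters"),
                         params = membrane_params(),
                         radius = 3, length = 20, centers = NULL,
                         lattice = 4, n_rows = 2, box_xy = 40, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    ideal_tubule = fixture_tubule(params, radius, length, centers, seed),
    hex_network = fixture_hex(params, lattice, box_xy),
    striped_array = fixture_stripes(params, lattice, n_rows, box_xy),
    known_clusters = fixture_known(params, centers, box_xy))
}

fixture_tubule <- function(params, radius, length, centers, seed) {
  a <- 1.1
  patch <- build_flat_membrane(40 * 40, params, a0 = sqrt(3) / 2 * a^2,
                               lz = max(60, 2 * length + 20),
                               jitter = 0.01, seed = seed)
  box <- state_box(patch)
  if (is.null(centers)) centers <- matrix(box[1:2] / 2, ncol = 2)
  radius <- rep_len(radius, nrow(centers))
  length <- rep_len(length, nrow(centers))
  keep <- rep(TRUE, nrow(patch))
  tubes <- list()
  for (t in seq_len(nrow(centers))) {
    ctr <- centers[t, ]
    d <- sqrt((patch$x - ctr[1])^2 + (patch$y - ctr[2])^2)
    keep <- keep & d > radius[t] + 0.5
    nring <- max(6L, round(2 * pi * radius[t] / a))
    nz <- max(2L, round(length[t] / (sqrt(3) / 2 * a)))
    zs <- seq(0, length[t], length.out = nz)
    ang <- lapply(seq_along(zs), function(iz) {
      2 * pi * (seq_len(nring) - 1 + 0.5 * (iz %% 2)) / nring
    })
    tubes[[t]] <- tibble::tibble(
      type = "membrane",
      x = ctr[1] + radius[t] * cos(unlist(ang)),
      y = ctr[2] + radius[t] * sin(unlist(ang)),
      z = rep(zs, each = nring),
      ux = cos(unlist(ang)), uy = sin(unlist(ang)), uz = 0)
  }
  df <- dplyr::bind_rows(c(list(tibble::as_tibble(patch)[keep, ]), tubes))
  st <- particle_state(df, box = box)
  list(state = st,
       truth = list(n_tubules = nrow(centers), R_tb = radius,
                    length = length))
}

rod_chain <- function(com, dir, params) {
  n_sg <- params$N_sg
  ell <- params$bond_length
  s <- (seq_len(n_sg) - (n_sg + 1) / 2) * ell
  tibble::tibble(type = "rod",
                 x = com[1] + s * dir[1], y = com[2] + s * dir[2],
                 z = com[3] + s * dir[3],
                 ux = 0, uy = 0, uz = 1)
}

rods_state <- function(coms, dirs, params, box) {
  n_rod <- nrow(coms)
  chains <- lapply(seq_len(n_rod), function(r) {
    ch <- rod_chain(coms[r, ], dirs[r, ], params)
    ch$rod <- r
    ch$seg <- seq_len(params$N_sg)
    ch
  })
  particle_state(dplyr::bind_rows(chains), box = box)
}

fixture_hex <- function(params, lattice, box_xy) {
  nx <- max(3L, round(box_xy / lattice))
  ny <- max(4L, 2L * round(box_xy / (lattice * sqrt(3))))
  Lx <- nx * lattice
  Ly <- ny * lattice * sqrt(3) / 2
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  coms <- cbind((ix + 0.5 * (iy %% 2)) * lattice, iy * lattice * sqrt(3) / 2, 0)
  dirs <- matrix(rep(c(1, 0, 0), nrow(coms)), ncol = 3, byrow = TRUE)
  st <- rods_state(coms, dirs, params, box = c(Lx, Ly, 60))
  list(state = st,
       truth = list(n_clusters = 1L, percolating = c(x = TRUE, y = TRUE)))
}

fixture_stripes <- function(params, lattice, n_rows, box_xy) {
  nx <- max(3L, round(box_xy / lattice))
  Lx <- nx * lattice
  Ly <- box_xy
  gap <- Ly / n_rows # rows far apart: each row is its own cluster
  coms <- do.call(rbind, lapply(seq_len(n_rows), function(rw) {
    cbind((seq_len(nx) - 1) * lattice, (rw - 0.5) * gap, 0)
  }))
  dirs <- matrix(rep(c(0, 1, 0), nrow(coms)), ncol = 3, byrow = TRUE)
  st <- rods_state(coms, dirs, params, box = c(Lx, Ly, 60))
  list(state = st,
       truth = list(n_clusters = n_rows,
                    percolating = c(x = TRUE, y = FALSE)))
}

fixture_known <- function(params, centers, box_xy) {
  if (is.null(centers)) {
    centers <- rbind(c(10, 10, 0), c(10 + 0.4 * params$r_rod, 10, 0))
    truth <- list(n_clusters = 1L, sizes = 2L)
  } else {
    truth <- NULL
  }
  dirs <- matrix(rep(c(1, 0, 0), nrow(centers)), ncol = 3, byrow = TRUE)
  st <- rods_state(centers, dirs, params, box = c(box_xy, box_xy, 60))
  list(state = st, truth = truth)
}
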