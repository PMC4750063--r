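#' Bending rigidity from the height-fluctuation spectrum
#'
#' Grids the membrane height field h(x, y), Fourier transforms it, and reads
#' the bending rigidity from the small-q behaviour of the spectrum,
#' `<|h_q|^2> = kT / (A (kappa q^4 + gamma q^2))`, with the frame tension
#' `gamma` fixed at its measured value (0 for a tensionless run). Frames in
#' which some grid cell is empty (torn or strongly overhanging membrane) are
#' rejected; more than `max_reject` rejection is an error. The error bar is a
#' bootstrap over frames.
#'
#' @param frames A list of `particle_state` frames of a flat, rod-free
#'   membrane, all with the same box.
#' @param params A [membrane_params()] object.
#' @param bin Grid bin size (sigma).
#' @param q_max Upper edge of the fitted q window (1/sigma).
#' @param gamma Frame tension fixed in the fit (kT/sigma^2).
#' @param n_boot Bootstrap replicates over frames.
#' @param max_reject Maximum tolerated fraction of rejected frames.
#' @return A `kappa_fit` object: list with `kappa`, `se`, `n_frames`,
#'   `n_modes` and the per-mode `spectrum` tibble.
#' @export
estimate_kappa <- function(frames, params, bin = 2,
                           q_max = 2 * pi / (5 * params$sigma), gamma = 0,
                           n_boot = 100, max_reject = 0.2) {
  stopifnot(length(frames) >= 2)
  box <- state_box(frames[[1]])
  nx <- max(4L, floor(box[1] / bin))
  ny <- max(4L, floor(box[2] / bin))
  A <- box[1] * box[2]
  acell <- A / (nx * ny)
  grid_frame <- function(st) {
    b <- state_box(st)
    if (max(abs(b[1:2] - box[1:2]) / box[1:2]) > 0.01) {
      stop("frames must share the same projected box (within 1%)", call. = FALSE)
    }
    gx <- pmin(nx - 1L, floor((st$x %% b[1]) / b[1] * nx))
    gy <- pmin(ny - 1L, floor((st$y %% b[2]) / b[2] * ny))
    cell <- gx + nx * gy
    z <- st$z - mean(st$z)
    h <- rowsum(z, cell)
    cnt <- rowsum(rep(1, length(cell)), cell)
    if (nrow(h) < nx * ny) return(NULL) # empty cell: reject the frame
    m <- matrix(0, nx, ny)
    m[cbind(as.integer(rownames(h)) %% nx + 1L,
            as.integer(rownames(h)) %/% nx + 1L)] <- h / cnt
    m
  }
  qx <- 2 * pi / box[1] * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  qy <- 2 * pi / box[2] * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  q2 <- outer(qx^2, qy^2, `+`)
  sel <- which(q2 > 0 & sqrt(q2) <= q_max)
  if (length(sel) < 3) stop("q window contains too few modes", call. = FALSE)
  spec <- matrix(NA_real_, length(frames), length(sel))
  rejected <- 0L
  for (f in seq_along(frames)) {
    m <- grid_frame(frames[[f]])
    if (is.null(m)) { rejected <- rejected + 1L; next }
    H <- stats::fft(m) * acell
    spec[f, ] <- (Mod(H)^2)[sel]
  }
  if (rejected / length(frames) > max_reject) {
    stop(sprintf("%d of %d frames rejected (empty grid cells)",
                 rejected, length(frames)), call. = FALSE)
  }
  spec <- spec[stats::complete.cases(spec), , drop = FALSE]
  kT <- params$kT
  kappa_from <- function(rows) {
    sbar <- colMeans(spec[rows, , drop = FALSE])
    mean((kT * A / sbar - gamma * q2[sel]) / q2[sel]^2)
  }
  nfr <- nrow(spec)
  kap <- kappa_from(seq_len(nfr))
  boot <- replicate(n_boot, kappa_from(sample.int(nfr, nfr, replace = TRUE)))
  sbar <- colMeans(spec)
  spectrum <- tibble::tibble(q = sqrt(q2[sel]), S = sbar,
                             kappa_q = (kT * A / sbar - gamma * q2[sel]) /
                               q2[sel]^2)
  structure(list(kappa = kap, se = stats::sd(boot), n_frames = nfr,
                 n_modes = length(sel), rejected = rejected,
                 spectrum = spectrum, gamma = gamma, kT = kT, area = A),
            class = "kappa_fit")
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf("<kappa_fit> kappa/kT = %.3g +/- %.2g (%d frames, %d modes)\n",
              x$kappa / x$kT, x$se / x$kT, x$n_frames, x$n_modes))
  invisible(x)
}

#' In-plane diffusion coefficient and the time unit tau
#'
#' Unwraps particle trajectories across the periodic boundaries, computes the
#' in-plane mean-square displacement over multiple time origins and fits the
#' linear regime `MSD = 4 D t`. The regime must be diffusive: the log-log
#' slope over the fitted window must be 1 within `slope_tol` and the linear
#' fit must achieve R^2 >= `r2_min`, otherwise an error is raised. The time
#' unit is `tau = r_rod^2 / D`.
#'
#' @param frames A list of `particle_state` frames at uniform time spacing.
#' @param params A [membrane_params()] object.
#' @param fit_window Fraction of the lag range used for the fit (from
#'   `fit_window[1]` to `fit_window[2]` of the maximum lag).
#' @param slope_tol Allowed deviation of the log-log slope from 1.
#' @param r2_min Minimum R^2 of the linear fit.
#' @return A `diffusion_fit` object with `D`, `tau` and the `msd` tibble.
#' @export
estimate_diffusion <- function(frames, params, fit_window = c(0.1, 0.5),
                               slope_tol = 0.15, r2_min = 0.99) {
  stopifnot(length(frames) >= 5)
  box <- state_box(frames[[1]])
  times <- vapply(frames, state_time, numeric(1))
  n <- nrow(frames[[1]])
  # unwrap via frame-to-frame minimum-image displacements
  xy <- array(0, c(length(frames), n, 2))
  xy[1, , ] <- cbind(frames[[1]]$x, frames[[1]]$y)
  for (f in 2:length(frames)) {
    dx <- frames[[f]]$x - frames[[f - 1]]$x
    dy <- frames[[f]]$y - frames[[f - 1]]$y
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    xy[f, , 1] <- xy[f - 1, , 1] + dx
    xy[f, , 2] <- xy[f - 1, , 2] + dy
  }
  lags <- seq_len(length(frames) - 1)
  msd <- vapply(lags, function(L) {
    o <- seq_len(length(frames) - L)
    d <- xy[o + L, , , drop = FALSE] - xy[o, , , drop = FALSE]
    mean(d^2) * 2 # x,y averaged then summed: mean over both comps * 2
  }, numeric(1))
  tl <- times[1 + lags] - times[1]
  msd_tb <- tibble::tibble(lag_time = tl, msd = msd)
  w <- which(tl >= fit_window[1] * max(tl) & tl <= fit_window[2] * max(tl))
  if (length(w) < 3) stop("too few lags in the fit window", call. = FALSE)
  # weight lags by the number of time origins entering each average
  wts <- length(frames) - lags[w]
  ll <- stats::lm(log(msd[w]) ~ log(tl[w]), weights = wts)
  slope <- stats::coef(ll)[2]
  lin <- stats::lm(msd[w] ~ tl[w], weights = wts)
  r2 <- summary(lin)$r.squared
  if (abs(slope - 1) > slope_tol || r2 < r2_min) {
    stop(sprintf(paste("no diffusive regime: log-log slope %.3f, R^2 %.4f;",
                       "expected slope 1 and R^2 >= %.2f"),
                 slope, r2, r2_min), call. = FALSE)
  }
  D <- unname(stats::coef(lin)[2]) / 4
  structure(list(D = D, tau = params$r_rod^2 / D, slope = unname(slope),
                 r2 = r2, msd = msd_tb),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g sigma^2/time, tau = %.4g (slope %.3f, R2 %.4f)\n",
              x$D, x$tau, x$slope, x$r2))
  invisible(x)
}

#' Critical tension by bracketing
#'
#' Runs the supplied tubulation trial over a grid of imposed tensions and
#' returns the midpoint between the largest tension at which tubulation still
#' occurs and the smallest at which it is suppressed, together with the
#' bracketing interval. Optional bisection steps refine the bracket.
#'
#' @param gammas Increasing grid of tensions (kT/sigma^2).
#' @param runner Function `(gamma, seed) -> logical` returning whether
#'   tubulation occurred. [make_tubulation_runner()] builds one from a system
#'   specification; tests may inject a surrogate.
#' @param seeds Seeds per grid point; the majority vote decides.
#' @param refine Number of bisection refinements of the bracket.
#' @return A list with `gamma_star`, `lower`, `upper` and the trial `table`.
#' @export
measure_critical_tension <- function(gammas, runner, seeds = 1L, refine = 0L) {
  gammas <- sort(gammas)
  vote <- function(g) {
    res <- vapply(seq_len(seeds), function(s) isTRUE(runner(g, s)), logical(1))
    mean(res) > 0.5
  }
  tub <- vapply(gammas, vote, logical(1))
  tab <- tibble::tibble(gamma = gammas, tubulated = tub)
  if (all(tub) || !any(tub)) {
    stop("no bracket: tubulation state identical across the whole gamma grid",
         call. = FALSE)
  }
  lo <- max(gammas[tub])
  hi <- min(gammas[!tub & gammas > lo])
  if (!is.finite(hi)) {
    stop("grid is not ordered around the transition", call. = FALSE)
  }
  for (i in seq_len(refine)) {
    mid <- (lo + hi) / 2
    t <- vote(mid)
    tab <- dplyr::bind_rows(tab, tibble::tibble(gamma = mid, tubulated = t))
    if (t) lo <- mid else hi <- mid
  }
  list(gamma_star = (lo + hi) / 2, lower = lo, upper = hi,
       table = dplyr::arrange(tab, .data$gamma))
}

#' Build a tubulation trial for [measure_critical_tension()]
#'
#' @param n,n_rod System size and rod count for the flat patch.
#' @param params Production [membrane_params()].
#' @param t_equil,t_prod,frame_interval Protocol durations (raw simulation
#'   time unless `tau` is given).
#' @param tau Optional time-unit calibration.
#' @return A function `(gamma, seed) -> logical`.
#' @export
make_tubulation_runner <- function(n, n_rod, params, t_equil, t_prod,
                                   frame_interval, tau = NULL) {
  function(gamma, seed) {
    st <- build_flat_membrane(n, params, seed = seed)
    st <- seed_rods(st, n_rod, params, seed = seed)
    pr <- run_protocol(st, params,
                       protocol_spec(t_equil, t_prod, frame_interval,
                                     seed = seed),
                       ensemble = ensemble_spec(gamma = gamma), tau = tau)
    any(pr$obs$n_tubules > 0, na.rm = TRUE)
  }
}

#' Calibrate the bending stiffness to a target rigidity
#'
#' Adjusts `k_bend` by secant iteration until the measured bending rigidity
#' of the tensionless bare membrane falls inside `target +/- tol`, measuring
#' kappa with [estimate_kappa()] on a fresh simulation at each step.
#'
#' @param params Starting [membrane_params()].
#' @param target Target kappa (kT).
#' @param tol Acceptance half-width (kT).
#' @param n Patch size used for the calibration runs.
#' @param n_frames Spectrum frames per measurement.
#' @param steps_equil,steps_frame Integration steps for equilibration and
#'   between frames.
#' @param max_iter Secant iterations.
#' @param seed RNG seed.
#' @param verbose Print one line per iteration.
#' @return A list with calibrated `params`, final `kappa_fit` and the
#'   iteration `history` tibble.
#' @export
calibrate_bending <- function(params, target = 15, tol = 1, n = 1024,
                              n_frames = 150, steps_equil = 20000,
                              steps_frame = 200, max_iter = 6, seed = 1L,
                              verbose = FALSE) {
  measure <- function(p, sd) {
    st <- build_flat_membrane(n, p, seed = sd)
    st <- langevin_run(st, p, steps_equil, seed = sd,
                       ensemble = ensemble_spec(gamma = 0))
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      st <- langevin_run(st, p, steps_frame, seed = sd * 1000 + f)
      frames[[f]] <- st
    }
    estimate_kappa(frames, p)
  }
  hist <- list()
  k <- params$k_bend
  fit <- measure(params, seed)
  hist[[1]] <- tibble::tibble(iter = 0L, k_bend = k, kappa = fit$kappa,
                              se = fit$se)
  if (verbose) message(sprintf("iter 0: k_bend %.3g -> kappa %.3g", k, fit$kappa))
  k_prev <- k; kap_prev <- fit$kappa
  it <- 0L
  while (abs(fit$kappa - target) > tol && it < max_iter) {
    it <- it + 1L
    # kappa grows roughly linearly with k_bend; secant on the residual
    k_new <- if (it == 1L) {
      k * target / fit$kappa
    } else {
      k - (fit$kappa - target) * (k - k_prev) / (fit$kappa - kap_prev)
    }
    k_new <- max(1, min(100, k_new))
    k_prev <- k; kap_prev <- fit$kappa
    k <- k_new
    params$k_bend <- k
    fit <- measure(params, seed + it)
    hist[[it + 1]] <- tibble::tibble(iter = it, k_bend = k, kappa = fit$kappa,
                                     se = fit$se)
    if (verbose) {
      message(sprintf("iter %d: k_bend %.3g -> kappa %.3g +/- %.2g",
                      it, k, fit$kappa, fit$se))
    }
  }
  list(params = params, fit = fit, history = dplyr::bind_rows(hist),
       converged = abs(fit$kappa - target) <= tol)
}

#' Area per particle and area compression modulus
#'
#' From the projected-area series of a constant-tension run:
#' `a0 = <A>/N` and `K_A = kT <A> / var(A)`.
#'
#' @param areas Numeric vector of sampled projected areas.
#' @param n Number of particles.
#' @param kT Thermal energy.
#' @return A tibble with `a0` and `K_A`.
#' @export
area_statistics <- function(areas, n, kT = 1) {
  tibble::tibble(a0 = mean(areas) / n,
                 K_A = kT * mean(areas) / stats::var(areas))
}
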