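#' Broom-style tidiers
#'
#' `tidy()` returns per-component estimates, `glance()` a one-row model
#' summary, for the package's fitted objects.
#'
#' @param x A fitted object (`kappa_fit`, `diffusion_fit`, `cluster_report`,
#'   `rod_protocol` or `delta_f_curve`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.kappa_fit <- function(x, ...) {
  tibble::tibble(term = "kappa", estimate = x$kappa, std.error = x$se)
}

#' @rdname tidiers
#' @export
glance.kappa_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, se = x$se, n_frames = x$n_frames,
                 n_modes = x$n_modes, rejected = x$rejected, gamma = x$gamma)
}

#' @rdname tidiers
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("D", "tau"), estimate = c(x$D, x$tau))
}

#' @rdname tidiers
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D = x$D, tau = x$tau, slope = x$slope, r.squared = x$r2)
}

#' @rdname tidiers
#' @export
tidy.cluster_report <- function(x, ...) {
  dplyr::left_join(x$clusters, x$sizes, by = "cluster")
}

#' @rdname tidiers
#' @export
glance.cluster_report <- function(x, ...) {
  perc <- percolation_check(x)
  tibble::tibble(n_rod = x$n_rod, n_clusters = nrow(x$sizes),
                 mean_size_weighted = mean_cluster_size(x),
                 mean_size_number = mean_cluster_size(x, "number"),
                 percolating_x = perc$x, percolating_y = perc$y)
}

#' @rdname tidiers
#' @export
tidy.rod_protocol <- function(x, ...) x$obs

#' @rdname tidiers
#' @export
glance.rod_protocol <- function(x, ...) {
  obs <- x$obs
  prot <- if ("n_tubules" %in% names(obs)) {
    first_protrusion_time(obs$n_tubules, obs$time_tau)
  } else {
    NA_real_
  }
  tibble::tibble(
    frames = nrow(obs), t_end_tau = max(obs$time_tau),
    first_protrusion_tau = prot,
    pathway = if ("percolating_x" %in% names(obs)) classify_pathway(obs)
              else NA_character_)
}

#' @rdname tidiers
#' @export
tidy.delta_f_curve <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @export
glance.delta_f_curve <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(phi_rod = p$phi_rod, C_side = p$C_side,
                 min_C1 = attr(x, "min_C1"), min_dF = attr(x, "min_dF"))
}
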