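#' Parameters of the geometric array model
#'
#' The analytic model compares the curvature energy of two idealised rod
#' assemblies on a membrane: a striped (unbranched, parallel) array and a
#' hexagonal (branched network) array. Rod assemblies are rectangles of width
#' `r_rod` with bending rigidities `kappa_r1` along the rod axis and
#' `kappa_r2` perpendicular to it; the bare membrane has rigidity `kappa`.
#' Curvatures are naturally quoted in units of `1/r_rod` (the default
#' `r_rod = 1`).
#'
#' @param phi_rod Area fraction of the rod assemblies, in (0, 1) for the
#'   striped array and (0, 0.5] for the hexagonal array.
#' @param kappa Bare-membrane bending rigidity (kT).
#' @param kappa_r1 Rod-assembly rigidity along the rod axis (kT).
#' @param kappa_r2 Rod-assembly rigidity perpendicular to the rod axis (kT).
#' @param C_rod,C_side Rod spontaneous curvatures (1/r_rod).
#' @param r_rod Rod length, the model's length unit.
#' @return An `array_params` object.
#' @export
array_params <- function(phi_rod, kappa = 15, kappa_r1 = 40, kappa_r2 = 15,
                         C_rod = 0, C_side = 0, r_rod = 1) {
  if (phi_rod <= 0 || phi_rod >= 1) {
    stop("phi_rod must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(kappa > 0, kappa_r1 > 0, kappa_r2 > 0, r_rod > 0)
  structure(list(phi_rod = phi_rod, kappa = kappa, kappa_r1 = kappa_r1,
                 kappa_r2 = kappa_r2, C_rod = C_rod, C_side = C_side,
                 r_rod = r_rod),
            class = "array_params")
}

#' Curvature energy density of the striped array
#'
#' Rod strips (area fraction `phi_rod`) are cylindrically curved with `C_1`
#' along the rod axis and flat perpendicular to it; the bare strips between
#' them curve back with `-C_2`, where normal-vector continuity across the
#' pattern fixes `C_2 = phi_rod * C_1 / (1 - phi_rod)`. Energies are per unit
#' projected area, non-dimensionalised by `r_rod^2`.
#'
#' @param C1 Curvature along the rod axis (1/r_rod); vectorised.
#' @param p An [array_params()] object.
#' @return `F_st` values (kT per projected area times r_rod^2).
#' @export
striped_energy <- function(C1, p) {
  stopifnot(inherits(p, "array_params"))
  if (any(C1 < 0)) stop("C1 must be >= 0", call. = FALSE)
  phi <- p$phi_rod
  C2 <- phi * C1 / (1 - phi)
  r2 <- p$r_rod^2
  r2 * (phi * (p$kappa_r1 / 2 * (C1 - p$C_rod)^2 +
                 p$kappa_r2 / 2 * (0 - p$C_side)^2) +
          (1 - phi) * p$kappa / 2 * C2^2)
}

#' Geometry of the hexagonal (branched network) array
#'
#' The network is a honeycomb of rod-assembly rectangles (region I, length
#' `L_h - r_rod/sqrt(3)`, width `r_rod`), equilateral vertex triangles of
#' side `r_rod` (region II) and interior hexagons of side
#' `L_h - r_rod/sqrt(3)` (region III). The flat-pattern areas close exactly
#' and fixing the region-I area fraction to `phi_rod` yields
#' `L_h = r_rod (1 + sqrt(1 - 2 phi_rod)) / (sqrt(3) phi_rod)`, which
#' requires `phi_rod <= 1/2`.
#'
#' Region I is a saddle with curvature `C_1` along the rod axis and `-C_3`
#' perpendicular; regions II and III are spherical caps of curvature `C_1`
#' (continuity with the strip ends) and `-C_4`. Normal-vector continuity
#' along the two lattice directions gives
#' `C_3 = C_4 = C_1 r_rod / (sqrt(3) L_1)` with `L_1 = L_h - r_rod/sqrt(3)`.
#' The vertex cap angle closes as `theta_2 = pi/3 - C_1 r_rod / 2`; at
#' `theta_2 = 0` the three strip-end arcs wrap the full vertex and `C_1`
#' attains its maximum `2 pi / (3 r_rod)`.
#'
#' @param C1 Curvature along the rod axis (1/r_rod); vectorised.
#' @param p An [array_params()] object with `phi_rod <= 0.5`.
#' @return A tibble with `C_1`, `theta_2`, `C_3`, `C_4`, `L_h` and the area
#'   fractions `a_I`, `a_II`, `a_III`.
#' @export
hex_constraints <- function(C1, p) {
  stopifnot(inherits(p, "array_params"))
  r <- p$r_rod
  if (p$phi_rod > 0.5) {
    stop("the hexagonal array exists only for phi_rod <= 1/2", call. = FALSE)
  }
  cmax <- 2 * pi / (3 * r)
  if (any(C1 < 0 | C1 >= cmax)) {
    stop("C1 must lie in [0, 2*pi/(3*r_rod))", call. = FALSE)
  }
  phi <- p$phi_rod
  Lh <- r * (1 + sqrt(1 - 2 * phi)) / (sqrt(3) * phi)
  L1 <- Lh - r / sqrt(3)
  C3 <- C1 * r / (sqrt(3) * L1)
  a_tot <- 3 * sqrt(3) / 2 * Lh^2
  tibble::tibble(C_1 = C1,
                 theta_2 = pi / 3 - C1 * r / 2,
                 C_3 = C3, C_4 = C3,
                 L_h = Lh,
                 a_I = 3 * r * L1 / a_tot,
                 a_II = (sqrt(3) / 2 * r^2) / a_tot,
                 a_III = (3 * sqrt(3) / 2 * L1^2) / a_tot)
}

#' Curvature energy density of the hexagonal array
#'
#' Area-weighted sum of the saddle energy of the rod rectangles (region I)
#' and the spherical-cap energies of regions II and III, per unit projected
#' area times `r_rod^2`. The first (rod-axis) term is identical to the
#' striped array's, so their difference is independent of `C_rod` and
#' `kappa_r1`.
#'
#' @inheritParams hex_constraints
#' @return `F_hex` values.
#' @export
hex_energy <- function(C1, p) {
  g <- hex_constraints(C1, p)
  r2 <- p$r_rod^2
  # region I carries exactly phi_rod by the choice of L_h; using phi_rod
  # directly makes the rod-axis term cancel bitwise against the striped array
  r2 * (p$phi_rod * (p$kappa_r1 / 2 * (C1 - p$C_rod)^2 +
                   p$kappa_r2 / 2 * (-g$C_3 - p$C_side)^2) +
          g$a_II * p$kappa / 2 * (2 * C1)^2 +
          g$a_III * p$kappa / 2 * (2 * g$C_4)^2)
}

#' Energy difference between hexagonal and striped arrays
#'
#' Evaluates `delta_F = F_hex - F_st` on a grid of `C_1` and refines the
#' minimiser by golden-section/parabolic search. A negative minimum means the
#' branched network is locally favoured over the unbranched array.
#'
#' @param p An [array_params()] object.
#' @param C1 Grid of rod-axis curvatures; default covers the full domain.
#' @param tol Minimisation tolerance.
#' @return A `delta_f_curve`: tibble with `C_1`, `F_st`, `F_hex`, `dF`, and
#'   attributes `min_C1`, `min_dF`, `params`.
#' @export
delta_F <- function(p, C1 = NULL, tol = 1e-10) {
  cmax <- 2 * pi / (3 * p$r_rod)
  if (is.null(C1)) C1 <- seq(0, cmax * (1 - 1e-9), length.out = 512)
  fst <- striped_energy(C1, p)
  fhex <- hex_energy(C1, p)
  # both arrays share the same rod-axis curvature C_1, so the
  # kappa_r1 (C_1 - C_rod)^2 terms cancel algebraically: evaluate the
  # difference in its cancelled form (exactly independent of C_rod, kappa_r1)
  f <- function(c1) {
    g <- hex_constraints(c1, p)
    phi <- p$phi_rod
    C2 <- phi * c1 / (1 - phi)
    p$r_rod^2 *
      (phi * p$kappa_r2 / 2 * ((-g$C_3 - p$C_side)^2 - p$C_side^2) +
         g$a_II * p$kappa / 2 * (2 * c1)^2 +
         g$a_III * p$kappa / 2 * (2 * g$C_4)^2 -
         (1 - phi) * p$kappa / 2 * C2^2)
  }
  df <- f(C1)
  i0 <- which.min(df)
  lo <- C1[max(1, i0 - 1)]
  hi <- C1[min(length(C1), i0 + 1)]
  opt <- if (lo < hi) stats::optimize(f, c(lo, hi), tol = tol) else
    list(minimum = C1[i0], objective = df[i0])
  # one-sided search can beat the interior optimum at the domain edge
  if (df[i0] < opt$objective) opt <- list(minimum = C1[i0], objective = df[i0])
  out <- tibble::tibble(C_1 = C1, F_st = fst, F_hex = fhex, dF = df)
  structure(out, min_C1 = opt$minimum, min_dF = opt$objective, params = p,
            class = c("delta_f_curve", class(out)))
}

#' @export
print.delta_f_curve <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<delta_f_curve> phi = %.3g, C_side = %.3g: min dF = %.4g at C_1 = %.4g\n",
              p$phi_rod, p$C_side, attr(x, "min_dF"), attr(x, "min_C1")))
  NextMethod()
}

#' Network-formation threshold density
#'
#' The hexagonal edge length `L_h(phi_rod)` grows as the rod density falls;
#' a percolated network can only form spontaneously if rod assemblies reach
#' length `L_h` before tubulation starts. Given the assembly extent reachable
#' at tubulation onset, this returns the density at which `L_h` equals that
#' extent.
#'
#' @param p An [array_params()] object (its `phi_rod` is ignored).
#' @param onset_extent Linear extent (in `r_rod`) of the largest assembly at
#'   tubulation onset.
#' @param tol Bisection tolerance on `phi_rod`.
#' @return A list with `phi_threshold`, `bounded` flag, and the `L_h` curve.
#' @export
critical_network_density <- function(p, onset_extent, tol = 1e-8) {
  r <- p$r_rod
  Lh <- function(phi) r * (1 + sqrt(1 - 2 * phi)) / (sqrt(3) * phi)
  grid <- tibble::tibble(phi_rod = seq(0.01, 0.5, by = 0.005))
  grid$L_h <- Lh(grid$phi_rod)
  lo_val <- Lh(0.5) # smallest attainable L_h (phi at the domain edge)
  if (onset_extent <= lo_val) {
    return(list(phi_threshold = 0.5, bounded = FALSE, curve = grid))
  }
  root <- stats::uniroot(function(phi) Lh(phi) - onset_extent,
                         c(1e-6, 0.5), tol = tol)
  list(phi_threshold = root$root, bounded = TRUE, curve = grid)
}
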