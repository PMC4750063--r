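#' Detect membrane tubules
#'
#' Flat geometry: particles higher than `h_min` above the median plane mark a
#' protrusion. Candidates above the lower measurement threshold `h_meas` are
#' clustered by single linkage at `link`; a component counts as a tubule when
#' at least `min_particles` of its particles exceed `h_min`. The tubule axis
#' is the principal axis of the component, the radius `R_tb` is the mean
#' cylindrical radius of the distal (> `h_min`) particles about that axis,
#' and the length is the component extent along the axis plus `h_meas`.
#' Vesicle geometry: the same applied to the signed radial excess over the
#' fitted sphere, the sign giving the direction (outward/inward).
#'
#' All thresholds are exposed; the defaults are validated against constructed
#' fixtures with known tubule count and radius.
#'
#' @param state A `particle_state`.
#' @param params A [membrane_params()] object.
#' @param geometry `"flat"` or `"vesicle"`.
#' @param h_min Detection height over the reference surface (sigma);
#'   default `1.5 * r_rod`.
#' @param h_meas Lower threshold bounding the measured tubule body (sigma).
#' @param link Single-linkage distance for candidate particles (sigma).
#' @param min_particles Minimum number of distal particles per tubule.
#' @return A tibble with one row per tubule: `tubule`, `n`, `R_tb`, `length`,
#'   `direction`.
#' @export
detect_tubules <- function(state, params, geometry = c("flat", "vesicle"),
                           h_min = 1.5 * params$r_rod,
                           h_meas = 0.5 * params$r_rod, link = 1.5,
                           min_particles = 30L) {
  geometry <- match.arg(geometry)
  box <- state_box(state)
  pos <- cbind(state$x, state$y, state$z)
  if (geometry == "flat") {
    excess <- state$z - stats::median(state$z)
    sides <- list(outward = excess)
  } else {
    ctr <- colMeans(pos)
    rad <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
    excess <- rad - mean(rad)
    sides <- list(outward = excess, inward = -excess)
  }
  out <- list()
  for (dir in names(sides)) {
    ex <- sides[[dir]]
    cand <- which(ex > h_meas)
    if (length(cand) == 0) next
    p <- pos[cand, , drop = FALSE]
    pr <- neighbor_pairs_cpp(p, box, link)
    g <- igraph::graph_from_edgelist(pr, directed = FALSE)
    if (igraph::vcount(g) < nrow(p)) {
      g <- igraph::add_vertices(g, nrow(p) - igraph::vcount(g))
    }
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      ix <- which(comp$membership == cid)
      distal <- ex[cand[ix]] > h_min
      if (sum(distal) < min_particles) next
      q <- p[ix, , drop = FALSE]
      # unwrap about the first member (components are spatially compact)
      for (d in 1:3) {
        dd <- q[, d] - q[1, d]
        q[, d] <- q[1, d] + dd - box[d] * round(dd / box[d])
      }
      q <- sweep(q, 2, colMeans(q))
      sv <- svd(q)
      axis <- sv$v[, 1]
      proj <- as.numeric(q %*% axis)
      radial <- sqrt(rowSums((q - outer(proj, axis))^2))
      out[[length(out) + 1]] <- tibble::tibble(
        n = length(ix), R_tb = mean(radial[distal]),
        length = diff(range(proj)) + h_meas,
        direction = dir)
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else {
    tibble::tibble(n = integer(0), R_tb = numeric(0), length = numeric(0),
                   direction = character(0))
  }
  dplyr::bind_cols(tibble::tibble(tubule = seq_len(nrow(res))), res)
}
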