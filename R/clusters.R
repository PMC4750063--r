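#' Rod centres of mass with chain unwrapping
#'
#' Each rod chain is unwrapped by accumulating minimum-image bond vectors from
#' its first segment, so rods crossing a periodic boundary get a consistent
#' centre of mass (wrapped back into the box at the end).
#'
#' @param state A `particle_state` containing rods.
#' @param params A [membrane_params()] object.
#' @return A tibble with `rod`, `x, y, z` (wrapped COM) and the list-column
#'   `segs` of unwrapped segment coordinate matrices.
#' @export
rod_centres <- function(state, params) {
  if (!any(state$type == "rod")) {
    stop("state contains no rods", call. = FALSE)
  }
  box <- state_box(state)
  rows <- which(!is.na(state$rod))
  pos <- cbind(state$x, state$y, state$z)
  by_rod <- split(rows, state$rod[rows])
  res <- lapply(by_rod, function(ix) {
    ix <- ix[order(state$seg[ix])]
    p <- pos[ix, , drop = FALSE]
    if (nrow(p) > 1) {
      steps <- diff(p)
      steps <- steps - rep(box, each = nrow(p) - 1) *
        round(steps / rep(box, each = nrow(p) - 1))
      cum <- apply(steps, 2, cumsum)
      if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
      p <- rbind(p[1, ], sweep(cum, 2, p[1, ], `+`))
    }
    list(com = colMeans(p), segs = p)
  })
  com <- do.call(rbind, lapply(res, `[[`, "com"))
  tibble::tibble(rod = as.integer(names(by_rod)),
                 x = com[, 1] - box[1] * floor(com[, 1] / box[1]),
                 y = com[, 2] - box[2] * floor(com[, 2] / box[2]),
                 z = com[, 3],
                 segs = lapply(res, `[[`, "segs"))
}

#' Single-linkage rod clusters
#'
#' Two rods belong to the same cluster when their centres of mass are closer
#' (minimum-image) than `r_rod / 2`; clusters are the connected components of
#' that contact graph.
#'
#' @param state A `particle_state` with at least one rod.
#' @param params A [membrane_params()] object.
#' @param threshold Linkage threshold; default `r_rod / 2`.
#' @return A `cluster_report`: list with `clusters` (tibble rod -> cluster),
#'   `sizes`, `n_rod`, `coms`, `edges` (with minimum-image displacement
#'   vectors), `threshold`, `box` and `time`.
#' @export
find_rod_clusters <- function(state, params, threshold = params$r_rod / 2) {
  centres <- rod_centres(state, params)
  n_rod <- nrow(centres)
  box <- state_box(state)
  pos <- cbind(centres$x, centres$y, centres$z)
  pr <- neighbor_pairs_cpp(pos, box, threshold)
  disp <- matrix(0, nrow(pr), 3)
  if (nrow(pr) > 0) {
    for (d in 1:3) {
      dd <- pos[pr[, 2], d] - pos[pr[, 1], d]
      disp[, d] <- dd - box[d] * round(dd / box[d])
    }
  }
  g <- igraph::graph_from_edgelist(pr, directed = FALSE)
  if (igraph::vcount(g) < n_rod) {
    g <- igraph::add_vertices(g, n_rod - igraph::vcount(g))
  }
  comp <- igraph::components(g)
  membership <- comp$membership[seq_len(n_rod)]
  clusters <- tibble::tibble(rod = centres$rod,
                             cluster = as.integer(membership))
  sizes <- dplyr::count(clusters, .data$cluster, name = "n")
  structure(list(clusters = clusters, sizes = sizes, n_rod = n_rod,
                 coms = centres, edges = list(pairs = pr, disp = disp),
                 threshold = threshold, box = box,
                 time = state_time(state)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d rods in %d clusters, <N_cl> = %.3g\n",
              x$n_rod, nrow(x$sizes), mean_cluster_size(x)))
  invisible(x)
}

#' Mean cluster size
#'
#' The default is the weight-averaged size `sum(n_i^2) / sum(n_i)` — the size
#' of the cluster a randomly chosen rod sits in — which is dominated by a
#' percolated cluster when one exists. The number average `mean(n_i)` is
#' available as an option.
#'
#' @param report A `cluster_report`.
#' @param weighting `"weight"` (default) or `"number"`.
#' @return The mean cluster size (rods).
#' @export
mean_cluster_size <- function(report, weighting = c("weight", "number")) {
  weighting <- match.arg(weighting)
  n <- report$sizes$n
  if (weighting == "weight") sum(n^2) / sum(n) else mean(n)
}

#' Root-mean-square cluster height
#'
#' For each cluster the height variance is the mean of
#' `(z_segment - z_cm)^2` over all rod segments in the cluster, with `z_cm`
#' the z of the cluster's centre of mass; the reported `z_cl` is the square
#' root of the (unweighted) average of the per-cluster variances.
#'
#' @param state A `particle_state` (flat geometry: z is the height).
#' @param params A [membrane_params()] object.
#' @param report Optional precomputed `cluster_report`.
#' @return A list with `z_cl` and `per_cluster` (tibble of cluster, n_rods,
#'   variance).
#' @export
cluster_height <- function(state, params, report = NULL) {
  if (is.null(report)) report <- find_rod_clusters(state, params)
  segs_z <- lapply(report$coms$segs, function(p) p[, 3])
  cl <- report$clusters$cluster
  per <- lapply(split(seq_along(segs_z), cl), function(ix) {
    z <- unlist(segs_z[ix])
    zc <- mean(z) # centre of mass over all segments of the cluster
    c(n_rods = length(ix), variance = mean((z - zc)^2))
  })
  per <- do.call(rbind, per)
  per_cluster <- tibble::tibble(cluster = as.integer(rownames(per)),
                                n_rods = per[, "n_rods"],
                                variance = per[, "variance"])
  list(z_cl = sqrt(mean(per_cluster$variance)), per_cluster = per_cluster)
}

#' Percolation of rod clusters through the periodic boundaries
#'
#' A cluster percolates in x (or y) when, following minimum-image
#' displacements along its linkage edges, some rod connects back to its own
#' periodic image with a nonzero winding number in that direction.
#'
#' @param report A `cluster_report` from [find_rod_clusters()].
#' @return A list with logical `x`, `y` (any cluster percolating) and
#'   `per_cluster`, a tibble of flags per cluster.
#' @export
percolation_check <- function(report) {
  n <- report$n_rod
  pr <- report$edges$pairs
  disp <- report$edges$disp
  box <- report$box
  adj <- vector("list", n)
  if (nrow(pr) > 0) {
    for (k in seq_len(nrow(pr))) {
      a <- pr[k, 1]; b <- pr[k, 2]
      adj[[a]] <- c(adj[[a]], list(c(b, disp[k, ])))
      adj[[b]] <- c(adj[[b]], list(c(a, -disp[k, ])))
    }
  }
  cl <- report$clusters$cluster
  wind <- matrix(FALSE, max(cl), 2)
  pos <- matrix(NA_real_, n, 3)
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    pos[root, ] <- 0
    visited[root] <- TRUE
    queue <- root
    while (length(queue) > 0) {
      u <- queue[[1]]; queue <- queue[-1]
      for (e in adj[[u]]) {
        v <- e[1]; d <- e[2:4]
        cand <- pos[u, ] + d
        if (!visited[v]) {
          pos[v, ] <- cand
          visited[v] <- TRUE
          queue <- c(queue, v)
        } else {
          w <- round((cand - pos[v, ]) / box)
          if (w[1] != 0) wind[cl[u], 1] <- TRUE
          if (w[2] != 0) wind[cl[u], 2] <- TRUE
        }
      }
    }
  }
  per_cluster <- tibble::tibble(cluster = seq_len(nrow(wind)),
                                percolating_x = wind[, 1],
                                percolating_y = wind[, 2])
  per_cluster <- per_cluster[per_cluster$cluster %in% cl, ]
  list(x = any(wind[, 1]), y = any(wind[, 2]), per_cluster = per_cluster)
}

#' Classify the tubulation pathway of a run
#'
#' Pathways: `net` — a percolated network covering the membrane (a cluster
#' percolating in both directions and holding at least `theta_large` of all
#' rods) persists for at least `persist_tau` before the first protrusion;
#' `part` — percolation occurs before the first protrusion but fails the
#' coverage or persistence test; `iso` — no percolation before the first
#' protrusion. Returns `"undetermined"` for a series shorter than
#' `persist_tau` with no protrusion.
#'
#' @param obs Observable tibble from [run_protocol()] (columns `time_tau`,
#'   `percolating_x`, `percolating_y`, `largest_cluster_frac`, `n_tubules`).
#' @param theta_large Coverage threshold as a fraction of all rods.
#' @param persist_tau Persistence requirement (tau) for the `net` label.
#' @param persist_frames Consecutive frames required for a protrusion to
#'   count.
#' @return A character label: `"net"`, `"part"`, `"iso"` or `"undetermined"`.
#' @export
classify_pathway <- function(obs, theta_large = 0.5, persist_tau = 20,
                             persist_frames = 5L) {
  t <- obs$time_tau
  prot <- first_protrusion_time(obs$n_tubules, t, persist_frames)
  horizon <- if (is.na(prot)) max(t) else prot
  if (is.na(prot) && max(t) < persist_tau) return("undetermined")
  pre <- obs[t <= horizon, ]
  perc_any <- pre$percolating_x | pre$percolating_y
  if (!any(perc_any)) return("iso")
  full <- pre$percolating_x & pre$percolating_y &
    pre$largest_cluster_frac >= theta_large
  # longest maintained stretch of full-network frames before the protrusion
  r <- rle(full)
  spans <- r$lengths[r$values]
  if (length(spans) > 0) {
    dt_frame <- stats::median(diff(t))
    if (max(spans) * dt_frame >= persist_tau) return("net")
  }
  "part"
}

#' First protrusion time of a tubule-count series
#'
#' @param counts Integer vector of per-frame tubule counts.
#' @param times Frame times (tau).
#' @param persist_frames Consecutive frames a detection must persist.
#' @return The earliest time whose detection persists, or `NA`.
#' @export
first_protrusion_time <- function(counts, times, persist_frames = 5L) {
  on <- counts >= 1
  if (length(on) < persist_frames) return(NA_real_)
  run <- stats::filter(as.numeric(on), rep(1, persist_frames), sides = 1)
  hit <- which(run == persist_frames)
  if (length(hit) == 0) return(NA_real_)
  times[hit[1] - persist_frames + 1]
}
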