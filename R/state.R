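#' Particle states as tibbles
#'
#' A particle state is a tibble with one row per particle and columns
#' `type` ("membrane" or "rod"), `rod` (rod id, `NA` for membrane particles),
#' `seg` (position along the rod chain, `NA` for membrane particles),
#' positions `x, y, z`, unit orientation vectors `ux, uy, uz`, velocities
#' `vx, vy, vz` and angular velocities `wx, wy, wz`. The simulation box (three
#' edge lengths), periodicity flags and the frame time are carried as
#' attributes `box`, `periodic` and `time`.
#'
#' @param df A data frame with at least `type, x, y, z, ux, uy, uz`.
#' @param box Numeric length-3 box edge lengths.
#' @param periodic Logical length-3 periodicity flags.
#' @param time Frame time.
#' @return A `particle_state` tibble.
#' @export
particle_state <- function(df, box, periodic = c(TRUE, TRUE, TRUE), time = 0) {
  df <- tibble::as_tibble(df)
  for (col in c("vx", "vy", "vz", "wx", "wy", "wz")) {
    if (!col %in% names(df)) df[[col]] <- 0
    df[[col]][is.na(df[[col]])] <- 0
  }
  if (!"rod" %in% names(df)) df$rod <- NA_integer_
  if (!"seg" %in% names(df)) df$seg <- NA_integer_
  df <- df[, c("type", "rod", "seg", "x", "y", "z", "ux", "uy", "uz",
               "vx", "vy", "vz", "wx", "wy", "wz")]
  out <- structure(df, box = as.numeric(box), periodic = as.logical(periodic),
                   time = as.numeric(time),
                   class = c("particle_state", class(df)))
  validate_state(out)
}

#' @rdname particle_state
#' @param state A `particle_state` tibble.
#' @export
validate_state <- function(state) {
  stopifnot(is.data.frame(state))
  box <- attr(state, "box")
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("state must carry a positive length-3 'box' attribute", call. = FALSE)
  }
  un <- sqrt(state$ux^2 + state$uy^2 + state$uz^2)
  if (any(abs(un - 1) > 1e-9)) {
    stop("orientation vectors must be unit length (|u| - 1 <= 1e-9)",
         call. = FALSE)
  }
  if (!all(state$type %in% c("membrane", "rod"))) {
    stop("particle types must be 'membrane' or 'rod'", call. = FALSE)
  }
  if (any(state$type == "rod" & is.na(state$rod))) {
    stop("rod particles must carry a rod id", call. = FALSE)
  }
  invisible(state)
}

state_box <- function(state) attr(state, "box")
state_time <- function(state) attr(state, "time")

#' Rod topology of a state
#'
#' Derives the chain topology from the `rod`/`seg` columns: each rod must have
#' exactly `N_sg` particles stored in consecutive rows ordered by `seg`; bonds
#' join consecutive segments and angles join consecutive bond pairs.
#'
#' @param state A `particle_state`.
#' @param params A [membrane_params()] object.
#' @return A list with `rod_membership` (particle -> rod id, NA for membrane),
#'   `bonds` (two-column matrix of 1-based particle indices), `angles`
#'   (three-column matrix), `n_rod` and `phi_rod`.
#' @export
rod_topology <- function(state, params) {
  rid <- state$rod
  rods <- sort(unique(rid[!is.na(rid)]))
  n_sg <- params$N_sg
  bonds <- matrix(integer(0), ncol = 2)
  angles <- matrix(integer(0), ncol = 3)
  if (length(rods) > 0) {
    idx_by_rod <- split(seq_len(nrow(state))[!is.na(rid)], rid[!is.na(rid)])
    for (ix in idx_by_rod) {
      if (length(ix) != n_sg) {
        stop("each rod must have exactly N_sg particles", call. = FALSE)
      }
      if (any(diff(ix) != 1L)) {
        stop("rod particles must occupy consecutive rows in chain order",
             call. = FALSE)
      }
    }
    bonds <- do.call(rbind, lapply(idx_by_rod, function(ix) {
      cbind(ix[-length(ix)], ix[-1])
    }))
    angles <- do.call(rbind, lapply(idx_by_rod, function(ix) {
      if (length(ix) < 3) return(matrix(integer(0), ncol = 3))
      cbind(ix[1:(length(ix) - 2)], ix[2:(length(ix) - 1)], ix[3:length(ix)])
    }))
  }
  list(rod_membership = rid, bonds = bonds, angles = angles,
       n_rod = length(rods),
       phi_rod = length(rods) * n_sg / nrow(state))
}

# internal: matrices + 0-based topology for the C++ kernels
state_matrices <- function(state, params) {
  topo <- rod_topology(state, params)
  rid <- topo$rod_membership
  rid[is.na(rid)] <- 0L
  list(
    pos = cbind(state$x, state$y, state$z),
    ori = cbind(state$ux, state$uy, state$uz),
    vel = cbind(state$vx, state$vy, state$vz),
    angv = cbind(state$wx, state$wy, state$wz),
    rodid = as.integer(rid),
    bonds = matrix(as.integer(topo$bonds - 1L), ncol = 2),
    angles = matrix(as.integer(topo$angles - 1L), ncol = 3),
    box = state_box(state)
  )
}

# internal: write matrices back into a state tibble
state_from_matrices <- function(state, pos, ori, vel, angv, box = NULL,
                                time = NULL) {
  state$x <- pos[, 1]; state$y <- pos[, 2]; state$z <- pos[, 3]
  state$ux <- ori[, 1]; state$uy <- ori[, 2]; state$uz <- ori[, 3]
  state$vx <- vel[, 1]; state$vy <- vel[, 2]; state$vz <- vel[, 3]
  state$wx <- angv[, 1]; state$wy <- angv[, 2]; state$wz <- angv[, 3]
  if (!is.null(box)) attr(state, "box") <- as.numeric(box)
  if (!is.null(time)) attr(state, "time") <- as.numeric(time)
  state
}

#' Wrap particle positions into the primary box image
#'
#' @param state A `particle_state`.
#' @return The state with coordinates wrapped into `[0, L)` in each periodic
#'   direction.
#' @export
wrap_state <- function(state) {
  box <- state_box(state)
  per <- attr(state, "periodic")
  for (i in seq_len(3)) {
    if (!per[i]) next
    col <- c("x", "y", "z")[i]
    state[[col]] <- state[[col]] - box[i] * floor(state[[col]] / box[i])
  }
  state
}

#' Minimum-image displacement between two points
#'
#' @param a,b Numeric length-3 coordinates.
#' @param box Length-3 box edges.
#' @return The displacement `b - a` folded into the minimum image.
#' @export
min_image_disp <- function(a, b, box) {
  d <- b - a
  d - box * round(d / box)
}

#' @export
print.particle_state <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("<particle_state> %d particles (%d rod), box %.3g x %.3g x %.3g, t = %.4g\n",
              nrow(x), sum(x$type == "rod"), box[1], box[2], box[3],
              attr(x, "time")))
  NextMethod()
}
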