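#' Write and read trajectories in the package's extended-XYZ dialect
#'
#' Each frame is an XYZ block: a particle-count line, a comment line of
#' `key=value` tokens (`time`, `box`, `periodic`, `c_rod`, `c_side`,
#' `columns`) and one row per particle with columns
#' `type rod seg x y z ux uy uz` (`rod`/`seg` are `-` for membrane
#' particles). Values are written with 17 significant digits, so a
#' write-read round trip reproduces positions and orientations exactly.
#'
#' @param frames A list of `particle_state` frames (or a single state).
#' @param file Output path.
#' @param params Optional [membrane_params()]; records the curvatures in the
#'   comment line.
#' @return `write_trajectory()` returns `file` invisibly; `read_trajectory()`
#'   returns a list of `particle_state` frames.
#' @export
write_trajectory <- function(frames, file, params = NULL) {
  if (inherits(frames, "particle_state")) frames <- list(frames)
  con <- file(file, "w")
  on.exit(close(con))
  for (st in frames) {
    box <- state_box(st)
    per <- attr(st, "periodic")
    crod <- if (is.null(params)) NA else params$C_rod
    cside <- if (is.null(params)) NA else params$C_side
    writeLines(as.character(nrow(st)), con)
    writeLines(sprintf(
      'time=%.17g box="%.17g %.17g %.17g" periodic="%d %d %d" c_rod=%g c_side=%g columns=type:rod:seg:x:y:z:ux:uy:uz',
      state_time(st), box[1], box[2], box[3], per[1], per[2], per[3],
      crod, cside), con)
    rod <- ifelse(is.na(st$rod), "-", as.character(st$rod))
    seg <- ifelse(is.na(st$seg), "-", as.character(st$seg))
    writeLines(sprintf("%s %s %s %.17g %.17g %.17g %.17g %.17g %.17g",
                       st$type, rod, seg, st$x, st$y, st$z,
                       st$ux, st$uy, st$uz), con)
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n <= 0) {
      stop(sprintf("line %d: expected a particle count, got '%s'", i, lines[i]),
           call. = FALSE)
    }
    if (!is.na(n_ref) && n != n_ref) {
      stop(sprintf("line %d: particle count %d differs from first frame (%d)",
                   i, n, n_ref), call. = FALSE)
    }
    n_ref <- n
    hdr <- lines[i + 1L]
    grab <- function(key, quoted = FALSE) {
      pat <- if (quoted) sprintf('%s="([^"]*)"', key) else
        sprintf("%s=([^ ]+)", key)
      m <- regmatches(hdr, regexec(pat, hdr))[[1]]
      if (length(m) < 2) {
        stop(sprintf("line %d: malformed header, missing '%s'", i + 1L, key),
             call. = FALSE)
      }
      m[2]
    }
    tm <- as.numeric(grab("time"))
    box <- as.numeric(strsplit(grab("box", TRUE), " +")[[1]])
    per <- as.integer(strsplit(grab("periodic", TRUE), " +")[[1]]) == 1L
    cols <- strsplit(grab("columns"), ":")[[1]]
    if (!identical(cols, c("type", "rod", "seg", "x", "y", "z",
                           "ux", "uy", "uz"))) {
      stop(sprintf(paste("line %d: unsupported column layout '%s'",
                         "(plain XYZ without orientations is rejected)"),
                   i + 1L, paste(cols, collapse = ":")), call. = FALSE)
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), " +")
    bad <- which(lengths(tok) != 9L)
    if (length(bad) > 0) {
      stop(sprintf("line %d: expected 9 columns", i + 1L + bad[1]),
           call. = FALSE)
    }
    tk <- matrix(unlist(tok), ncol = 9, byrow = TRUE)
    num <- apply(tk[, 4:9, drop = FALSE], 2, as.numeric)
    if (anyNA(num)) {
      stop(sprintf("non-numeric coordinate in frame starting at line %d", i),
           call. = FALSE)
    }
    un <- sqrt(rowSums(num[, 4:6, drop = FALSE]^2))
    if (any(abs(un - 1) > 1e-6)) {
      stop(sprintf("line %d: non-unit orientation vector",
                   i + 1L + which(abs(un - 1) > 1e-6)[1]), call. = FALSE)
    }
    num[, 4:6] <- num[, 4:6] / un # remove rounding-level drift
    df <- tibble::tibble(
      type = tk[, 1],
      rod = suppressWarnings(as.integer(ifelse(tk[, 2] == "-", NA, tk[, 2]))),
      seg = suppressWarnings(as.integer(ifelse(tk[, 3] == "-", NA, tk[, 3]))),
      x = num[, 1], y = num[, 2], z = num[, 3],
      ux = num[, 4], uy = num[, 5], uz = num[, 6])
    frames[[length(frames) + 1L]] <-
      particle_state(df, box = box, periodic = per, time = tm)
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("no frames found in file", call. = FALSE)
  frames
}

#' Run manifest
#'
#' A JSON record sufficient to re-run a simulation bit-identically on the
#' same platform: full parameter echo, seed, package version, wall time and
#' the inventory (with MD5 checksums) of the produced files.
#'
#' @param params A [membrane_params()] object.
#' @param seed RNG seed of the run.
#' @param files Character vector of output files to inventory.
#' @param extra Named list of additional metadata (protocol, ensemble, ...).
#' @param file Optional output path; when given the JSON is written there.
#' @return The manifest as a named list (invisibly if written).
#' @export
run_manifest <- function(params, seed, files = character(0), extra = list(),
                         file = NULL) {
  man <- c(list(
    package = "bartube",
    version = as.character(utils::packageVersion("bartube")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = unclass(params),
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })), extra)
  if (!is.null(file)) {
    jsonlite::write_json(man, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
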