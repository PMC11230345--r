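#' Run configurations
#'
#' A run configuration bundles a parameter set (preset name plus
#' overrides), command settings and a seed, and serialises losslessly to a
#' YAML file so every run can be reproduced from the file written next to
#' its outputs.
#'
#' @param preset preset name (see [preset_params()]) or NULL when
#'   \code{params} is given explicitly.
#' @param params explicit parameter list (overrides applied on top of the
#'   preset).
#' @param settings named list of command-specific settings (durations,
#'   grids, labels, ...).
#' @param seed integer seed.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(preset = NULL, params = list(), settings = list(),
                       seed = 1L) {
  stopifnot(is.list(params), is.list(settings))
  structure(list(preset = preset, params = params, settings = settings,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(preset = x$preset,
             params = if (is.null(x$params)) list() else x$params,
             settings = if (is.null(x$settings)) list() else x$settings,
             seed = if (is.null(x$seed)) 1L else x$seed)
}

#' @rdname run_config
#' @export
resolve_params <- function(config) {
  if (!is.null(config$preset))
    do.call(preset_params, c(list(name = config$preset), config$params))
  else do.call(bead_params, config$params)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

#' Trajectory I/O
#'
#' \code{write_trajectory_csv} writes a trajectory as plain CSV (header
#' comment lines carry the seed, dt and config metadata; columns are the
#' time, one partner column per bead with 0 = unbound, and the flattened
#' bead-major coordinates).  \code{read_trajectory_csv} reads it back;
#' \code{write_xyz} exports the frames in XYZ format for molecular
#' viewers.
#'
#' @param traj a \code{"switching_trajectory"}.
#' @param path output file.
#' @param params parameters used to rebuild the trajectory on read.
#' @param every write every this many frames (XYZ export).
#' @return The path, invisibly (writers); a trajectory (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  n <- traj$params$n_beads; d <- traj$params$dim
  hdr <- c(sprintf("# switchbeads trajectory: n_beads=%d dim=%d", n, d),
           sprintf("# dt=%.17g record_every=%d seed=%s", traj$dt,
                   traj$record_every,
                   if (is.null(traj$seed)) "NA" else as.character(traj$seed)))
  cols <- c("t", paste0("partner", seq_len(n)),
            paste0("x", rep(seq_len(n), each = d), "_", rep(seq_len(d), n)))
  df <- data.frame(traj$times, traj$partners, traj$positions)
  names(df) <- cols
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, params) {
  hdr <- readLines(path, n = 2L)
  field <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr[2])
  df <- utils::read.csv(path, comment.char = "#")
  n <- params$n_beads
  seed <- field("seed")
  structure(list(
    times = df[[1]],
    positions = as.matrix(df[, (n + 2L):ncol(df), drop = FALSE]),
    partners = as.matrix(df[, 2L:(n + 1L), drop = FALSE]),
    params = params,
    dt = as.numeric(field("dt")),
    seed = if (seed == "NA") NULL else as.integer(seed),
    record_every = as.integer(field("record_every"))),
    class = "switching_trajectory")
}

#' @rdname write_trajectory_csv
#' @export
write_xyz <- function(traj, path, every = 1L) {
  n <- traj$params$n_beads
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq(1L, n_frames(traj), by = every)) {
    pos <- frame_positions(traj, i)
    if (ncol(pos) == 2L) pos <- cbind(pos, 0)
    writeLines(as.character(n), con)
    writeLines(sprintf("t=%g", traj$times[i]), con)
    writeLines(sprintf("C %.6f %.6f %.6f", pos[, 1], pos[, 2], pos[, 3]),
               con)
  }
  invisible(path)
}
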