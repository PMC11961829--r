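# Exporters: curve/particle/grid CSV, legacy-VTK point clouds, stage
# segmentation JSON, and the run manifest. Every exporter refuses to write
# non-finite values silently.

assert_finite <- function(x, what) {
  if (any(!is.finite(as.matrix(x)))) {
    stop(sprintf("refusing to export non-finite values in %s", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an experiment curve to CSV
#'
#' @param curve An `experiment_curve`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  assert_finite(curve[c("time", "strain", "stress", "force")], "curve")
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a particle snapshot to CSV
#'
#' Columns: position, velocity, total and plastic volume ratios, status.
#'
#' @param state An [mpm_state()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_particles_csv <- function(state, path) {
  d <- state$p$d
  ax <- c("x", "y", "z")[seq_len(d)]
  df <- data.frame(state$p$x, state$p$v, J = state$p$J, J_P = state$p$Jp,
                   status = status_labels(state$p$status))
  names(df) <- c(ax, paste0("v", ax), "J", "J_P", "status")
  assert_finite(df[seq_len(2L * d + 2L)], "particle snapshot")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a particle snapshot as a legacy-VTK point cloud
#'
#' ASCII legacy VTK POLYDATA with per-point scalars `J`, `J_P` and `status`;
#' 2-D runs are written with z = 0.
#'
#' @param state An [mpm_state()].
#' @param path Output `.vtk` path.
#' @return The path, invisibly.
#' @export
write_particles_vtk <- function(state, path) {
  p <- state$p
  assert_finite(p$x, "particle positions")
  n <- p$n
  xyz <- matrix(0, n, 3L)
  xyz[, seq_len(p$d)] <- p$x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "npsim particle cloud", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(xyz, con, row.names = FALSE, col.names = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS J double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(p$J, digits = 9), con)
  writeLines(c("SCALARS J_P double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(p$Jp, digits = 9), con)
  writeLines(c("SCALARS status int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(p$status), con)
  invisible(path)
}

#' Write grid diagnostics to CSV
#'
#' One row per active grid node: 0-based grid coordinates, mass, and
#' velocity components.
#'
#' @param state An [mpm_state()] after [grid_update()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_grid_csv <- function(state, path) {
  g <- state$grid
  act <- which(g$active)
  d <- state$cfg$d
  df <- data.frame(g$coords[act, , drop = FALSE], mass = g$mass[act],
                   g$vel[act, , drop = FALSE])
  names(df) <- c(paste0("i", c("x", "y", "z")[seq_len(d)]), "mass",
                 paste0("v", c("x", "y", "z")[seq_len(d)]))
  assert_finite(df, "grid diagnostics")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a stage segmentation to JSON
#'
#' @param seg A [segment_stages()] result.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_segmentation_json <- function(seg, path) {
  obj <- list(stages = as.data.frame(seg),
              breakpoints = attr(seg, "breakpoints"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to replay a run: the normalized configuration,
#' the seed, the package version, the output files produced, and the wall
#' time (informational). Written atomically (temp file + rename).
#'
#' @param conf A configuration list as from [load_config()].
#' @param seed Seed used for the run.
#' @param outputs Named character vector/list of produced file paths.
#' @param path Output JSON path.
#' @param walltime Elapsed seconds (informational only).
#' @return The path, invisibly.
#' @export
write_manifest <- function(conf, seed, outputs, path, walltime = NA_real_) {
  obj <- list(
    package = "npsim",
    version = as.character(utils::packageVersion("npsim")),
    seed = seed,
    config = config_normalize(conf),
    outputs = as.list(outputs),
    walltime_s = walltime
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
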