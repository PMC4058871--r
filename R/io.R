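#' Write a capture report as JSON
#'
#' Versioned schema; counts, headline metrics, per-face/per-element capture
#' breakdown, the per-parcel fate table and the scenario fingerprint.  Output
#' is deterministic: identical configurations produce byte-identical files.
#'
#' @param report a [compute_report()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- list(
    schema_version = report$schema_version,
    fingerprint = report$fingerprint,
    n_injected = report$n_injected,
    counts = as.list(report$counts),
    CE_percent = report$CE,
    element_retention_percent = report$element_retention,
    wall_trapped_percent = report$wall_trapped_pct,
    timeout_percent = report$timeout_pct,
    captured_per_face = as.list(unclass(report$captured_per_face)),
    captured_per_element = as.list(unclass(report$captured_per_element)),
    parcels = report$parcels)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", factor = "string")
  invisible(path)
}

#' Write parcel trajectories as CSV
#'
#' Long format: `parcel_id, t, x, y, u_p, v_p, fate`, decimated at the
#' tracker stride.
#'
#' @param track a [track_all()] result with recorded trajectories.
#' @param path output file.
#' @export
write_trajectories_csv <- function(track, path) {
  if (is.null(track$trajectories))
    stop("write_trajectories_csv: trajectories were not recorded")
  tabs <- lapply(seq_along(track$trajectories), function(i) {
    m <- track$trajectories[[i]]
    data.frame(parcel_id = i, m, fate = as.character(track$fate[i]))
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a force/field profile as CSV
#'
#' @param profile a [force_profile()] data.frame.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a flow field as a legacy-ASCII VTK rectilinear grid
#'
#' Cell-center velocity (and the momentum sink, when present) on the solved
#' window, with blocked cells zeroed and flagged.
#'
#' @param ff a [flow_field()].
#' @param path output file (conventionally `.vtk`).
#' @export
write_flow_vtk <- function(ff, path) {
  g <- ff$grid
  nx <- g$nx; ny <- g$ny
  uc <- 0.5 * (ff$U[1:nx, ] + ff$U[2:(nx + 1), ])
  vc <- 0.5 * (ff$V[, 1:ny] + ff$V[, 2:(ny + 1)])
  uc[g$blocked] <- 0; vc[g$blocked] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("magsep steady flow field")
  w("ASCII")
  w("DATASET RECTILINEAR_GRID")
  w("DIMENSIONS %d %d 1", nx + 1, ny + 1)
  w("X_COORDINATES %d double", nx + 1)
  writeLines(paste(format(g$xf, digits = 12), collapse = " "), con)
  w("Y_COORDINATES %d double", ny + 1)
  writeLines(paste(format(g$yf, digits = 12), collapse = " "), con)
  w("Z_COORDINATES 1 double")
  writeLines("0", con)
  w("CELL_DATA %d", nx * ny)
  w("VECTORS velocity double")
  # VTK cell ordering wants x fastest = R column-major of an nx-by-ny matrix
  writeLines(paste(format(as.vector(uc), digits = 9),
                   format(as.vector(vc), digits = 9), "0"), con)
  w("SCALARS pressure double 1")
  w("LOOKUP_TABLE default")
  writeLines(format(as.vector(ff$P), digits = 9), con)
  w("SCALARS blocked int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(as.integer(as.vector(g$blocked))), con)
  if (!is.null(ff$sink)) {
    w("VECTORS momentum_sink double")
    writeLines(paste(format(as.vector(ff$sink$Su), digits = 9),
                     format(as.vector(ff$sink$Sv), digits = 9), "0"), con)
  }
  invisible(path)
}

#' Write parcel trajectories as VTK polylines
#'
#' @param track a [track_all()] result with recorded trajectories.
#' @param path output file.
#' @export
write_trajectories_vtk <- function(track, path) {
  if (is.null(track$trajectories))
    stop("write_trajectories_vtk: trajectories were not recorded")
  pts <- do.call(rbind, lapply(track$trajectories, function(m) m[, c("x", "y")]))
  npts <- nrow(pts)
  lens <- vapply(track$trajectories, nrow, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("magsep parcel trajectories")
  w("ASCII")
  w("DATASET POLYDATA")
  w("POINTS %d double", npts)
  writeLines(paste(format(pts[, 1], digits = 9),
                   format(pts[, 2], digits = 9), "0"), con)
  w("LINES %d %d", length(lens), sum(lens + 1))
  off <- c(0, cumsum(lens))
  for (i in seq_along(lens))
    writeLines(paste(c(lens[i], seq(off[i], off[i + 1] - 1)), collapse = " "),
               con)
  invisible(path)
}
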