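#' Capture report for a tracking run
#'
#' Two headline metrics are always reported together: the capture
#' (filtration) efficiency `CE = 100 (1 - escaped / injected)`, which counts
#' wall-trapped parcels as retained, and the element retention
#' `100 * captured_on_elements / injected`, which counts only parcels stuck
#' on element faces.
#'
#' @param track a [track_all()] result.
#' @param s the [scenario()] that produced it.
#' @return object of class `capture_report`.
#' @export
compute_report <- function(track, s) {
  n <- track$n
  if (n == 0) stop("compute_report: no parcels injected")
  fate <- track$fate
  counts <- table(fate)
  escaped <- sum(fate == "escaped")
  captured <- sum(fate == "captured_element")
  trapped_bottom <- sum(fate == "trapped_wall_bottom")
  trapped_top <- sum(fate == "trapped_wall_top")
  timeout <- sum(fate == "in_flow")

  per_face <- table(track$face[fate == "captured_element"])
  per_element <- table(factor(track$element[fate == "captured_element"],
                              levels = seq_along(s$array$elements)))

  parcel_table <- data.frame(
    parcel = seq_len(n),
    y_seed = NA_real_,
    fate = fate,
    element = track$element,
    face = track$face,
    x_final = track$final[, "x"], y_final = track$final[, "y"],
    t_final = track$final[, "t"])

  structure(list(
    n_injected = n,
    counts = c(captured_element = captured,
               trapped_wall_bottom = trapped_bottom,
               trapped_wall_top = trapped_top,
               escaped = escaped, timeout = timeout),
    captured_per_face = per_face,
    captured_per_element = per_element,
    CE = 100 * (1 - escaped / n),
    element_retention = 100 * captured / n,
    wall_trapped_pct = 100 * (trapped_bottom + trapped_top) / n,
    timeout_pct = 100 * timeout / n,
    parcels = parcel_table,
    fingerprint = scenario_fingerprint(s),
    schema_version = 1L),
    class = "capture_report")
}

#' @export
print.capture_report <- function(x, ...) {
  cat(sprintf("<capture_report> %d parcels: CE = %.1f%%, element retention = %.1f%%\n",
              x$n_injected, x$CE, x$element_retention))
  cat(sprintf("  captured on elements: %d, wall-trapped: %.1f%%, timeouts: %d\n",
              x$counts[["captured_element"]], x$wall_trapped_pct,
              x$counts[["timeout"]]))
  invisible(x)
}

#' Built-in scenario fixtures
#'
#' Named nominal configurations (200 um x 10 mm channel, water, 1 um beads,
#' 3.9e5 A/m bias, u_avg = 1 cm/s, 100 streams unless stated):
#' \describe{
#'   \item{conventional_3 / _5 / _8}{embedded 40 um elements, b = 80 um.}
#'   \item{single_40um / _80um / _120um}{one embedded square element of that
#'     side, for force-profile studies.}
#'   \item{stair_5_b80}{five flow-invasive stair-step elements, a = 40 um,
#'     b = 80 um, spanning the channel height.}
#'   \item{stair_3_b80, stair_3_b120}{three-element stairs anchored on the
#'     channel base.}
#'   \item{twoway_0.028 / _0.084 / _0.14}{stair_3_b120 with two-way coupling
#'     at that inlet volume fraction (percent).}
#' }
#'
#' @param name fixture name.
#' @param u_avg optional inlet-velocity override (m/s).
#' @return a [scenario()].
#' @export
scenario_fixture <- function(name, u_avg = 0.01) {
  chan <- channel()
  mk <- function(arr, coupling = "one", phi = 0)
    scenario(chan = chan, array = arr, u_avg = u_avg,
             coupling = coupling, phi = phi)
  side <- function(nm) switch(nm, single_40um = 40e-6, single_80um = 80e-6,
                              single_120um = 120e-6)
  switch(name,
    conventional_3 = mk(build_conventional(3, chan = chan)),
    conventional_5 = mk(build_conventional(5, chan = chan)),
    conventional_8 = mk(build_conventional(8, chan = chan)),
    single_40um = ,
    single_80um = ,
    single_120um = mk(build_conventional(1, W = side(name), H = side(name),
                                         chan = chan)),
    stair_5_b80 = mk(build_stair_step(5, b = 80e-6, chan = chan)),
    stair_3_b80 = mk(build_stair_step(3, b = 80e-6, chan = chan)),
    stair_3_b120 = mk(build_stair_step(3, b = 120e-6, chan = chan)),
    twoway_0.028 = mk(build_stair_step(3, b = 120e-6, chan = chan),
                      coupling = "two", phi = 0.00028),
    twoway_0.084 = mk(build_stair_step(3, b = 120e-6, chan = chan),
                      coupling = "two", phi = 0.00084),
    twoway_0.14 = mk(build_stair_step(3, b = 120e-6, chan = chan),
                     coupling = "two", phi = 0.0014),
    stop("scenario_fixture: unknown fixture '", name, "'"))
}

#' Run a scenario end to end
#'
#' Solves the flow (when the layout is flow-invasive or two-way coupling is
#' requested), tracks all parcels and assembles the capture report.  When
#' `out_dir` is given, writes the report JSON, trajectory CSV, flow VTK and a
#' vertical force-profile CSV there.
#'
#' @param s a [scenario()], or a fixture name for [scenario_fixture()].
#' @param out_dir optional output directory.
#' @param profile_only only compute and (optionally) write the magnetic
#'   force profile along the vertical centerline above the first element;
#'   skips flow and tracking.
#' @param quiet suppress progress messages.
#' @return list with `scenario`, `report`, `track`, `flow` (may be `NULL`),
#'   `profile`, and for two-way runs the outer `history`; for `profile_only`
#'   just `scenario` and `profile`.
#' @export
run_scenario <- function(s, out_dir = NULL, profile_only = FALSE,
                         quiet = FALSE) {
  if (is.character(s)) s <- scenario_fixture(s)
  v <- validate_scenario(s)
  if (any(v$level == "fatal"))
    stop("run_scenario: fatal finding(s): ",
         paste(v$message[v$level == "fatal"], collapse = "; "))
  say <- function(...) if (!quiet) message(...)

  m <- elem_matrix(s$array)
  profile <- NULL
  if (nrow(m) > 0) {
    e1 <- m[1, ]
    ytop <- e1[2] + e1[4]
    profile <- force_profile(s$array, s$particle,
                             e1[1], max(ytop, 0) + 1e-9,
                             e1[1], s$channel$Hc - 1e-9, n = 2001)
  }
  if (profile_only) {
    out <- list(scenario = s, profile = profile)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_profile_csv(profile, file.path(out_dir, "force_profile.csv"))
    }
    return(invisible(out))
  }

  if (s$coupling == "two") {
    say("two-way coupled solve ...")
    tw <- two_way_solve(s)
    ff <- tw$flow; tr <- tw$track; rep_ <- tw$report
    history <- tw$history
  } else {
    ff <- NULL
    history <- NULL
    if (is_invasive(s)) {
      say("solving flow around invasive elements ...")
      ff <- solve_flow(s)
    }
    streams <- seed_inlet(s$n_streams, s$channel, s$u_avg)
    say("tracking ", nrow(streams), " parcels ...")
    tr <- track_all(streams, s, ff)
    rep_ <- compute_report(tr, s)
  }
  rep_$parcels$y_seed <- seed_inlet(s$n_streams, s$channel, s$u_avg)$y

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(rep_, file.path(out_dir, "report.json"))
    write_trajectories_csv(tr, file.path(out_dir, "trajectories.csv"))
    if (!is.null(profile))
      write_profile_csv(profile, file.path(out_dir, "force_profile.csv"))
    if (!is.null(ff)) {
      write_flow_vtk(ff, file.path(out_dir, "flow.vtk"))
      write_trajectories_vtk(tr, file.path(out_dir, "trajectories.vtk"))
    }
  }
  invisible(list(scenario = s, report = rep_, track = tr, flow = ff,
                 profile = profile, history = history))
}

#' Sweep scenarios over a parameter grid
#'
#' Runs [run_scenario()] once per row of a parameter grid, modifying the
#' base scenario.  Supported parameters: `u_avg` (m/s), `n_elements`,
#' `phi`.  Individual failures are recorded per row and the sweep continues.
#'
#' @param base a [scenario()] or fixture name.
#' @param grid data.frame (or named list of vectors, crossed) of parameter
#'   values.
#' @return tidy data.frame: one row per grid point with `CE`,
#'   `element_retention`, `wall_trapped_pct`, `runtime_s`, `error`.
#' @export
sweep_scenarios <- function(base, grid) {
  if (is.character(base)) base <- scenario_fixture(base)
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  if (nrow(grid) == 0) {
    out <- grid
    out$CE <- out$element_retention <- out$wall_trapped_pct <-
      out$runtime_s <- numeric(0)
    out$error <- character(0)
    return(out)
  }
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    s <- base
    for (nm in names(grid)) {
      val <- grid[[nm]][r]
      s <- switch(nm,
        u_avg = { s$u_avg <- val; s },
        phi = { s$phi <- val; s$coupling <- if (val > 0) "two" else "one"; s },
        n_elements = {
          m <- elem_matrix(s$array)
          e1 <- s$array$elements[[1]]
          b <- if (nrow(m) >= 2) m[2, 1] - m[1, 1] else 80e-6
          a <- if (nrow(m) >= 2) m[2, 2] - m[1, 2] else 0
          s$array <- if (is_invasive(s))
            build_stair_step(val, W = 2 * e1$w, H = 2 * e1$h, a = a, b = b,
                             x0 = e1$center_x, Mes = e1$Mes,
                             Hbias = s$array$Hbias, chan = s$channel)
          else
            build_conventional(val, W = 2 * e1$w, H = 2 * e1$h, b = b,
                               x0 = e1$center_x, Mes = e1$Mes,
                               Hbias = s$array$Hbias, chan = s$channel)
          s
        },
        stop("sweep_scenarios: unsupported parameter '", nm, "'"))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_scenario(s, quiet = TRUE), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    row <- cbind(grid[r, , drop = FALSE], row.names = NULL)
    if (inherits(res, "error")) {
      row$CE <- NA_real_; row$element_retention <- NA_real_
      row$wall_trapped_pct <- NA_real_
      row$runtime_s <- dt; row$error <- conditionMessage(res)
    } else {
      row$CE <- res$report$CE
      row$element_retention <- res$report$element_retention
      row$wall_trapped_pct <- res$report$wall_trapped_pct
      row$runtime_s <- dt; row$error <- NA_character_
    }
    rows[[r]] <- row
  }
  do.call(rbind, rows)
}
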