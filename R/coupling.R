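#' Map an inlet volume fraction to per-stream parcel mass flow rates
#'
#' The total particle mass flow (per unit depth) is `phi * rho_p * Q` with
#' `Q = u_avg * Hc` the fluid volumetric flow.  It is apportioned to the
#' seeded streams in proportion to each stream's flux-tube volumetric flow
#' under the fully developed inlet profile, so streams near the walls carry
#' less mass than core streams.  The particle-to-fluid mass ratio is
#' `phi * rho_p / rho_f`.
#'
#' @param phi inlet particle volume fraction (dimensionless; 0.0014 = 0.14%).
#' @param s a [scenario()].
#' @param streams a [seed_inlet()] data.frame.
#' @return numeric vector of per-stream mass flow rates (kg/s per unit
#'   depth), with attribute `mass_ratio`.
#' @export
loading_to_mdot <- function(phi, s, streams) {
  stopifnot(phi >= 0)
  if (phi >= 0.01)
    warning("loading_to_mdot: volume fraction outside the dilute range")
  n <- nrow(streams)
  Hc <- s$channel$Hc
  yb <- seq(0, Hc, length.out = n + 1) # flux-tube boundaries
  antider <- function(y) 6 * s$u_avg * (y^2 / (2 * Hc) - y^3 / (3 * Hc^2))
  q <- antider(yb[-1]) - antider(yb[-(n + 1)]) # per-tube volumetric flow
  mdot <- phi * s$particle$rho_p * q
  attr(mdot, "mass_ratio") <- phi * s$particle$rho_p / s$fluid$rho
  mdot
}

#' Drag-reaction momentum sink accumulated along parcel trajectories
#'
#' Runs the tracker with per-cell accumulation switched on: for every step a
#' parcel spends `dt` inside a grid cell, the cell receives
#' `-(6 pi eta Rp)(u - u_p) (mdot/m_p) dt / V_cell` (N/m^3), the reaction to
#' Stokes drag weighted by the number flow rate the parcel represents.  The
#' magnetic force is not fed back to the fluid.  Captured and trapped
#' parcels stop contributing.
#'
#' @param s a [scenario()] (two-way coupling implied by a nonzero `phi`).
#' @param ff a solved [flow_field()].
#' @param streams a [seed_inlet()] data.frame.
#' @param mdot per-stream mass flow rates from [loading_to_mdot()].
#' @param settings tracker settings.
#' @return list with the sink matrices `Su`, `Sv` (N/m^3 on grid cells), the
#'   grid, and the underlying `track` result.
#' @export
accumulate_sink <- function(s, ff, streams, mdot, settings = s$tracker) {
  tr <- track_all(streams, s, ff, settings = settings, mdot = mdot,
                  accumulate_sink = TRUE)
  c(tr$sink, list(track = tr))
}

#' Steady two-way coupled solution
#'
#' Frozen-field outer iteration: solve the flow with the current momentum
#' sink, re-track all parcels through it, re-accumulate the sink
#' (under-relaxed), and repeat until both the capture outcome and the sink
#' field stop changing.  The zero-loading limit reproduces the one-way
#' solution exactly.
#'
#' @param s a [scenario()] with `coupling = "two"` and a volume fraction
#'   `phi`.
#' @param grid optional [flow_grid()].
#' @param relax under-relaxation factor on the sink field, in (0, 1].  The
#'   default 0.3 follows common discrete-phase practice for stable source
#'   coupling at appreciable loading.
#' @param max_outer outer-iteration cap.
#' @param tol_sink relative sink-change tolerance (L2 norm over all cells).
#'   Because parcels have discrete fates, borderline parcels can flip
#'   between passes and the iteration settles into a limit cycle of a
#'   parcel or two in amplitude; that state is accepted (with a warning)
#'   since the under-relaxed flow has converged to the cycle mean.  A
#'   capture outcome still drifting beyond two parcels over the trailing
#'   five passes is a convergence error.
#' @return list with the converged `flow` ([flow_field()]), `track`
#'   ([track_all()] result), `report` ([compute_report()]), `sink`, and the
#'   outer-iteration `history` (capture efficiency and sink change per pass).
#' @export
two_way_solve <- function(s, grid = NULL, relax = 0.3, max_outer = 30,
                          tol_sink = 0.05) {
  if (s$coupling != "two")
    stop("two_way_solve: scenario is not in two-way mode")
  stopifnot(relax > 0, relax <= 1)
  if (is.null(grid)) grid <- flow_grid(s)
  streams <- seed_inlet(s$n_streams, s$channel, s$u_avg)
  mdot <- loading_to_mdot(s$phi, s, streams)
  one_parcel <- 100 / s$n_streams + 1e-9
  cycle_tol <- 2 * 100 / s$n_streams + 1e-9

  sink <- NULL
  prev_raw <- NULL
  hist <- data.frame(iter = integer(), CE = numeric(), dsink = numeric())
  for (it in seq_len(max_outer)) {
    ff <- solve_flow(s, grid, sink = sink)
    acc <- accumulate_sink(s, ff, streams, mdot)
    rep_ <- compute_report(acc$track, s)
    raw <- list(Su = acc$Su, Sv = acc$Sv)
    if (is.null(prev_raw)) {
      dsink <- Inf
    } else {
      nrm <- sqrt(sum(prev_raw$Su^2) + sum(prev_raw$Sv^2))
      dsink <- if (nrm == 0) 0 else
        sqrt(sum((raw$Su - prev_raw$Su)^2) +
               sum((raw$Sv - prev_raw$Sv)^2)) / nrm
    }
    sink <- if (is.null(sink)) raw else
      list(Su = relax * raw$Su + (1 - relax) * sink$Su,
           Sv = relax * raw$Sv + (1 - relax) * sink$Sv)
    prev_raw <- raw
    hist <- rbind(hist, data.frame(iter = it, CE = rep_$CE, dsink = dsink))
    if (s$phi == 0) break # zero loading: sink is identically zero
    if (it >= 4 && dsink < tol_sink &&
        abs(diff(tail(hist$CE, 2))) <= one_parcel) break
  }
  if (s$phi > 0 && it == max_outer && dsink >= tol_sink) {
    if (diff(range(tail(hist$CE, 5))) <= cycle_tol)
      warning("two_way_solve: settled into a limit cycle after ",
              max_outer, " passes; using the relaxed (cycle-mean) sink")
    else
      stop("two_way_solve: outer iteration did not converge; history:\n",
           paste(utils::capture.output(print(hist)), collapse = "\n"))
  }

  # final consistent pass with the converged sink
  ff <- solve_flow(s, grid, sink = sink)
  tr <- track_all(streams, s, ff, mdot = mdot)
  list(flow = ff, track = tr, report = compute_report(tr, s),
       sink = sink, history = hist)
}
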