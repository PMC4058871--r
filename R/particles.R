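#' Parcel-tracking settings
#'
#' The drag ODE has a velocity relaxation time `tau_p = (2/9) rho_p Rp^2 /
#' eta` (about 1e-7 s at nominal parameters), far below any flow time scale,
#' so the default integrator advances the drag ODE exactly over each step
#' with the fluid velocity and magnetic force frozen ("exp"); steps are
#' bounded by a displacement target, fine near the elements and coarser in
#' the open channel.  The "rk4" integrator applies classical RK4 to the full
#' stiff system with a fixed small step and serves as a cross-check.
#'
#' @param capture_dist center-to-surface capture distance (m); `NULL` means
#'   the bead radius (perfect sticking on contact).
#' @param rex corner exclusion radius for the magnetic force (m).
#' @param ds_near,ds_far displacement bound per step (m) inside / outside the
#'   near-element region.
#' @param near_margin margin around the element bounding box defining the
#'   near region (m).
#' @param dt_max absolute step-size cap (s).
#' @param t_max maximum transit time (s); `NULL` picks 10 transit times of
#'   the slowest seeded stream.  Parcels still in flow at `t_max` are
#'   reported as timeouts.
#' @param integrator `"exp"` (default) or `"rk4"`.
#' @param rk4_dt RK4 time step (s); must stay well below the stability limit
#'   `2.79 tau_p`.
#' @param stride trajectory decimation stride (record every `stride`-th step).
#' @param record keep decimated trajectories.
#' @return named list of settings.
#' @export
tracker_settings <- function(capture_dist = NULL, rex = 0.25e-6,
                             ds_near = 0.5e-6, ds_far = 5e-6,
                             near_margin = 80e-6, dt_max = 0.02,
                             t_max = NULL, integrator = "exp",
                             rk4_dt = 1e-7, stride = 20, record = TRUE) {
  stopifnot(integrator %in% c("exp", "rk4"))
  list(capture_dist = capture_dist, rex = rex, ds_near = ds_near,
       ds_far = ds_far, near_margin = near_margin, dt_max = dt_max,
       t_max = t_max, integrator = integrator, rk4_dt = rk4_dt,
       stride = as.integer(stride), record = record)
}

#' Seed parcels uniformly over the inlet plane
#'
#' Stream `k` (of `n_streams`) starts at `y_k = (k - 1/2) Hc / n_streams`,
#' `x = 0`, moving with the local fluid velocity.
#'
#' @param n_streams number of streams.
#' @param chan a [channel()].
#' @param u_avg average inlet velocity (m/s).
#' @return data.frame with columns `x`, `y`, `u_p`, `v_p` (one row per
#'   parcel) of class `parcels`.
#' @export
seed_inlet <- function(n_streams, chan = channel(), u_avg = 0.01) {
  stopifnot(n_streams >= 1)
  y <- (seq_len(n_streams) - 0.5) * chan$Hc / n_streams
  out <- data.frame(x = 0, y = y,
                    u_p = poiseuille(chan, u_avg, y), v_p = 0)
  class(out) <- c("parcels", "data.frame")
  out
}

fate_levels <- c("in_flow", "captured_element", "trapped_wall_bottom",
                 "trapped_wall_top", "escaped")

#' Track all parcels to a terminal state
#'
#' Advances every parcel under Stokes drag and the effective-dipole magnetic
#' force until it is captured on an element face, trapped at a wall (within
#' the capture distance with the net wall-normal force pointing into the
#' wall), escapes past the outlet, or exceeds the maximum transit time.
#' Captured and trapped parcels stop integrating (perfect sticking, no
#' re-release).
#'
#' @param parcels a [seed_inlet()] data.frame (or compatible).
#' @param s a [scenario()].
#' @param ff a [flow_field()] from [solve_flow()], or `NULL` to use the
#'   exact fully developed profile (valid for unobstructed layouts).
#' @param settings see [tracker_settings()]; defaults to `s$tracker`.
#' @param mdot per-parcel mass flow rate (kg/s), for two-way bookkeeping;
#'   default zero (pure tracer streams).
#' @param accumulate_sink also accumulate the per-cell drag-reaction
#'   momentum sink on the flow grid (requires `ff`).
#' @return object of class `track_result`: per-parcel `fate` factor, capture
#'   element/face, final states, step counts, decimated trajectories, and
#'   (when requested) the sink field.
#' @export
track_all <- function(parcels, s, ff = NULL, settings = s$tracker,
                      mdot = NULL, accumulate_sink = FALSE) {
  if (accumulate_sink && is.null(ff))
    stop("track_all: sink accumulation requires a solved flow field")
  n <- nrow(parcels)
  if (is.null(mdot)) mdot <- numeric(n)
  stopifnot(length(mdot) == n)

  p <- s$particle
  gamma <- 6 * pi * s$fluid$eta * p$Rp
  cd <- if (is.null(settings$capture_dist)) p$Rp else settings$capture_dist
  m <- elem_matrix(s$array)
  if (nrow(m) > 0) {
    nb <- c(min(m[, 1] - m[, 3]), max(m[, 1] + m[, 3]),
            max(0, min(m[, 2] - m[, 4])), min(s$channel$Hc, max(m[, 2] + m[, 4])))
    nb <- nb + c(-1, 1, -1, 1) * settings$near_margin
  } else {
    nb <- c(1, -1, 1, -1) # empty box: never "near"
  }
  t_max <- settings$t_max
  if (is.null(t_max)) {
    y1 <- min(parcels$y, s$channel$Hc - parcels$y)
    u_slow <- poiseuille(s$channel, s$u_avg, y1)
    t_max <- 10 * s$channel$Lc / u_slow
  }

  cpp_settings <- list(
    rex = settings$rex, capture_dist = cd,
    ds_near = settings$ds_near, ds_far = settings$ds_far,
    near_box = nb, dt_max = settings$dt_max, t_max = t_max,
    integrator = if (settings$integrator == "exp") 0L else 1L,
    rk4_dt = settings$rk4_dt, stride = settings$stride,
    record = isTRUE(settings$record), do_sink = isTRUE(accumulate_sink))

  res <- cpp_track(as.matrix(parcels[, c("x", "y", "u_p", "v_p")]),
                   as.numeric(mdot), flow_to_cpp(s, ff), m, s$array$Hbias,
                   list(Vp = p$Vp, mp = p$mp, gamma = gamma,
                        Msp = p$Msp, chia = p$chi_a),
                   cpp_settings)

  fate <- factor(fate_levels[res$fate + 1], levels = fate_levels)
  out <- list(
    fate = fate,
    element = res$element,
    face = factor(c("top", "bottom", "left", "right")[res$face],
                  levels = c("top", "bottom", "left", "right")),
    final = `colnames<-`(res$final, c("x", "y", "u_p", "v_p", "t")),
    nsteps = res$nsteps,
    trajectories = res$trajectories,
    mdot = mdot, n = n, t_max = t_max)
  if (accumulate_sink) {
    out$sink <- list(Su = res$Su, Sv = res$Sv, grid = ff$grid)
  }
  n_timeout <- sum(fate == "in_flow")
  if (n_timeout > 0.01 * n)
    warning(sprintf("track_all: %d of %d parcels timed out (> 1%%)",
                    n_timeout, n))
  class(out) <- "track_result"
  out
}

#' @export
print.track_result <- function(x, ...) {
  tb <- table(x$fate)
  cat("<track_result>", x$n, "parcels:",
      paste(names(tb)[tb > 0], tb[tb > 0], sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
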