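#' Microchannel geometry
#'
#' A straight 2D channel: `x` runs downstream from the inlet over `[0, Lc]`,
#' `y` from the floor (`y = 0`) to the ceiling (`y = Hc`).  Unit depth in `z`
#' is assumed for all per-unit-depth flow-rate bookkeeping.
#'
#' @param height channel height Hc (m); default 200 um.
#' @param length channel length Lc (m); default 10 mm.
#' @return object of class `channel`.
#' @export
channel <- function(height = 200e-6, length = 10e-3) {
  stopifnot(height > 0, length > 0)
  structure(list(Hc = height, Lc = length), class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel> %.0f um high x %.2f mm long\n", 1e6 * x$Hc, 1e3 * x$Lc))
  invisible(x)
}

#' Carrier fluid properties
#'
#' @param eta dynamic viscosity (kg/(m s)); default water, 1e-3.
#' @param rho density (kg/m^3); default 1000.
#' @export
fluid <- function(eta = 1e-3, rho = 1000) {
  stopifnot(eta > 0, rho > 0)
  structure(list(eta = eta, rho = rho), class = "fluid")
}

#' Conventional layout: elements embedded in the channel base
#'
#' `n` identical elements sit below the channel floor with their top faces
#' flush at `y = 0` (centers at `y = -H/2`), so the flow domain stays an
#' unobstructed rectangle and the fully developed parabolic profile is exact.
#'
#' @param n number of elements (`>= 1`).
#' @param W,H element full width and height (m).
#' @param b horizontal center-to-center spacing (m), `b >= W`.
#' @param x0 x of the first element center (m); default 1 mm from the inlet.
#'   With one-way coupling no force acts upstream, so results do not depend
#'   on `x0`.
#' @param Mes element saturation magnetization (A/m).
#' @param Hbias uniform bias field (A/m), along +y.
#' @param chan a [channel()]; the layout must fit within its length.
#' @return an [element_array()].
#' @examples
#' build_conventional(3) # 3 embedded 40 um elements, b = 80 um
#' @export
build_conventional <- function(n, W = 40e-6, H = 40e-6, b = 80e-6,
                               x0 = 1e-3, Mes = 8.6e5, Hbias = 3.9e5,
                               chan = channel()) {
  stopifnot(n >= 1, W > 0, H > 0)
  if (n > 1 && b < W) stop("build_conventional: spacing b must be >= element width W")
  cx <- x0 + (seq_len(n) - 1) * b
  if (max(cx) + W / 2 > chan$Lc || min(cx) - W / 2 < 0)
    stop("build_conventional: layout exceeds channel length")
  element_array(lapply(cx, function(x) rect_element(x, -H / 2, W, H, Mes)),
                Hbias = Hbias)
}

#' Flow-invasive stair-step layout
#'
#' Element `k` (`k = 0 .. n-1`) is centered at `(x0 + k b, H/2 + k a)`: the
#' first element rests on the channel base and the stair ascends downstream,
#' cascading the short-range capture force across the channel height.
#'
#' @inheritParams build_conventional
#' @param a vertical center-to-center rise per element (m).
#' @examples
#' build_stair_step(5) # spans the 200 um channel
#' @export
build_stair_step <- function(n, W = 40e-6, H = 40e-6, a = 40e-6, b = 80e-6,
                             x0 = 1e-3, Mes = 8.6e5, Hbias = 3.9e5,
                             chan = channel()) {
  stopifnot(n >= 1, W > 0, H > 0, a >= 0)
  if (n > 1 && b < W) stop("build_stair_step: spacing b must be >= element width W")
  k <- seq_len(n) - 1
  cx <- x0 + k * b
  cy <- H / 2 + k * a
  if (max(cy) + H / 2 > chan$Hc)
    stop("build_stair_step: top element breaches the channel ceiling")
  if (max(cx) + W / 2 > chan$Lc || min(cx) - W / 2 < 0)
    stop("build_stair_step: layout exceeds channel length")
  element_array(mapply(function(x, y) rect_element(x, y, W, H, Mes),
                       cx, cy, SIMPLIFY = FALSE),
                Hbias = Hbias)
}

#' Simulation scenario
#'
#' Bundles channel, element array, particle, fluid, inlet condition, coupling
#' mode and solver/tracker settings.  Defaults are the nominal operating
#' point: water at `u_avg` = 1 cm/s in a 200 um x 10 mm channel, 1 um beads,
#' 0.5 T (3.9e5 A/m) vertical bias.
#'
#' @param chan a [channel()].
#' @param array an [element_array()].
#' @param particle a [magnetic_particle()].
#' @param fl a [fluid()].
#' @param u_avg average inlet velocity (m/s).
#' @param coupling `"one"` (fluid drives particles only) or `"two"` (drag
#'   reaction fed back into the momentum equation).
#' @param phi inlet particle volume fraction (dimensionless, e.g. 0.0014 for
#'   0.14%); only meaningful for two-way coupling.
#' @param n_streams number of uniformly seeded inlet streams.
#' @param solver list of flow-solver settings, see [solver_settings()].
#' @param tracker list of tracking settings, see [tracker_settings()].
#' @param seed reserved for future stochastic extensions; the nominal
#'   pipeline is deterministic.
#' @return object of class `scenario`.
#' @export
scenario <- function(chan = channel(), array = element_array(),
                     particle = myone_bead(), fl = fluid(),
                     u_avg = 0.01, coupling = c("one", "two"), phi = 0,
                     n_streams = 100,
                     solver = solver_settings(), tracker = tracker_settings(),
                     seed = NULL) {
  coupling <- match.arg(coupling)
  stopifnot(u_avg > 0, phi >= 0, n_streams >= 1)
  structure(
    list(channel = chan, array = array, particle = particle, fluid = fl,
         u_avg = u_avg, coupling = coupling, phi = phi,
         n_streams = as.integer(n_streams),
         solver = solver, tracker = tracker, seed = seed),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d element(s), u_avg = %g cm/s, %s-way coupling%s, %d streams\n",
    length(x$array$elements), 100 * x$u_avg, x$coupling,
    if (x$coupling == "two") sprintf(" (phi = %g%%)", 100 * x$phi) else "",
    x$n_streams))
  invisible(x)
}

#' Does the scenario contain flow-invasive elements?
#' @param s a [scenario()].
#' @return TRUE if any element rectangle intersects the open flow domain.
#' @export
is_invasive <- function(s) {
  m <- elem_matrix(s$array)
  nrow(m) > 0 && any(m[, 2] + m[, 4] > 1e-12)
}

## ---- YAML configuration ----------------------------------------------------

um <- 1e-6

#' Load a scenario from a YAML configuration
#'
#' Keys mirror the [scenario()] fields with units encoded in key names
#' (`_um`, `_m_per_s`, `_A_per_m`, `_percent`, ...).  An empty configuration
#' gives the all-nominal scenario.  Unknown keys are an error.
#'
#' @param config path to a YAML file, or a YAML string.
#' @return a [scenario()].
#' @examples
#' s <- load_scenario("elements: {layout: stair_step, count: 3, spacing_um: 120}")
#' @export
load_scenario <- function(config = "") {
  cfg <- if (file.exists(config)) yaml::read_yaml(config)
         else yaml::yaml.load(config)
  if (is.null(cfg)) cfg <- list()

  known_top <- c("channel", "elements", "bias_A_per_m", "particle", "fluid",
                 "inlet", "coupling", "solver", "tracker", "seed")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) stop("load_scenario: unknown key(s): ", paste(bad, collapse = ", "))

  get <- function(block, key, default) {
    v <- if (is.null(cfg[[block]]) || is.null(cfg[[block]][[key]])) default
         else cfg[[block]][[key]]
    # YAML 1.1 reads scientific notation without an explicit sign ("8.6e5")
    # as a string; coerce numeric-looking scalars
    if (is.character(v) && is.numeric(default) &&
        !is.na(suppressWarnings(as.numeric(v)))) v <- as.numeric(v)
    v
  }
  check_keys <- function(block, known) {
    bad <- setdiff(names(cfg[[block]]), known)
    if (length(bad))
      stop("load_scenario: unknown key(s) in '", block, "': ",
           paste(bad, collapse = ", "))
  }

  check_keys("channel", c("height_um", "length_um"))
  chan <- channel(height = get("channel", "height_um", 200) * um,
                  length = get("channel", "length_um", 10000) * um)

  check_keys("particle", c("radius_um", "density_kg_per_m3", "Msp_A_per_m", "chi_a"))
  part <- magnetic_particle(Rp = get("particle", "radius_um", 0.5) * um,
                            rho_p = get("particle", "density_kg_per_m3", 1800),
                            Msp = get("particle", "Msp_A_per_m", 4.3e4),
                            chi_a = get("particle", "chi_a", 1.4))

  check_keys("fluid", c("viscosity_kg_per_m_s", "density_kg_per_m3"))
  fl <- fluid(eta = get("fluid", "viscosity_kg_per_m_s", 1e-3),
              rho = get("fluid", "density_kg_per_m3", 1000))

  Hbias <- if (is.null(cfg$bias_A_per_m)) 3.9e5 else as.numeric(cfg$bias_A_per_m)

  check_keys("elements", c("layout", "count", "width_um", "height_um",
                           "spacing_um", "rise_um", "x0_um", "Mes_A_per_m"))
  layout <- get("elements", "layout", "stair_step")
  n_el <- get("elements", "count", 3)
  arr <- switch(layout,
    none = element_array(Hbias = Hbias),
    conventional = build_conventional(
      n = n_el,
      W = get("elements", "width_um", 40) * um,
      H = get("elements", "height_um", 40) * um,
      b = get("elements", "spacing_um", 80) * um,
      x0 = get("elements", "x0_um", 1000) * um,
      Mes = get("elements", "Mes_A_per_m", 8.6e5),
      Hbias = Hbias, chan = chan),
    stair_step = build_stair_step(
      n = n_el,
      W = get("elements", "width_um", 40) * um,
      H = get("elements", "height_um", 40) * um,
      a = get("elements", "rise_um", 40) * um,
      b = get("elements", "spacing_um", 80) * um,
      x0 = get("elements", "x0_um", 1000) * um,
      Mes = get("elements", "Mes_A_per_m", 8.6e5),
      Hbias = Hbias, chan = chan),
    stop("load_scenario: unknown layout '", layout, "'"))

  check_keys("inlet", c("u_avg_m_per_s", "n_streams"))
  check_keys("coupling", c("mode", "phi_percent"))
  mode <- get("coupling", "mode", "one")
  if (!mode %in% c("one", "two"))
    stop("load_scenario: coupling mode must be 'one' or 'two'")

  check_keys("solver", names(solver_settings()))
  check_keys("tracker", names(tracker_settings()))
  solver <- do.call(solver_settings, if (is.null(cfg$solver)) list() else cfg$solver)
  tracker <- do.call(tracker_settings, if (is.null(cfg$tracker)) list() else cfg$tracker)

  scenario(chan = chan, array = arr, particle = part, fl = fl,
           u_avg = get("inlet", "u_avg_m_per_s", 0.01),
           coupling = mode,
           phi = get("coupling", "phi_percent", 0) / 100,
           n_streams = get("inlet", "n_streams", 100),
           solver = solver, tracker = tracker, seed = cfg$seed)
}

#' Validate a scenario
#'
#' @param s a [scenario()].
#' @return data.frame of findings with columns `level` (`"fatal"` or
#'   `"warning"`) and `message`; zero rows when the scenario is clean.
#' @export
validate_scenario <- function(s) {
  findings <- list()
  add <- function(level, msg) findings[[length(findings) + 1]] <<- c(level, msg)

  if (s$fluid$eta <= 0) add("fatal", "viscosity must be positive")
  if (s$fluid$rho <= 0) add("fatal", "fluid density must be positive")
  if (s$u_avg <= 0) add("fatal", "inlet velocity must be positive")
  if (s$channel$Hc < 20 * s$particle$Rp)
    add("warning", "channel height is not large compared to the bead diameter")
  m <- elem_matrix(s$array)
  if (nrow(m) > 0) {
    if (any(m[, 2] + m[, 4] > s$channel$Hc + 1e-12))
      add("fatal", "an element breaches the channel ceiling")
    if (any(m[, 1] - m[, 3] < 0) || any(m[, 1] + m[, 3] > s$channel$Lc))
      add("fatal", "an element lies outside the channel length")
    if (any(m[, 2] - m[, 4] < -2 * m[, 4] - 1e-12))
      add("fatal", "an element lies entirely below the embedding depth")
  }
  if (s$coupling == "two" && s$phi > 0.01)
    add("warning", "volume fraction outside the dilute range (> 1%)")
  if (s$coupling == "one" && s$phi > 0)
    add("warning", "phi is ignored under one-way coupling")
  if (length(findings) == 0)
    return(data.frame(level = character(), message = character()))
  data.frame(level = vapply(findings, `[`, "", 1),
             message = vapply(findings, `[`, "", 2))
}

#' Scenario fingerprint
#'
#' Deterministic FNV-1a hash of the serialized configuration, embedded in
#' reports for reproducibility.
#' @param s a [scenario()].
#' @return character scalar (16 hex digits).
#' @export
scenario_fingerprint <- function(s) {
  raw <- serialize(list(s$channel, elem_matrix(s$array), s$array$Hbias,
                        unclass(s$particle), unclass(s$fluid), s$u_avg,
                        s$coupling, s$phi, s$n_streams, s$solver, s$tracker),
                   connection = NULL, version = 2)
  v <- as.integer(raw)
  # two 32-bit multiplicative accumulators (multipliers keep the product
  # within double precision: 2^32 * 69069 < 2^53)
  h1 <- 2166136261; h2 <- 305419896
  for (b in v) {
    h1 <- (h1 * 69069 + b + 1) %% 4294967296
    h2 <- (h2 * 65599 + b * 131 + 7) %% 4294967296
  }
  paste0(format(as.hexmode(h1 %/% 65536), width = 4),
         format(as.hexmode(h1 %% 65536), width = 4),
         format(as.hexmode(h2 %/% 65536), width = 4),
         format(as.hexmode(h2 %% 65536), width = 4))
}
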