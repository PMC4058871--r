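#' Rectangular soft-magnetic element
#'
#' A long rectangular element (2D cross-section) of full width `width` and
#' full height `height`, uniformly magnetized to its saturation magnetization
#' `Mes` along +y by the external bias field.  Internally the element stores
#' half-dimensions `w = width/2`, `h = height/2`.
#'
#' @param center_x,center_y element center (m), in channel coordinates
#'   (x downstream from the inlet, y = 0 at the channel floor).
#' @param width,height full cross-sectional dimensions (m).
#' @param Mes saturation magnetization (A/m), magnetized along +y.
#' @return object of class `rect_element`.
#' @examples
#' rect_element(1e-3, -20e-6, 40e-6, 40e-6, 8.6e5)
#' @export
rect_element <- function(center_x, center_y, width, height, Mes = 8.6e5) {
  stopifnot(width > 0, height > 0, Mes > 0)
  structure(
    list(center_x = center_x, center_y = center_y,
         w = width / 2, h = height / 2, Mes = Mes),
    class = "rect_element")
}

#' @export
print.rect_element <- function(x, ...) {
  cat(sprintf("<rect_element> %.1f x %.1f um at (%.1f, %.1f) um, Mes = %.3g A/m\n",
              2e6 * x$w, 2e6 * x$h, 1e6 * x$center_x, 1e6 * x$center_y, x$Mes))
  invisible(x)
}

#' Array of magnetized elements plus a uniform bias field
#'
#' @param elements list of [rect_element()] objects (may be empty).
#' @param Hbias uniform bias field magnitude (A/m), directed along +y.
#' @return object of class `element_array`.
#' @export
element_array <- function(elements = list(), Hbias = 3.9e5) {
  stopifnot(Hbias >= 0)
  if (inherits(elements, "rect_element")) elements <- list(elements)
  for (e in elements) stopifnot(inherits(e, "rect_element"))
  if (length(elements) >= 2) {
    m <- elem_matrix_from_list(elements)
    for (i in seq_len(nrow(m) - 1)) for (j in seq(i + 1, nrow(m))) {
      ox <- abs(m[i, 1] - m[j, 1]) < (m[i, 3] + m[j, 3]) - 1e-12
      oy <- abs(m[i, 2] - m[j, 2]) < (m[i, 4] + m[j, 4]) - 1e-12
      if (ox && oy) stop("element_array: elements ", i, " and ", j, " overlap")
    }
  }
  structure(list(elements = elements, Hbias = Hbias), class = "element_array")
}

#' @export
print.element_array <- function(x, ...) {
  cat(sprintf("<element_array> %d element(s), Hbias = %.3g A/m\n",
              length(x$elements), x$Hbias))
  invisible(x)
}

elem_matrix_from_list <- function(elements) {
  if (length(elements) == 0)
    return(matrix(numeric(0), 0, 5))
  t(vapply(elements,
           function(e) c(e$center_x, e$center_y, e$w, e$h, e$Mes),
           numeric(5)))
}

elem_matrix <- function(arr) elem_matrix_from_list(arr$elements)

#' Superparamagnetic particle (magnetic bead)
#'
#' Derived quantities are computed on construction: the intrinsic
#' susceptibility `chi_p = 3 chi_a / (3 - chi_a)` (sphere demagnetization
#' factor `Nd = 1/3`), volume `Vp`, and mass `mp`.
#'
#' @param Rp bead radius (m).
#' @param rho_p bead density (kg/m^3).
#' @param Msp bead saturation magnetization (A/m).
#' @param chi_a apparent (low-field) susceptibility, `0 < chi_a < 3`.
#' @return object of class `magnetic_particle`.
#' @examples
#' myone_bead()
#' @export
magnetic_particle <- function(Rp = 0.5e-6, rho_p = 1800, Msp = 4.3e4,
                              chi_a = 1.4) {
  stopifnot(Rp > 0, rho_p > 0, Msp > 0, chi_a > 0, chi_a < 3)
  Vp <- 4 / 3 * pi * Rp^3
  structure(
    list(Rp = Rp, rho_p = rho_p, Msp = Msp, chi_a = chi_a,
         chi_p = 3 * chi_a / (3 - chi_a), Nd = 1 / 3,
         Vp = Vp, mp = rho_p * Vp),
    class = "magnetic_particle")
}

#' @rdname magnetic_particle
#' @details `myone_bead()` returns the nominal 1 um bead used throughout
#'   (Rp = 0.5 um, rho_p = 1800 kg/m^3, Msp = 4.3e4 A/m, chi_a = 1.4).
#' @export
myone_bead <- function() magnetic_particle()

#' @export
print.magnetic_particle <- function(x, ...) {
  cat(sprintf(
    "<magnetic_particle> Rp = %.3g um, rho = %g kg/m3, Msp = %.3g A/m, chi_a = %g (chi_p = %.4g)\n",
    1e6 * x$Rp, x$rho_p, x$Msp, x$chi_a, x$chi_p))
  invisible(x)
}

corner_check <- function(m, x, y) {
  if (nrow(m) == 0) return(invisible())
  for (e in seq_len(nrow(m))) {
    cxs <- m[e, 1] + c(-1, 1) * m[e, 3]
    cys <- m[e, 2] + c(-1, 1) * m[e, 4]
    # a point is a corner iff x equals a vertical face and y a horizontal face
    onx <- (x == cxs[1]) | (x == cxs[2])
    ony <- (y == cys[1]) | (y == cys[2])
    if (any(onx & ony))
      stop("singular evaluation: point coincides with an element corner")
  }
  invisible()
}

#' Magnetic field of a single element
#'
#' Closed-form field (A/m) of one magnetized rectangular element alone, with
#' no bias contribution, evaluated at channel coordinates.  The field diverges
#' logarithmically at the four corners; evaluation exactly on a corner is a
#' singular-evaluation error.
#'
#' @param elem a [rect_element()].
#' @param x,y evaluation point(s) (m), vectorized.
#' @return data.frame with columns `Hx`, `Hy` (A/m).
#' @export
element_field <- function(elem, x, y) {
  stopifnot(inherits(elem, "rect_element"), length(x) == length(y))
  m <- elem_matrix_from_list(list(elem))
  corner_check(m, x, y)
  H <- cpp_total_field(m, 0, as.numeric(x), as.numeric(y))
  as.data.frame(H)
}

#' Total field of an element array plus bias
#'
#' Superposition of [element_field()] over all elements plus the uniform bias
#' `(0, Hbias)`.
#'
#' @param arr an [element_array()].
#' @inheritParams element_field
#' @return data.frame with columns `Hx`, `Hy` (A/m).
#' @export
total_field <- function(arr, x, y) {
  stopifnot(inherits(arr, "element_array"), length(x) == length(y))
  m <- elem_matrix(arr)
  corner_check(m, x, y)
  as.data.frame(cpp_total_field(m, arr$Hbias, as.numeric(x), as.numeric(y)))
}

#' Particle magnetization response f(H)
#'
#' Piecewise magnetization model with self-demagnetization and saturation:
#' below the switch field `Msp / chi_a` the bead magnetizes linearly with the
#' apparent susceptibility (`f = chi_a`, equivalently `3 chi_p / (chi_p + 3)`
#' for a non-magnetic carrier); at and above it the bead is saturated and
#' `f = Msp / H`.  Continuous at the switch.
#'
#' @param p a [magnetic_particle()].
#' @param Hmag applied field magnitude(s) (A/m), `>= 0`.
#' @return dimensionless response, same length as `Hmag`.
#' @export
f_of_H <- function(p, Hmag) {
  stopifnot(inherits(p, "magnetic_particle"))
  if (any(Hmag < 0)) stop("f_of_H: Hmag must be non-negative")
  Hsat <- p$Msp / p$chi_a
  ifelse(Hmag < Hsat, p$chi_a, p$Msp / Hmag)
}

#' Effective-dipole magnetic force on a bead
#'
#' `F = mu0 Vp f(|Ha|) (Ha . grad) Ha` with the analytic field Jacobian.
#' Within a distance `rex` of an element corner the evaluation point is
#' projected onto the exclusion circle, which clamps the (log-divergent) force
#' to its value on that circle; such points are flagged in `clamped`.
#'
#' @param arr an [element_array()].
#' @param p a [magnetic_particle()].
#' @param x,y evaluation point(s) (m), vectorized.
#' @param rex corner exclusion radius (m); default 0.25 um (half the nominal
#'   bead radius).
#' @return data.frame with columns `Fmx`, `Fmy` (N) and logical `clamped`.
#' @export
magnetic_force <- function(arr, p, x, y, rex = 0.25e-6) {
  stopifnot(inherits(arr, "element_array"), inherits(p, "magnetic_particle"),
            length(x) == length(y))
  res <- cpp_magnetic_force(elem_matrix(arr), arr$Hbias, p$Vp, p$Msp, p$chi_a,
                            as.numeric(x), as.numeric(y), rex)
  out <- as.data.frame(res$F)
  out$clamped <- res$clamped
  out
}

#' Field and force profile along a sampled segment
#'
#' Samples [total_field()] and [magnetic_force()] along the straight segment
#' from `(x0, y0)` to `(x1, y1)`.  Sign convention: `Fmy < 0` is attraction
#' toward an element below the line.
#'
#' @inheritParams magnetic_force
#' @param x0,y0,x1,y1 segment end points (m).
#' @param n number of samples.
#' @return data.frame with columns `x_m`, `y_m`, `Hx_A_per_m`, `Hy_A_per_m`,
#'   `Fmx_N`, `Fmy_N`, suitable for CSV export.
#' @export
force_profile <- function(arr, p, x0, y0, x1, y1, n = 501, rex = 0.25e-6) {
  s <- seq(0, 1, length.out = n)
  x <- x0 + s * (x1 - x0)
  y <- y0 + s * (y1 - y0)
  H <- total_field(arr, x, y)
  Fm <- magnetic_force(arr, p, x, y, rex = rex)
  data.frame(x_m = x, y_m = y,
             Hx_A_per_m = H$Hx, Hy_A_per_m = H$Hy,
             Fmx_N = Fm$Fmx, Fmy_N = Fm$Fmy)
}
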