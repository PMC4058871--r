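# Shared fixtures for the suite.  Coarse solver settings keep CFD-backed
# tests fast; physics-accuracy tests that need the production resolution set
# it explicitly.

coarse_solver <- function(...) {
  solver_settings(dy_um = 4, dx_fine_um = 4, upstream_um = 300,
                  downstream_um = 400, ...)
}

# a short-channel conventional scenario: same element layout as the nominal
# 3-element embedded array, but the channel is truncated downstream so
# integrator-equivalence runs stay cheap (fates are decided well before 3 mm)
short_conventional <- function(n = 3, Lc = 3e-3, n_streams = 100) {
  chan <- channel(length = Lc)
  scenario(chan = chan, array = build_conventional(n, chan = chan),
           n_streams = n_streams)
}

# independent surface-charge quadrature oracle for the element field:
# integrate the 2D Coulomb kernel over the two charged faces
oracle_field <- function(elem, x, y) {
  w <- elem$w; h <- elem$h; Mes <- elem$Mes
  xl <- x - elem$center_x; yl <- y - elem$center_y
  kx <- function(xp, ys, s) s * Mes / (2 * pi) * (xl - xp) /
    ((xl - xp)^2 + (yl - ys)^2)
  ky <- function(xp, ys, s) s * Mes / (2 * pi) * (yl - ys) /
    ((xl - xp)^2 + (yl - ys)^2)
  q <- function(f, ys, s) stats::integrate(f, -w, w, ys = ys, s = s,
                                           rel.tol = 1e-12,
                                           abs.tol = 1e-16)$value
  c(Hx = q(kx, h, 1) + q(kx, -h, -1),
    Hy = q(ky, h, 1) + q(ky, -h, -1))
}
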