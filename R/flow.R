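#' Flow-solver settings
#'
#' The steady flow is solved on a rectilinear staggered grid covering a
#' window of the channel around the elements; outside the window the flow is
#' the exact fully developed profile (disturbances from the obstacles decay
#' exponentially on the scale of the channel height, and no appreciable
#' magnetic force acts there).  Cells are uniform and fine near the elements
#' and geometrically stretched away from them.
#'
#' @param dy_um uniform vertical cell size (um); must divide the channel
#'   height and the element vertical placement.
#' @param dx_fine_um horizontal cell size in the element region (um).
#' @param dx_max_um cap on stretched cell size (um).
#' @param pad_um width of the uniformly fine region beyond the elements (um).
#' @param upstream_um,downstream_um window extent upstream of the first and
#'   downstream of the last element (um).
#' @param stretch geometric growth ratio of the graded cells.
#' @param picard_tol relative velocity-change tolerance of the Picard
#'   (Oseen) iteration on the convective term.
#' @param max_picard iteration cap; exceeding it is a convergence error.
#' @return named list of settings.
#' @export
solver_settings <- function(dy_um = 2, dx_fine_um = 2, dx_max_um = 20,
                            pad_um = 40, upstream_um = 600,
                            downstream_um = 1000, stretch = 1.15,
                            picard_tol = 1e-8, max_picard = 25) {
  list(dy_um = dy_um, dx_fine_um = dx_fine_um, dx_max_um = dx_max_um,
       pad_um = pad_um, upstream_um = upstream_um,
       downstream_um = downstream_um, stretch = stretch,
       picard_tol = picard_tol, max_picard = max_picard)
}

#' Fully developed laminar profile between parallel plates
#'
#' `u(y) = 6 u_avg (y/Hc)(1 - y/Hc)`; the depth-average is `u_avg` and the
#' per-unit-depth volumetric flow rate is `u_avg * Hc`.
#'
#' @param chan a [channel()].
#' @param u_avg average velocity (m/s).
#' @param y height(s) above the floor (m), within `[0, Hc]`.
#' @return streamwise velocity (m/s).
#' @export
poiseuille <- function(chan, u_avg, y) {
  if (any(y < -1e-15) || any(y > chan$Hc + 1e-15))
    stop("poiseuille: y outside the channel")
  s <- pmin(pmax(y / chan$Hc, 0), 1)
  6 * u_avg * s * (1 - s)
}

# cell-averaged parabola over [y0, y1]: exact integral so the discrete inlet
# flux equals u_avg * Hc to machine precision
poiseuille_cell_avg <- function(Hc, u_avg, y0, y1) {
  antider <- function(y) 6 * u_avg * (y^2 / (2 * Hc) - y^3 / (3 * Hc^2))
  (antider(y1) - antider(y0)) / (y1 - y0)
}

graded_widths <- function(L, d0, dmax, r) {
  if (L <= 1e-15) return(numeric(0))
  wds <- c()
  d <- d0 * r
  while (sum(wds) < L) {
    d <- min(d, dmax)
    wds <- c(wds, d)
    d <- d * r
    if (length(wds) > 10000) stop("graded_widths: failed to span region")
  }
  wds * (L / sum(wds))
}

#' Build the structured flow grid for a scenario
#'
#' Rectilinear staggered grid over a window of the channel, with an obstacle
#' mask for flow-invasive elements.  Element faces must coincide with cell
#' faces (they do for the default sizes; otherwise adjust `dx_fine_um` /
#' `dy_um`).
#'
#' @param s a [scenario()].
#' @param settings see [solver_settings()]; defaults to `s$solver`.
#' @return object of class `flow_grid`: face coordinates `xf`, `yf`, cell
#'   centers, cell widths, and logical obstacle mask `blocked` (nx x ny).
#' @export
flow_grid <- function(s, settings = s$solver) {
  um <- 1e-6
  Hc <- s$channel$Hc
  Lc <- s$channel$Lc
  dy <- settings$dy_um * um
  ny <- round(Hc / dy)
  if (abs(ny * dy - Hc) > 1e-12)
    stop("flow_grid: dy_um must divide the channel height")
  dxf <- settings$dx_fine_um * um
  dxm <- settings$dx_max_um * um

  m <- elem_matrix(s$array)
  inv <- nrow(m) > 0 & (if (nrow(m)) m[, 2] + m[, 4] > 1e-12 else logical(0))
  if (nrow(m) > 0) {
    xlo_e <- min(m[, 1] - m[, 3])
    xhi_e <- max(m[, 1] + m[, 3])
  } else {
    xlo_e <- xhi_e <- min(Lc / 2, 1e-3)
  }
  pad <- round(settings$pad_um * um / dxf) * dxf
  x0w <- max(0, xlo_e - pad - settings$upstream_um * um)
  x1w <- min(Lc, xhi_e + pad + settings$downstream_um * um)
  flo <- max(x0w, xlo_e - pad)
  fhi <- min(x1w, xhi_e + pad)
  nfine <- max(1L, round((fhi - flo) / dxf))
  fine_faces <- flo + (0:nfine) * ((fhi - flo) / nfine)

  wl <- rev(graded_widths(flo - x0w, dxf, dxm, settings$stretch))
  wr <- graded_widths(x1w - fhi, dxf, dxm, settings$stretch)
  xf <- c(flo - rev(cumsum(rev(wl))), fine_faces, fhi + cumsum(wr))
  xf[1] <- x0w
  xf[length(xf)] <- x1w
  nx <- length(xf) - 1
  yf <- (0:ny) * dy

  blocked <- matrix(FALSE, nx, ny)
  if (any(inv)) {
    for (e in which(inv)) {
      fi <- function(v, faces, what) {
        i <- which.min(abs(faces - v))
        if (abs(faces[i] - v) > 1e-10)
          stop("flow_grid: element ", what,
               " face does not coincide with a grid face; adjust dx_fine_um/dy_um")
        i
      }
      iL <- fi(m[e, 1] - m[e, 3], xf, "left")
      iR <- fi(m[e, 1] + m[e, 3], xf, "right")
      jB <- fi(max(0, m[e, 2] - m[e, 4]), yf, "bottom")
      jT <- fi(min(Hc, m[e, 2] + m[e, 4]), yf, "top")
      blocked[iL:(iR - 1), jB:(jT - 1)] <- TRUE
    }
  }

  structure(
    list(xf = xf, yf = yf, xc = (xf[-1] + xf[-length(xf)]) / 2,
         yc = (yf[-1] + yf[-length(yf)]) / 2,
         dxc = diff(xf), dy = dy, nx = nx, ny = ny,
         blocked = blocked, window = c(x0w, x1w)),
    class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("<flow_grid> %d x %d cells over x = [%.3f, %.3f] mm, %d blocked\n",
              x$nx, x$ny, 1e3 * x$window[1], 1e3 * x$window[2],
              sum(x$blocked)))
  invisible(x)
}

# Assemble the linearized (Oseen) steady incompressible system on the
# staggered grid.  Unknown ordering: u faces ((nx+1) x ny, column-major over
# (f, j)), then v faces (nx x (ny+1)), then cell pressures.  U0/V0 carry the
# previous Picard iterate for the upwinded convective fluxes (zero matrices
# give the Stokes system).  Returns list(A, b).
assemble_flow <- function(grid, eta, rho, uin, U0, V0, sink = NULL) {
  nx <- grid$nx; ny <- grid$ny
  dxc <- grid$dxc; dy <- grid$dy
  xc <- grid$xc
  B <- grid$blocked
  Nu <- (nx + 1) * ny
  Nv <- nx * (ny + 1)
  Np <- nx * ny
  N <- Nu + Nv + Np
  iu <- function(f, j) (f - 1) * ny + j
  iv <- function(i, g) Nu + (i - 1) * (ny + 1) + g
  ip <- function(i, j) Nu + Nv + (i - 1) * ny + j

  Bpad <- rbind(FALSE, cbind(FALSE, B, FALSE), FALSE) # (nx+2) x (ny+2), 1-shift
  Bat <- function(i, j) Bpad[cbind(i + 1, j + 1)]     # blocked with ghosts FALSE

  ti <- tj <- tx <- vector("list", 32)
  bvec <- numeric(N)
  put <- function(slot, i, j, x) {
    ti[[slot]] <<- i; tj[[slot]] <<- j; tx[[slot]] <<- x
  }
  slot <- 0
  nslot <- function() { slot <<- slot + 1; slot }

  ## ---- u Dirichlet faces (inlet, outlet, obstacle-adjacent) ----
  fgrid <- rep(1:(nx + 1), each = ny)
  jgrid <- rep(1:ny, times = nx + 1)
  udir <- fgrid == 1 | fgrid == nx + 1 |
    Bat(fgrid - 1, jgrid) | Bat(fgrid, jgrid)
  rows <- iu(fgrid[udir], jgrid[udir])
  put(nslot(), rows, rows, rep(1, length(rows)))
  uval <- ifelse(fgrid == 1 | fgrid == nx + 1, uin[jgrid], 0)
  bvec[rows] <- uval[udir]

  ## ---- u momentum (interior, non-Dirichlet) ----
  sel <- !udir & fgrid >= 2 & fgrid <= nx
  f <- fgrid[sel]; j <- jgrid[sel]
  dxu <- xc[f] - xc[f - 1]
  De <- eta * dy / dxc[f]
  Dw <- eta * dy / dxc[f - 1]
  nblk <- Bat(f - 1, j + 1) & Bat(f, j + 1)   # solid wall at yf above
  sblk <- Bat(f - 1, j - 1) & Bat(f, j - 1)
  # channel walls use a second-order one-sided shear stencil,
  # tau = eta (9 uP - uN)/(3 dy), split so that the parabolic profile is an
  # exact discrete solution: the wall side carries (8/3) eta dxu/dy on uP
  # (no link) and the opposite link gains eta dxu/(3 dy).  Obstacle faces
  # keep the robust half-cell (first-order) form.
  Dn <- ifelse(j == ny, (8 / 3) * eta * dxu / dy,
        ifelse(nblk, eta * dxu / (dy / 2), eta * dxu / dy))
  Ds <- ifelse(j == 1, (8 / 3) * eta * dxu / dy,
        ifelse(sblk, eta * dxu / (dy / 2), eta * dxu / dy))
  Dn <- Dn + ifelse(j == 1 & !nblk, eta * dxu / (3 * dy), 0)
  Ds <- Ds + ifelse(j == ny & !sblk, eta * dxu / (3 * dy), 0)

  Uat <- function(ff, jj) U0[cbind(ff, jj)]
  Vat <- function(ii, gg) V0[cbind(ii, gg)]
  Fe <- rho * dy * 0.5 * (Uat(f, j) + Uat(f + 1, j))
  Fw <- rho * dy * 0.5 * (Uat(f - 1, j) + Uat(f, j))
  Fn <- rho * dxu * 0.5 * (Vat(f - 1, j + 1) + Vat(f, j + 1))
  Fs <- rho * dxu * 0.5 * (Vat(f - 1, j) + Vat(f, j))

  aE <- De + pmax(-Fe, 0)
  aW <- Dw + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0)
  aS <- Ds + pmax(Fs, 0)
  aP <- aE + aW + aN + aS + (Fe - Fw + Fn - Fs)

  rows <- iu(f, j)
  put(nslot(), rows, rows, aP)
  put(nslot(), rows, iu(f + 1, j), -aE)
  put(nslot(), rows, iu(f - 1, j), -aW)
  kn <- j < ny
  put(nslot(), rows[kn], iu(f[kn], j[kn] + 1), -aN[kn])
  ks <- j > 1
  put(nslot(), rows[ks], iu(f[ks], j[ks] - 1), -aS[ks])
  # pressure gradient: + dy (pE - pW)
  put(nslot(), rows, ip(f, j), rep(dy, length(rows)))
  put(nslot(), rows, ip(f - 1, j), rep(-dy, length(rows)))
  if (!is.null(sink)) {
    sE <- sink$Su[cbind(f, j)]
    sW <- sink$Su[cbind(f - 1, j)]
    bvec[rows] <- bvec[rows] + 0.5 * (sE + sW) * dxu * dy
  }

  ## ---- v Dirichlet faces (walls, obstacle-adjacent) ----
  igrid <- rep(1:nx, each = ny + 1)
  ggrid <- rep(1:(ny + 1), times = nx)
  vdir <- ggrid == 1 | ggrid == ny + 1 |
    Bat(igrid, ggrid - 1) | Bat(igrid, ggrid)
  rows <- iv(igrid[vdir], ggrid[vdir])
  put(nslot(), rows, rows, rep(1, length(rows)))

  ## ---- v momentum (interior, non-Dirichlet) ----
  sel <- !vdir
  i <- igrid[sel]; g <- ggrid[sel]
  Dn <- eta * dxc[i] / dy
  Ds <- eta * dxc[i] / dy
  eblk <- Bat(i + 1, g - 1) & Bat(i + 1, g)
  wblk <- Bat(i - 1, g - 1) & Bat(i - 1, g)
  xcp <- c(xc, grid$xf[nx + 1]) # padded for i = nx lookup (unused there)
  De <- ifelse(i == nx, 0,
        ifelse(eblk, eta * dy / (dxc[i] / 2), eta * dy / (xcp[i + 1] - xc[i])))
  xcm <- c(grid$xf[1], xc)
  Dw <- ifelse(i == 1, eta * dy / (dxc[1] / 2),
        ifelse(wblk, eta * dy / (dxc[i] / 2), eta * dy / (xc[i] - xcm[i])))

  # interior v faces have g in 2..ny, so the u rows g-1 and g both exist
  Fe <- rho * dy * 0.5 * (Uat(i + 1, g - 1) + Uat(i + 1, g))
  Fw <- rho * dy * 0.5 * (Uat(i, g - 1) + Uat(i, g))
  Fn <- rho * dxc[i] * 0.5 * (Vat(i, g) + Vat(i, g + 1))
  Fs <- rho * dxc[i] * 0.5 * (Vat(i, g - 1) + Vat(i, g))

  aE <- De + pmax(-Fe, 0)
  aW <- Dw + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0)
  aS <- Ds + pmax(Fs, 0)
  aP <- aE + aW + aN + aS + (Fe - Fw + Fn - Fs)

  rows <- iv(i, g)
  put(nslot(), rows, rows, aP)
  ke <- i < nx
  put(nslot(), rows[ke], iv(i[ke] + 1, g[ke]), -aE[ke])
  kw <- i > 1
  put(nslot(), rows[kw], iv(i[kw] - 1, g[kw]), -aW[kw])
  put(nslot(), rows, iv(i, g + 1), -aN)
  put(nslot(), rows, iv(i, g - 1), -aS)
  # pressure gradient: + dxc (pN - pS)
  put(nslot(), rows, ip(i, g), dxc[i])
  put(nslot(), rows, ip(i, g - 1), -dxc[i])
  if (!is.null(sink)) {
    sN <- sink$Sv[cbind(i, g)]
    sS <- sink$Sv[cbind(i, g - 1)]
    bvec[rows] <- bvec[rows] + 0.5 * (sN + sS) * dxc[i] * dy
  }

  ## ---- continuity / pressure rows ----
  icell <- rep(1:nx, each = ny)
  jcell <- rep(1:ny, times = nx)
  open <- !B[cbind(icell, jcell)]
  # pin the pressure in one open cell far from the obstacles
  pin <- icell == nx & jcell == 1
  cont <- open & !pin
  ii <- icell[cont]; jj <- jcell[cont]
  rows <- ip(ii, jj)
  put(nslot(), rows, iu(ii + 1, jj), rep(dy, length(rows)))
  put(nslot(), rows, iu(ii, jj), rep(-dy, length(rows)))
  put(nslot(), rows, iv(ii, jj + 1), dxc[ii])
  put(nslot(), rows, iv(ii, jj), -dxc[ii])
  rows <- ip(icell[!cont], jcell[!cont])
  put(nslot(), rows, rows, rep(1, length(rows)))

  keep <- !vapply(ti, is.null, TRUE)
  A <- Matrix::sparseMatrix(i = unlist(ti[keep]), j = unlist(tj[keep]),
                            x = unlist(tx[keep]), dims = c(N, N))
  list(A = A, b = bvec, Nu = Nu, Nv = Nv, Np = Np)
}

#' Solve the steady incompressible flow in the channel
#'
#' Finite-volume discretization on the staggered grid (first-order upwind
#' convection, exact parabolic inflow/outflow, no-slip walls and blocked-cell
#' obstacles), linearized by Picard (Oseen) iteration and solved directly by
#' sparse LU at each pass.  At the channel Reynolds numbers of interest
#' (about 2) a handful of passes reaches the nonlinear fixed point.
#'
#' @param s a [scenario()].
#' @param grid a [flow_grid()]; built from `s` when `NULL`.
#' @param sink optional momentum-sink field, a list with matrices `Su`, `Sv`
#'   (N/m^3 on grid cells), entering the momentum equations as a body-force
#'   density (two-way coupling).
#' @return object of class `flow_field` with staggered velocities `U`
#'   ((nx+1) x ny) and `V` (nx x (ny+1)), cell pressures `P`, node (corner)
#'   velocities `Un`, `Vn` used for interpolation, the Picard residual
#'   history, and the grid.
#' @export
solve_flow <- function(s, grid = NULL, sink = NULL) {
  if (is.null(grid)) grid <- flow_grid(s)
  nx <- grid$nx; ny <- grid$ny
  eta <- s$fluid$eta; rho <- s$fluid$rho
  uin <- poiseuille_cell_avg(s$channel$Hc, s$u_avg,
                             grid$yf[-(ny + 1)], grid$yf[-1])

  U <- matrix(0, nx + 1, ny)
  V <- matrix(0, nx, ny + 1)
  hist <- numeric(0)
  for (it in seq_len(s$solver$max_picard)) {
    sys <- assemble_flow(grid, eta, rho, uin, U, V, sink)
    x <- as.numeric(Matrix::solve(sys$A, sys$b, sparse = TRUE))
    # unknown ordering is j-fastest within each block
    Un_ <- t(matrix(x[seq_len(sys$Nu)], ny, nx + 1))
    Vn_ <- t(matrix(x[sys$Nu + seq_len(sys$Nv)], ny + 1, nx))
    P_ <- t(matrix(x[sys$Nu + sys$Nv + seq_len(sys$Np)], ny, nx))
    delta <- max(abs(Un_ - U), abs(Vn_ - V)) / max(abs(Un_), 1e-300)
    hist <- c(hist, delta)
    U <- Un_; V <- Vn_; P <- P_
    if (delta < s$solver$picard_tol) break
  }
  if (delta >= s$solver$picard_tol)
    stop("solve_flow: Picard iteration did not converge; residual history: ",
         paste(signif(hist, 3), collapse = ", "))

  # corner-node velocities for continuous interpolation; exactly zero on
  # every no-slip boundary (walls and obstacle surfaces)
  Bpad <- rbind(FALSE, cbind(FALSE, grid$blocked, FALSE), FALSE)
  fg <- rep(1:(nx + 1), times = ny + 1)
  gg <- rep(1:(ny + 1), each = nx + 1)
  nodeblk <- matrix(Bpad[cbind(fg, gg)] | Bpad[cbind(fg + 1, gg)] |
                    Bpad[cbind(fg, gg + 1)] | Bpad[cbind(fg + 1, gg + 1)],
                    nx + 1, ny + 1)
  Un <- matrix(0, nx + 1, ny + 1)
  Un[, 2:ny] <- 0.5 * (U[, 1:(ny - 1)] + U[, 2:ny])
  Vn <- matrix(0, nx + 1, ny + 1)
  Vn[2:nx, ] <- 0.5 * (V[1:(nx - 1), ] + V[2:nx, ])
  Vn[nx + 1, ] <- V[nx, ]
  Un[nodeblk] <- 0
  Vn[nodeblk] <- 0

  div <- dy_div_residual(grid, U, V)
  structure(
    list(grid = grid, U = U, V = V, P = P, Un = Un, Vn = Vn,
         picard_history = hist, div_max = div,
         sink = sink, u_avg = s$u_avg, Hc = s$channel$Hc, Lc = s$channel$Lc,
         rho = rho),
    class = "flow_field")
}

dy_div_residual <- function(grid, U, V) {
  nx <- grid$nx; ny <- grid$ny
  div <- (U[2:(nx + 1), , drop = FALSE] - U[1:nx, , drop = FALSE]) * grid$dy +
    (V[, 2:(ny + 1), drop = FALSE] - V[, 1:ny, drop = FALSE]) * grid$dxc
  div[grid$blocked] <- 0
  max(abs(div))
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d x %d cells, %d Picard pass(es), last delta %.2e, max |div| %.2e\n",
    x$grid$nx, x$grid$ny, length(x$picard_history),
    tail(x$picard_history, 1), x$div_max))
  invisible(x)
}

#' Sample the flow velocity at arbitrary points
#'
#' Continuous bilinear interpolation of the corner-node velocities; exactly
#' zero on no-slip boundaries.  Outside the solved window the exact fully
#' developed profile is returned.  Querying a point inside an obstacle is an
#' error.
#'
#' @param ff a [flow_field()] from [solve_flow()].
#' @param x,y query point(s) (m).
#' @return data.frame with columns `u`, `v` (m/s).
#' @export
sample_velocity <- function(ff, x, y) {
  g <- ff$grid
  if (any(y < 0 | y > ff$Hc)) stop("sample_velocity: point outside the channel")
  n <- length(x)
  u <- v <- numeric(n)
  inw <- x >= g$window[1] & x <= g$window[2]
  chan <- channel(ff$Hc, ff$Lc)
  u[!inw] <- poiseuille(chan, ff$u_avg, y[!inw])
  if (any(inw)) {
    xi <- pmin(pmax(findInterval(x[inw], g$xf), 1), g$nx)
    yi <- pmin(pmax(findInterval(y[inw], g$yf), 1), g$ny)
    if (any(g$blocked[cbind(xi, yi)]))
      stop("sample_velocity: query inside an obstacle")
    tx <- (x[inw] - g$xf[xi]) / g$dxc[xi]
    ty <- (y[inw] - g$yf[yi]) / g$dy
    bl <- cbind(xi, yi); br <- cbind(xi + 1, yi)
    tl <- cbind(xi, yi + 1); tr <- cbind(xi + 1, yi + 1)
    u[inw] <- (1 - tx) * (1 - ty) * ff$Un[bl] + tx * (1 - ty) * ff$Un[br] +
      (1 - tx) * ty * ff$Un[tl] + tx * ty * ff$Un[tr]
    v[inw] <- (1 - tx) * (1 - ty) * ff$Vn[bl] + tx * (1 - ty) * ff$Vn[br] +
      (1 - tx) * ty * ff$Vn[tl] + tx * ty * ff$Vn[tr]
  }
  data.frame(u = u, v = v)
}

#' Mass flux through each vertical cross-section
#'
#' @param ff a [flow_field()].
#' @return numeric vector, one per x-face: per-unit-depth volumetric flux
#'   (m^2/s) through that cross-section.
#' @export
cross_section_flux <- function(ff) {
  colSums(t(ff$U) * ff$grid$dy)
}

#' Stream function of a solved flow field
#'
#' Integrated upward from the floor (`psi = 0` there); differences between
#' iso-lines equal the mass flux per unit depth between them (kg/s).  For the
#' unobstructed channel `psi(top) = rho u_avg Hc`.
#'
#' @param ff a [flow_field()].
#' @return list with `psi` ((nx+1) x (ny+1) node matrix, kg/s per unit
#'   depth), and node coordinates `xf`, `yf`.
#' @export
stream_function <- function(ff) {
  g <- ff$grid
  psi <- cbind(0, t(apply(ff$U * g$dy * ff$rho, 1, cumsum)))
  list(psi = psi, xf = g$xf, yf = g$yf)
}

# flow description handed to the C++ tracker: either analytic (unobstructed)
# or the node-interpolated solved field, with the analytic profile outside
# the window
flow_to_cpp <- function(s, ff = NULL) {
  base <- list(analytic = is.null(ff), u_avg = s$u_avg,
               Hc = s$channel$Hc, Lc = s$channel$Lc)
  if (!is.null(ff)) {
    base$xn <- ff$grid$xf
    base$yn <- ff$grid$yf
    base$Un <- ff$Un
    base$Vn <- ff$Vn
  }
  base
}
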