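test_that("closed-form element field matches the surface-charge quadrature oracle", {
  e <- rect_element(0, 0, 40e-6, 40e-6, 8.6e5)
  # a representative off-axis point
  H <- element_field(e, 30e-6, 50e-6)
  Ho <- oracle_field(e, 30e-6, 50e-6)
  expect_equal(H$Hx, Ho[["Hx"]], tolerance = 1e-6)
  expect_equal(H$Hy, Ho[["Hy"]], tolerance = 1e-6)

  # 100 random points outside the element
  set.seed(42)
  n <- 0
  while (n < 100) {
    x <- runif(1, -150e-6, 150e-6)
    y <- runif(1, -150e-6, 150e-6)
    if (abs(x) < 22e-6 && abs(y) < 22e-6) next # skip points on/near faces
    n <- n + 1
    H <- element_field(e, x, y)
    Ho <- oracle_field(e, x, y)
    expect_lt(max(abs(c(H$Hx - Ho[["Hx"]], H$Hy - Ho[["Hy"]]))) /
                sqrt(sum(Ho^2)), 1e-6)
  }
})

test_that("element field has odd Hx symmetry and a dipole far field", {
  e <- rect_element(0, 0, 40e-6, 40e-6, 8.6e5)
  # centerline: Hx = 0 by odd symmetry
  expect_equal(element_field(e, rep(0, 3), c(25e-6, 60e-6, -90e-6))$Hx,
               rep(0, 3))
  expect_equal(element_field(e, c(10e-6, -10e-6), c(50e-6, 50e-6))$Hx,
               c(1, -1) * element_field(e, 10e-6, 50e-6)$Hx)

  # far field: point line-dipole of moment Mes * W * H per unit length
  r <- 100 * 20e-6
  m <- 8.6e5 * 40e-6 * 40e-6
  for (th in c(0, pi / 7, pi / 3, 2)) {
    x <- r * sin(th); y <- r * cos(th) # th from the magnetization axis
    H <- element_field(e, x, y)
    # 2D line dipole: Hr = m cos(th)/(2 pi r^2), Hth = m sin(th)/(2 pi r^2)
    Hr <- m * cos(th) / (2 * pi * r^2)
    Hth <- m * sin(th) / (2 * pi * r^2)
    Hd <- c(Hr * sin(th) + Hth * cos(th), Hr * cos(th) - Hth * sin(th))
    expect_lt(sqrt(sum((c(H$Hx, H$Hy) - Hd)^2)) / sqrt(sum(Hd^2)), 0.01)
  }
})

test_that("total field superposes elements linearly over a uniform bias", {
  # empty array: bias only
  H0 <- total_field(element_array(Hbias = 3.9e5), 1e-3, 5e-5)
  expect_equal(c(H0$Hx, H0$Hy), c(0, 3.9e5))

  # linearity in the magnetization: two half-strength fields sum to the
  # full-strength field of the same rectangle
  e_full <- rect_element(1e-3, -2e-5, 40e-6, 40e-6, 8.6e5)
  e_half <- rect_element(1e-3, -2e-5, 40e-6, 40e-6, 4.3e5)
  x <- c(0.95e-3, 1.02e-3, 1.2e-3); y <- c(10e-6, 90e-6, 5e-6)
  expect_equal(element_field(e_half, x, y) + element_field(e_half, x, y),
               element_field(e_full, x, y))

  # N-element field is the sum of single-element fields plus bias
  arr <- build_stair_step(3, b = 120e-6)
  Ht <- total_field(arr, x, y)
  Hs <- Reduce(`+`, lapply(arr$elements, function(e)
    as.matrix(element_field(e, x, y))))
  expect_equal(Ht$Hx, Hs[, "Hx"], tolerance = 1e-14)
  expect_equal(Ht$Hy, Hs[, "Hy"] + 3.9e5, tolerance = 1e-14)
})

test_that("field is divergence- and curl-free outside the elements", {
  arr <- build_stair_step(3, b = 80e-6)
  set.seed(7)
  pts <- 0
  dstep <- 1e-8
  while (pts < 30) {
    x <- runif(1, 0.9e-3, 1.4e-3); y <- runif(1, 0, 2e-4)
    m <- magsep:::elem_matrix(arr)
    inside <- any(abs(x - m[, 1]) < m[, 3] + 2e-6 &
                  abs(y - m[, 2]) < m[, 4] + 2e-6)
    if (inside) next
    pts <- pts + 1
    Hxp <- total_field(arr, x + dstep, y); Hxm <- total_field(arr, x - dstep, y)
    Hyp <- total_field(arr, x, y + dstep); Hym <- total_field(arr, x, y - dstep)
    dHxdx <- (Hxp$Hx - Hxm$Hx) / (2 * dstep)
    dHydy <- (Hyp$Hy - Hym$Hy) / (2 * dstep)
    dHydx <- (Hxp$Hy - Hxm$Hy) / (2 * dstep)
    dHxdy <- (Hyp$Hx - Hym$Hx) / (2 * dstep)
    scale <- max(abs(c(dHxdx, dHydy, dHydx, dHxdy)), 1)
    expect_lt(abs(dHxdx + dHydy) / scale, 1e-3)
    expect_lt(abs(dHydx - dHxdy) / scale, 1e-3)
  }
})

test_that("magnetization response is piecewise with a continuous switch", {
  p <- myone_bead()
  Hsw <- p$Msp / p$chi_a
  expect_equal(Hsw, 4.3e4 / 1.4)
  expect_equal(f_of_H(p, c(0, 1e3, Hsw * 0.999)), rep(1.4, 3))
  # saturated branch at the nominal bias
  expect_equal(f_of_H(p, 3.9e5), 4.3e4 / 3.9e5)
  # equivalent chi_p form below saturation (chi_f = 0)
  expect_equal(3 * p$chi_p / (p$chi_p + 3), p$chi_a)
  # continuity at the switch
  eps <- Hsw * 1e-9
  expect_lt(abs(f_of_H(p, Hsw - eps) - f_of_H(p, Hsw + eps)), 1e-8)
  expect_error(f_of_H(p, -1), "non-negative")
})

test_that("magnetic force vanishes in a uniform field and matches finite differences", {
  p <- myone_bead()
  # no elements: uniform bias exerts no force
  Fm <- magnetic_force(element_array(Hbias = 3.9e5), p, c(1e-3, 2e-3), c(5e-5, 1e-4))
  expect_equal(c(Fm$Fmx, Fm$Fmy), rep(0, 4))

  # analytic gradient vs central differences of the field (step 1e-9 m)
  arr <- build_conventional(2)
  MU0 <- 4e-7 * pi
  set.seed(3)
  for (k in 1:20) {
    x <- runif(1, 0.9e-3, 1.15e-3); y <- runif(1, 2e-6, 1.5e-4)
    Fa <- magnetic_force(arr, p, x, y, rex = 0)
    d <- 1e-9
    H <- total_field(arr, x, y)
    Hmag <- sqrt(H$Hx^2 + H$Hy^2)
    gxx <- (total_field(arr, x + d, y)$Hx - total_field(arr, x - d, y)$Hx) / (2 * d)
    gxy <- (total_field(arr, x, y + d)$Hx - total_field(arr, x, y - d)$Hx) / (2 * d)
    gyx <- (total_field(arr, x + d, y)$Hy - total_field(arr, x - d, y)$Hy) / (2 * d)
    gyy <- (total_field(arr, x, y + d)$Hy - total_field(arr, x, y - d)$Hy) / (2 * d)
    cf <- MU0 * p$Vp * f_of_H(p, Hmag)
    Ffd <- cf * c(H$Hx * gxx + H$Hy * gxy, H$Hx * gyx + H$Hy * gyy)
    expect_equal(c(Fa$Fmx, Fa$Fmy), Ffd, tolerance = 1e-4)
  }
})

test_that("saturated force equals mu0 Vp Msp grad|H| along a line", {
  arr <- build_conventional(3)
  p <- myone_bead()
  MU0 <- 4e-7 * pi
  xs <- seq(0.95e-3, 1.2e-3, length.out = 40)
  ys <- rep(10e-6, 40)
  H <- total_field(arr, xs, ys)
  expect_true(all(sqrt(H$Hx^2 + H$Hy^2) >= p$Msp / p$chi_a)) # saturated
  Fm <- magnetic_force(arr, p, xs, ys, rex = 0)
  d <- 1e-10
  Hmag <- function(x, y) {
    h <- total_field(arr, x, y); sqrt(h$Hx^2 + h$Hy^2)
  }
  gx <- (Hmag(xs + d, ys) - Hmag(xs - d, ys)) / (2 * d)
  gy <- (Hmag(xs, ys + d) - Hmag(xs, ys - d)) / (2 * d)
  expect_equal(Fm$Fmx, MU0 * p$Vp * p$Msp * gx, tolerance = 1e-5)
  expect_equal(Fm$Fmy, MU0 * p$Vp * p$Msp * gy, tolerance = 1e-5)
})

test_that("peak attractive force above a square element scales inversely with its side", {
  p <- myone_bead()
  peak <- vapply(c(40e-6, 80e-6, 120e-6), function(side) {
    arr <- build_conventional(1, W = side, H = side)
    pr <- force_profile(arr, p, 1e-3, 1e-9, 1e-3, 2e-4, n = 20001)
    -min(pr$Fmy_N)
  }, 0)
  # strict ordering, small elements produce the strongest near-surface force
  expect_true(peak[1] > peak[2] && peak[2] > peak[3])
  # exact scale invariance of the closed form: peak * side is constant
  expect_equal(peak[1] * 40, peak[2] * 80, tolerance = 1e-3)
  expect_equal(peak[1] * 40, peak[3] * 120, tolerance = 1e-3)
  # an order-of-magnitude decay one element-height above the surface
  arr <- build_conventional(1)
  pr <- force_profile(arr, p, 1e-3, 1e-9, 1e-3, 2e-4, n = 20001)
  F_at_H <- -pr$Fmy_N[which.min(abs(pr$y_m - 40e-6))]
  expect_lt(F_at_H, 0.2 * peak[1])
  expect_gt(F_at_H, 0.03 * peak[1])
})

test_that("force profile across an array alternates sign and is self-consistent", {
  arr <- build_conventional(5)
  p <- myone_bead()
  pr <- force_profile(arr, p, 0.9e-3, 10e-6, 1.45e-3, 10e-6, n = 1101)
  m <- magsep:::elem_matrix(arr)
  over <- vapply(pr$x_m, function(x) any(abs(x - m[, 1]) < m[, 3] - 2e-6), TRUE)
  gap <- vapply(pr$x_m, function(x)
    all(abs(x - m[, 1]) > m[, 3] + 10e-6) && x > min(m[, 1]) && x < max(m[, 1]),
    TRUE)
  # attractive (downward) above elements, repulsive (upward) over the gaps
  expect_true(all(pr$Fmy_N[over] < 0))
  expect_true(all(pr$Fmy_N[gap] > 0))

  # Fmx odd about each element centerline
  dx <- seq(2e-6, 18e-6, by = 2e-6)
  Fl <- magnetic_force(arr, p, m[3, 1] - dx, rep(10e-6, length(dx)))
  Fr <- magnetic_force(arr, p, m[3, 1] + dx, rep(10e-6, length(dx)))
  expect_equal(Fl$Fmx, -Fr$Fmx, tolerance = 1e-10)

  # profile values equal pointwise calls
  i <- c(5, 100, 600)
  Fp <- magnetic_force(arr, p, pr$x_m[i], pr$y_m[i])
  expect_equal(pr$Fmx_N[i], Fp$Fmx)
  expect_equal(pr$Fmy_N[i], Fp$Fmy)
})

test_that("corner evaluation is singular for fields and clamped for forces", {
  e <- rect_element(0, 0, 40e-6, 40e-6)
  arr <- element_array(list(e))
  p <- myone_bead()
  expect_error(element_field(e, 20e-6, 20e-6), "singular")
  expect_error(total_field(arr, -20e-6, -20e-6), "singular")
  # inside the exclusion radius the force is clamped to its value on the
  # circle: two interior points in the same direction agree exactly
  rex <- 0.25e-6
  nearA <- magnetic_force(arr, p, 20e-6 + 0.1e-6, 20e-6, rex = rex)
  nearB <- magnetic_force(arr, p, 20e-6 + 0.2e-6, 20e-6, rex = rex)
  outside <- magnetic_force(arr, p, 20e-6 + 0.4e-6, 20e-6, rex = rex)
  expect_true(nearA$clamped && nearB$clamped)
  expect_false(outside$clamped)
  expect_equal(nearA$Fmx, nearB$Fmx)
  expect_equal(nearA$Fmy, nearB$Fmy)
  expect_true(abs(nearA$Fmy) >= abs(outside$Fmy)) # clamp keeps the ring value
})
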