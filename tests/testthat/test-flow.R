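test_that("the passive drop is in capillary equilibrium", {
  cv <- initial_semicircle(64)
  m <- semi_mesh(0.05, 64)
  st <- solve_stokes(m, cv, director_on(m, cv, 0, 0), ca = 0)
  expect_lt(max(sqrt(rowSums(st$u^2))), 1e-3)
  expect_lt(max(abs(st$pressure - 1)), 1e-2)
})

test_that("manufactured Stokes solution converges at order >= 2", {
  mms_err <- function(h, n) {
    cv <- initial_semicircle(n)
    m <- build_mesh(cv, h)
    # u = (3x^2y^2, -2xy^3) (divergence-free), P = x^3 + y^3
    bf <- function(x, y) cbind(-3 * x^2 - 6 * y^2, 3 * y^2 + 12 * x * y)
    trac <- function(x, y, nx, ny) {
      P <- x^3 + y^3
      s11 <- -P + 12 * x * y^2
      s12 <- 6 * x^2 * y - 2 * y^3
      s22 <- -P - 12 * x * y^2
      cbind(s11 * nx + s12 * ny, s12 * nx + s22 * ny)
    }
    sv <- function(x, y) cbind(3 * x^2 * y^2, -2 * x * y^3)
    st <- solve_stokes(m, cv, const_director(m, 0, 0), ca = 0,
                       body_force = bf, interface_traction = trac,
                       substrate_velocity = sv)
    X <- st$p2$X
    ue <- cbind(3 * X[, 1]^2 * X[, 2]^2, -2 * X[, 1] * X[, 2]^3)
    sqrt(mean(rowSums((st$u - ue)^2)))
  }
  e1 <- mms_err(0.12, 28)
  e2 <- mms_err(0.06, 54)
  expect_lt(e2, 5e-5)
  expect_gt(log2(e1 / e2), 2)
})

test_that("Stokes response is exactly linear in the activity", {
  cv <- initial_semicircle(32)
  m <- semi_mesh(0.1, 32)
  d <- director_on(m, cv, 0, 0)
  s1 <- solve_stokes(m, cv, d, ca = 1.25)
  s2 <- solve_stokes(m, cv, d, ca = 2.5)
  # the capillary part is affine; activity-driven parts scale linearly
  s0 <- solve_stokes(m, cv, d, ca = 0)
  expect_lt(max(abs((s2$u - s0$u) / 2 - (s1$u - s0$u))), 1e-10)
})

test_that("planar/homeotropic duality holds on the same geometry", {
  cv <- initial_semicircle(32)
  m <- semi_mesh(0.1, 32)
  for (wi in 0:1) {
    d1 <- director_on(m, cv, 0, wi)
    d2 <- director_on(m, cv, 1, wi + 1)
    s1 <- solve_stokes(m, cv, d1, ca = 1.7)
    s2 <- solve_stokes(m, cv, d2, ca = -1.7)
    expect_lt(max(abs(s1$u - s2$u)), 1e-10)
  }
})

test_that("instantaneous flow at (0,0), Ca = -2.5 is a mirror pair of vortices", {
  cv <- initial_semicircle(64)
  m <- semi_mesh(0.05, 64)
  st <- solve_stokes(m, cv, director_on(m, cv, 0, 0), ca = -2.5)
  psi <- streamfunction(st, m)
  vc <- vortex_census(psi, m)
  # the dominant cells form a mirror pair of opposite rotation sense
  # (weak secondary corner eddies may also clear the amplitude threshold
  # in this instantaneous, not-yet-steady flow)
  top <- vc$vortices[order(-abs(vc$vortices$psi))[1:2], ]
  expect_lt(prod(top$psi), 0)
  expect_equal(sort(top$x)[1], 2 - sort(top$x)[2], tolerance = 0.05)
  # mirror equivariance of the flow itself
  pts <- cbind(c(0.5, 0.8, 1.3), c(0.25, 0.5, 0.4))
  ux <- interp_p1(m, st$u[seq_len(nrow(m$V)), 1], pts)
  uxm <- interp_p1(m, st$u[seq_len(nrow(m$V)), 1], cbind(2 - pts[, 1], pts[, 2]))
  expect_lt(max(abs(ux + uxm)), 0.02 * max(abs(st$u)))
})

test_that("streamfunction is consistent with the velocity field", {
  cv <- initial_semicircle(32)
  m <- semi_mesh(0.1, 32)
  st0 <- fake_flow(m, function(x, y) cbind(0 * x, 0 * y))
  expect_identical(max(abs(streamfunction(st0, m))), 0)

  # at a steady state the boundary is a streamline, so psi = 0 Dirichlet is
  # consistent and curl(psi) must reconstruct the velocity
  run <- quick_run(-2.5, h = 0.1, t_end = 8)
  m2 <- run$mesh; st <- run$flow
  psi <- streamfunction(st, m2)
  # curl(psi) per triangle vs mean velocity per triangle (both P1-accurate)
  g <- activedrop:::tri_geometry(m2$V, m2$T)
  T <- m2$T
  dpx <- psi[T[, 1]] * g$bx[, 1] + psi[T[, 2]] * g$bx[, 2] + psi[T[, 3]] * g$bx[, 3]
  dpy <- psi[T[, 1]] * g$by[, 1] + psi[T[, 2]] * g$by[, 2] + psi[T[, 3]] * g$by[, 3]
  uc <- (st$u[T[, 1], ] + st$u[T[, 2], ] + st$u[T[, 3], ]) / 3
  err <- sqrt(sum(g$area * ((dpy - uc[, 1])^2 + (-dpx - uc[, 2])^2)))
  nrm <- sqrt(sum(g$area * rowSums(uc^2)))
  expect_lt(err / nrm, 0.2)
})

test_that("vortex census counts and merges streamfunction extrema", {
  m <- semi_mesh(0.05, 64)
  expect_identical(vortex_census(numeric(nrow(m$V)), m)$count, 0L)
  # synthetic cellular field: extrema of opposite sign near (0.5, 0.5)
  # and (1.5, 0.5)
  psi <- sin(pi * m$V[, 1]) * sin(pi * m$V[, 2])
  bnd <- unique(c(m$boundary_edges$v1, m$boundary_edges$v2))
  psi[bnd] <- 0
  vc <- vortex_census(psi, m)
  expect_identical(vc$count, 2L)
  expect_equal(sort(vc$vortices$x), c(0.5, 1.5), tolerance = 0.1)
  expect_lt(prod(vc$vortices$psi), 0)
})
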