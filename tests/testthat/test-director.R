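test_that("anchoring specs reduce winding numbers mod 4", {
  expect_identical(anchoring_spec(4, 5)$w_s, 0L)
  expect_identical(anchoring_spec(0, 7)$w_i, 3L)
  expect_error(anchoring_spec(2, 0), "w_s")
})

test_that("boundary director encodes quarter-turn anchoring", {
  cv <- initial_semicircle(32)
  m <- semi_mesh(0.1, 32)
  bc0 <- boundary_director(m, cv, anchoring_spec(0, 0))
  sub <- setdiff(m$substrate_chain, range(m$substrate_chain))
  i0 <- match(m$substrate_chain, bc0$idx)
  expect_true(all(abs(bc0$p[i0, 1] - 1) < 1e-12 & abs(bc0$p[i0, 2]) < 1e-12))

  bc1 <- boundary_director(m, cv, anchoring_spec(1, 0))
  i1 <- match(m$substrate_chain, bc1$idx)
  expect_true(all(abs(bc1$p[i1, 1]) < 1e-12 & abs(bc1$p[i1, 2] - 1) < 1e-12))

  # w_i = 1 at the apex: tangent (1,0) rotated CCW -> outward normal (0,1)
  bci <- boundary_director(m, cv, anchoring_spec(0, 1))
  apex_vertex <- m$curve_vertex_ids[which.max(cv$nodes[, 2])]
  pa <- bci$p[match(apex_vertex, bci$idx), ]
  expect_lt(abs(pa[1]), 0.06)
  expect_gt(pa[2], 0.99)

  # corner precedence: substrate value wins at the contact vertices
  corner <- m$curve_vertex_ids[1]
  expect_equal(unname(bci$p[match(corner, bci$idx), ]), c(1, 0))
})

test_that("harmonic extension of a constant is that constant", {
  m <- semi_mesh(0.1, 32)
  bnd <- sort(unique(c(m$boundary_edges$v1, m$boundary_edges$v2)))
  bc <- list(idx = bnd, p = cbind(rep(1, length(bnd)), rep(0, length(bnd))))
  d <- solve_director(m, bc)
  expect_lt(max(abs(d$p[, 1] - 1)), 1e-10)
  expect_lt(max(abs(d$p[, 2])), 1e-10)
})

test_that("harmonic solve converges at second order against Re(z^2)", {
  err <- function(h, n) {
    cv <- initial_semicircle(n)
    m <- build_mesh(cv, h)
    bnd <- sort(unique(c(m$boundary_edges$v1, m$boundary_edges$v2)))
    f <- function(x, y) (x - 1)^2 - y^2
    bc <- list(idx = bnd, p = cbind(f(m$V[bnd, 1], m$V[bnd, 2]), 0))
    d <- solve_director(m, bc)
    max(abs(d$p[, 1] - f(m$V[, 1], m$V[, 2])))
  }
  e1 <- err(0.1, 32)
  e2 <- err(0.05, 64)
  expect_lt(e2, 5e-4)
  expect_gt(log2(e1 / e2), 1.7)
})

test_that("maximum principle bounds the director magnitude", {
  cv <- initial_semicircle(32)
  m <- semi_mesh(0.1, 32)
  for (w in list(c(0, 0), c(0, 1), c(0, 2), c(1, 1), c(1, 3))) {
    d <- director_on(m, cv, w[1], w[2])
    expect_lt(max(sqrt(rowSums(d$p^2))), 1 + 1e-9)
    expect_lt(max(abs(d$p)), 1 + 1e-9)
  }
})

test_that("defect census finds the contact-point defects and bulk vortices", {
  cv <- initial_semicircle(64)
  m <- semi_mesh(0.05, 64)
  d <- director_on(m, cv, 0, 0)
  dc <- defect_census(d, m)
  expect_identical(nrow(dc), 2L)
  dcorner <- pmin(sqrt(dc$x^2 + dc$y^2), sqrt((dc$x - 2)^2 + dc$y^2))
  expect_lt(max(dcorner), 2 * m$h_mesh)

  # constant field: no defects
  expect_identical(nrow(defect_census(const_director(m, 1, 0), m)), 0L)

  # synthetic vortex centred at (1, 0.5)
  eps <- 0.15
  r <- sqrt((m$V[, 1] - 1)^2 + (m$V[, 2] - 0.5)^2)
  p <- cbind(m$V[, 1] - 1, m$V[, 2] - 0.5) / pmax(r, eps)
  syn <- structure(list(p = p, normalize = FALSE), class = "director_field")
  dc2 <- defect_census(syn, m, threshold = 0.3)
  expect_identical(nrow(dc2), 1L)
  expect_lt(sqrt((dc2$x - 1)^2 + (dc2$y - 0.5)^2), m$h_mesh)
})

test_that("director solutions are mirror-equivariant (w_i = 1 vs 3)", {
  cv <- initial_semicircle(48)
  m1 <- build_mesh(cv, 0.08)
  d1 <- director_on(m1, cv, 0, 1)
  cvr <- reflect_curve(cv)
  m3 <- build_mesh(cvr, 0.08)
  d3 <- director_on(m3, cvr, 0, 3)
  pts <- cbind(c(0.5, 1.0, 1.5, 0.8), c(0.3, 0.5, 0.2, 0.7))
  pts_m <- cbind(2 - pts[, 1], pts[, 2])
  v1 <- interp_p1(m1, d1$p, pts)
  v3 <- interp_p1(m3, d3$p, pts_m)
  # the mirrored clockwise field is the reflected counterclockwise one up to
  # the nematic head-tail sign: p3(Mx) = -M p1(x) = (p1x, -p1y)
  expect_equal(v3[, 1], v1[, 1], tolerance = 5e-3)
  expect_equal(v3[, 2], -v1[, 2], tolerance = 5e-3)
  # the active stress (quadratic in p) is sign-free, so the flows mirror
  ca <- 2.5
  s1 <- solve_stokes(m1, cv, d1, ca = ca)
  s3 <- solve_stokes(m3, cvr, d3, ca = ca)
  u1 <- interp_p1(m1, s1$u[seq_len(nrow(m1$V)), ], pts)
  u3 <- interp_p1(m3, s3$u[seq_len(nrow(m3$V)), ], pts_m)
  expect_lt(max(abs(u3[, 1] + u1[, 1])), 0.03 * max(abs(u1)))
  expect_lt(max(abs(u3[, 2] - u1[, 2])), 0.03 * max(abs(u1)))
})
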