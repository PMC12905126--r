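test_that("entropy rates match closed-form quadrature on prescribed fields", {
  cv <- initial_semicircle(32)
  m <- semi_mesh(0.1, 32)
  area <- mesh_area(m)

  st0 <- fake_flow(m, function(x, y) cbind(0 * x, 0 * y))
  er0 <- entropy_rates(st0, const_director(m, 1, 0), ca = 2, mesh = m)
  expect_identical(c(er0$s_dot_v, er0$s_dot_a, er0$s_dot_tot), c(0, 0, 0))

  # pure shear u = (y, 0): (grad u + grad u^T):grad u = 1 pointwise,
  # so s_dot_v = area; with p at 45 degrees, (pp):grad u = 1/2
  st <- fake_flow(m, function(x, y) cbind(y, 0 * x))
  p45 <- const_director(m, sqrt(0.5), sqrt(0.5))
  er <- entropy_rates(st, p45, ca = 2, mesh = m)
  expect_equal(er$s_dot_v, area, tolerance = 1e-12)
  expect_equal(er$s_dot_a, -2 * 0.5 * area, tolerance = 1e-12)
  expect_equal(er$s_dot_tot, er$s_dot_v + er$s_dot_a, tolerance = 1e-12)

  # with p along x, (pp):grad u = du_x/dx = 0
  er2 <- entropy_rates(st, const_director(m, 1, 0), ca = 2, mesh = m)
  expect_equal(er2$s_dot_a, 0, tolerance = 1e-14)
})

test_that("viscous dissipation is non-negative for active solves", {
  cv <- initial_semicircle(32)
  m <- semi_mesh(0.1, 32)
  for (ca in c(-2.5, 1, 5)) {
    d <- director_on(m, cv, 0, 1)
    st <- solve_stokes(m, cv, d, ca = ca)
    er <- entropy_rates(st, d, ca = ca, mesh = m)
    expect_gte(er$s_dot_v, 0)
  }
})

test_that("max speed reports the largest nodal speed", {
  m <- semi_mesh(0.1, 32)
  expect_identical(max_speed(fake_flow(m, function(x, y) cbind(0 * x, 0 * y))), 0)
  st <- fake_flow(m, function(x, y) cbind(-y, x))
  # |u| = distance from the origin; the far contact point has r = 2
  expect_equal(max_speed(st), 2, tolerance = 1e-9)
})

test_that("power-law fits recover exponents", {
  x <- c(0.25, 0.5, 1, 2)
  f <- fit_power_law(x, 3 * x^2)
  expect_equal(f$exponent, 2, tolerance = 1e-10)
  expect_equal(f$prefactor, 3, tolerance = 1e-10)
  expect_equal(fit_power_law(x, x)$exponent, 1, tolerance = 1e-12)
  set.seed(42)
  reps <- replicate(20, {
    y <- x^2 * (1 + 0.01 * rnorm(length(x)))
    fit_power_law(x, y)$exponent
  })
  expect_true(all(reps > 1.9 & reps < 2.1))
  expect_error(fit_power_law(x, c(1, -1, 1, 1)), "positive")
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "3")
})

test_that("morphology classification follows the shape taxonomy", {
  expect_identical(classify_morphology(initial_semicircle(64)), "simple-symmetric")

  # synthetic film connecting two lobes
  x <- seq(0, 2, length.out = 101)
  h <- 0.08 + 0.55 * (exp(-((x - 0.35) / 0.22)^2) + exp(-((x - 1.65) / 0.22)^2))
  nodes <- cbind(x, h)
  nodes[1, ] <- c(0, 0); nodes[101, ] <- c(2, 0)
  film <- interface_curve(nodes, check = FALSE)
  expect_identical(classify_morphology(film), "film-two-lobes")

  # skewed drop breaks symmetry
  cv <- initial_semicircle(64)
  sk <- cv$nodes
  sk[, 2] <- sk[, 2] * (1 + 0.3 * sk[, 1] / 2)
  sk[1, ] <- c(0, 0); sk[64, ] <- c(2, 0)
  skew <- interface_curve(sk)
  expect_identical(classify_morphology(skew), "broken-symmetry")

  # overhanging cap wider than the contact line: circular cap of radius 1.2
  # centred above the substrate midpoint
  th <- seq(163, 17, length.out = 60) * pi / 180
  cap <- cbind(1 + 1.2 * cos(th), 0.15 + 1.2 * sin(th))
  mush <- interface_curve(rbind(c(0, 0), cap, c(2, 0)), check = FALSE)
  expect_identical(classify_morphology(mush), "mushroom")

  # x-mirroring maps labels to themselves
  expect_identical(classify_morphology(reflect_curve(film)), "film-two-lobes")
  expect_identical(classify_morphology(reflect_curve(skew)), "broken-symmetry")
})
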