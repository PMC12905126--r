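test_that("initial semicircle is exact and rejects unresolvable node counts", {
  expect_error(initial_semicircle(3), "at least 16")
  cv <- initial_semicircle(64)
  r2 <- (cv$nodes[, 1] - 1)^2 + cv$nodes[, 2]^2
  expect_lt(max(abs(r2 - 1)), 1e-12)
  expect_equal(cv$nodes[1, ], c(0, 0))
  expect_equal(cv$nodes[64, ], c(2, 0))
  expect_lt(abs(enclosed_area(initial_semicircle(256)) - pi / 2), 1e-3)
})

test_that("interface curves enforce their invariants", {
  cv <- initial_semicircle(32)
  bad <- cv$nodes
  bad[10, 2] <- -0.1
  expect_error(interface_curve(bad), "y > 0")
  bad <- cv$nodes
  bad[1, ] <- c(0.1, 0)
  expect_error(interface_curve(bad), "contact nodes")
  # bowtie: swap two interior nodes to force a crossing
  bad <- cv$nodes
  bad[c(14, 18), ] <- bad[c(18, 14), ]
  expect_error(interface_curve(bad), "self-intersects")
})

test_that("frame and curvature match closed forms and conventions", {
  cv <- initial_semicircle(128)
  fr <- frame_and_curvature(cv)
  # unit semicircle: C = +1 (exactly, circumcircle of points on a circle)
  expect_lt(max(abs(fr$C[5:124] - 1)), 1e-10)
  # outward normal at the apex
  apex <- which.max(cv$nodes[, 2])
  expect_gt(fr$n[apex, 2], 0.99)
  # collinear nodes: C = 0 exactly on the flat part
  flat <- rbind(c(0, 0), c(0.2, 0.4), c(0.6, 0.4), c(1.0, 0.4), c(1.4, 0.4),
                c(1.8, 0.4), c(2, 0))
  fr2 <- frame_and_curvature(interface_curve(flat, check = FALSE))
  expect_identical(fr2$C[3:5], c(0, 0, 0))
  expect_error(frame_and_curvature(
    interface_curve(rbind(c(0, 0), c(1, 1), c(1, 1), c(2, 0)), check = FALSE)),
    "duplicate")
})

test_that("curvature matches the closed-form ellipse at second order", {
  ell_err <- function(n) {
    th <- seq(pi, 0, length.out = n)
    nodes <- cbind(1 + 2 * cos(th), sin(th))
    cv <- interface_curve(nodes, check = FALSE)
    fr <- frame_and_curvature(cv)
    # curvature of x = 2cos(th), y = sin(th): 2 / (4 sin^2 + cos^2)^(3/2)
    Cex <- 2 / (4 * sin(th)^2 + cos(th)^2)^1.5
    idx <- which(th > 0.1 * pi & th < 0.9 * pi)
    max(abs(fr$C[idx] - Cex[idx]) / Cex[idx])
  }
  e512 <- ell_err(512)
  expect_lt(e512, 0.01)
  # second-order convergence
  expect_gt(log2(ell_err(128) / ell_err(256)), 1.7)
})

test_that("redistribute equalises spacing and preserves the shape", {
  cv <- initial_semicircle(128)
  expect_lt(max(abs(redistribute(cv)$nodes - cv$nodes)), 1e-10)

  # clustered sampling (spacing ratio > 10) becomes uniform
  th <- pi * (1 - seq(0, 1, length.out = 64)^2)
  nodes <- rbind(c(0, 0), cbind(1 + cos(th[-c(1, 64)]), sin(th[-c(1, 64)])), c(2, 0))
  rr <- redistribute(interface_curve(nodes, check = FALSE))
  d <- sqrt(rowSums(diff(rr$nodes)^2))
  expect_lt(max(d) / min(d), 1.05)

  # perturbed semicircle: polygon area preserved
  cv <- initial_semicircle(512)
  fr <- frame_and_curvature(cv)
  nodes <- cv$nodes + 5e-4 * sin(6 * pi * cv$s / max(cv$s)) * fr$n
  nodes[1, ] <- c(0, 0); nodes[512, ] <- c(2, 0)
  c2 <- interface_curve(nodes)
  expect_lt(abs(enclosed_area(redistribute(c2)) - enclosed_area(c2)), 1e-6)

  # shape change bounded by the corner-cutting estimate
  dmax <- hausdorff_distance(redistribute(c2), c2)
  ds <- max(diff(c2$s))
  expect_lt(dmax, 0.1 * ds^2 * max(abs(frame_and_curvature(c2)$C)) + 1e-12)
})

test_that("mirror asymmetry is zero for symmetric shapes and exact for a step", {
  cv <- initial_semicircle(128)
  expect_lt(mirror_asymmetry(cv), 1e-10)

  # asymmetric by construction
  sk <- cv$nodes
  sk[, 2] <- sk[, 2] * (1 + 0.3 * sk[, 1] / 2)
  sk[1, ] <- c(0, 0); sk[128, ] <- c(2, 0)
  cs <- interface_curve(sk)
  expect_gt(mirror_asymmetry(cs), 0.01)
  # reflection invariance (exact)
  expect_identical(mirror_asymmetry(cs), mirror_asymmetry(reflect_curve(cs)))

  # piecewise-constant height profile: h = 0.5 on the left half, 0.25 on the
  # right; |A sym-diff A_mirrored| / |A| = 0.5 / 0.75 = 2/3
  mk <- rbind(c(0, 0), c(0.02, 0.5), c(0.98, 0.5), c(1.02, 0.25),
              c(1.98, 0.25), c(2, 0))
  expect_equal(mirror_asymmetry(interface_curve(mk, check = FALSE)), 2 / 3,
               tolerance = 0.02)
})
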