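#' Entropy production rates of a flow state
#'
#' The total entropy production rate (in rho*T-scaled dimensionless form) is
#' the stress power integrated over the drop; the pressure contribution
#' vanishes by incompressibility, leaving the viscous dissipation
#' `s_dot_v = int (grad u + grad u^T) : grad u dA >= 0` and the active work
#' `s_dot_a = -Ca int (pp) : grad u dA` (with `Q` in place of `pp` for the
#' tensor model). Quadrature is exact for the discrete polynomial degrees.
#'
#' @param state a `flow_state`.
#' @param nematic the `director_field` or `q_field` used in the solve.
#' @param ca the active Capillary number used in the solve.
#' @param mesh the `drop_mesh`.
#' @return list with `s_dot_v`, `s_dot_a`, `s_dot_tot`.
#' @export
entropy_rates <- function(state, nematic, ca, mesh) {
  g <- tri_geometry(mesh$V, mesh$T)
  quad <- tri_quadrature()
  T2 <- state$p2$T2
  ux <- state$u[, 1L]; uy <- state$u[, 2L]
  A <- active_tensor(nematic)
  sv <- sa <- 0
  for (q in seq_along(quad$w)) {
    gq <- p2_gradients(g, quad$lambda[q, ])
    G11 <- G12 <- G21 <- G22 <- 0
    for (b in 1:6) {
      G11 <- G11 + gq$GX[, b] * ux[T2[, b]]
      G12 <- G12 + gq$GY[, b] * ux[T2[, b]]
      G21 <- G21 + gq$GX[, b] * uy[T2[, b]]
      G22 <- G22 + gq$GY[, b] * uy[T2[, b]]
    }
    lq <- quad$lambda[q, ]
    a11 <- lq[1L] * A[mesh$T[, 1L], 1L] + lq[2L] * A[mesh$T[, 2L], 1L] + lq[3L] * A[mesh$T[, 3L], 1L]
    a12 <- lq[1L] * A[mesh$T[, 1L], 2L] + lq[2L] * A[mesh$T[, 2L], 2L] + lq[3L] * A[mesh$T[, 3L], 2L]
    a22 <- lq[1L] * A[mesh$T[, 1L], 3L] + lq[2L] * A[mesh$T[, 2L], 3L] + lq[3L] * A[mesh$T[, 3L], 3L]
    wA <- quad$w[q] * g$area
    sv <- sv + sum(wA * (2 * G11^2 + 2 * G22^2 + (G12 + G21)^2))
    sa <- sa - ca * sum(wA * (a11 * G11 + a12 * (G12 + G21) + a22 * G22))
  }
  list(s_dot_v = sv, s_dot_a = sa, s_dot_tot = sv + sa)
}

#' Maximum flow speed
#' @param state a `flow_state`.
#' @return `max |u|` over the velocity nodes.
#' @export
max_speed <- function(state) {
  if (nrow(state$u) == 0L) return(0)
  max(sqrt(rowSums(state$u^2)))
}

#' Fit a power law y = prefactor * x^exponent
#'
#' Least-squares fit of `log y` against `log x`, used for the scaling laws
#' of maximum speed and entropy production against `|Ca|`.
#'
#' @param x,y positive numeric vectors (>= 3 points).
#' @return list with `exponent` and `prefactor`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y)) {
    stop("need at least 3 (x, y) pairs")
  }
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit requires positive data")
  fit <- stats::lm(log(y) ~ log(x))
  list(exponent = unname(stats::coef(fit)[2L]),
       prefactor = exp(unname(stats::coef(fit)[1L])))
}

#' Classify the steady-state drop morphology
#'
#' Labels, checked in order:
#' `film-two-lobes` if the interface height over `x in [0.8, 1.2]` dips below
#' `film_ratio` times the maximum height and the height profile has at least
#' two local maxima; `broken-symmetry` if [mirror_asymmetry()] exceeds
#' `asym_threshold`; `mushroom` if the maximum drop width above half the apex
#' height exceeds the contact-line width 2 by more than `width_excess`;
#' otherwise `simple-symmetric`. The thresholds mirror how the shapes are
#' recognised by eye but make the state diagram machine-reproducible.
#'
#' @param curve an `interface_curve`.
#' @param film_ratio,asym_threshold,width_excess classifier thresholds.
#' @return a single character label.
#' @export
classify_morphology <- function(curve, film_ratio = 0.25,
                                asym_threshold = 0.01, width_excess = 0.05) {
  prof <- height_profile(curve, n = 201L)
  hmax <- max(prof$h)
  mid <- prof$x >= 0.8 & prof$x <= 1.2
  n_max <- count_local_maxima(prof$h)
  if (min(prof$h[mid]) < film_ratio * hmax && n_max >= 2L) {
    return("film-two-lobes")
  }
  if (mirror_asymmetry(curve) > asym_threshold) {
    return("broken-symmetry")
  }
  if (max_width_above(curve, 0.5 * hmax) > 2 * (1 + width_excess)) {
    return("mushroom")
  }
  "simple-symmetric"
}

count_local_maxima <- function(h, tol = 1e-9) {
  n <- length(h)
  if (n < 3L) return(as.integer(n > 0L))
  d <- diff(h)
  sgn <- sign(d)[abs(d) > tol]
  if (length(sgn) == 0L) return(1L)
  # a maximum is a rise followed (after any plateau) by a fall
  sum(sgn[-length(sgn)] > 0 & sgn[-1L] < 0)
}

# widest horizontal cross-section of the drop polygon at heights >= y0
max_width_above <- function(curve, y0) {
  p <- curve$nodes
  ys <- seq(y0, max(p[, 2L]) * 0.999, length.out = 64L)
  w <- vapply(ys, function(y) {
    n1 <- nrow(p)
    jj <- c(2:n1, 1L)
    y1 <- p[, 2L]; y2 <- p[jj, 2L]
    hit <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(hit)) return(0)
    tt <- (y - y1[hit]) / (y2[hit] - y1[hit])
    xs <- p[hit, 1L] + tt * (p[jj, 1L][hit] - p[hit, 1L])
    diff(range(xs))
  }, 0)
  max(w)
}
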