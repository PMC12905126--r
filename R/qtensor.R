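#' Q-tensor from a director and scalar order parameter
#'
#' `Q = S (pp - I/2)`: symmetric, traceless, and invariant under the nematic
#' head-tail flip `p -> -p`. Stored as the independent components
#' `(Q_xx, Q_xy)`; `Q_yy = -Q_xx`.
#'
#' @param p unit 2-vector (or n x 2 matrix of unit rows).
#' @param S scalar order parameter (>= 0), recycled over rows.
#' @return matrix with columns `Qxx`, `Qxy`.
#' @export
q_from_director <- function(p, S = 1) {
  p <- if (is.matrix(p)) p else matrix(p, 1L, 2L)
  if (any(abs(sqrt(rowSums(p^2)) - 1) > 1e-9)) {
    stop("`p` must be a unit vector")
  }
  if (any(S < 0)) stop("`S` must be non-negative")
  cbind(Qxx = S * (p[, 1L]^2 - 0.5), Qxy = S * p[, 1L] * p[, 2L])
}

#' Anchoring boundary data for the Q-tensor model
#'
#' Same winding-number geometry as [boundary_director()], but mapped through
#' `Q = S_max (pp - I/2)`, which makes configurations whose boundary
#' directors differ by `pi` identical: the Q model sees true nematic
#' anchoring, not boundary polarization.
#'
#' @inheritParams boundary_director
#' @param S_max boundary scalar order (strong anchoring at the Landau
#'   maximum `sqrt(2a/b)` by default; pass the value consistent with the
#'   `a`, `b` used in [solve_qtensor()]).
#' @return list with `idx` and matrix `Q` (columns Qxx, Qxy).
#' @export
boundary_qtensor <- function(mesh, curve, anchoring, S_max = 1) {
  bc <- boundary_director(mesh, curve, anchoring)
  list(idx = bc$idx, Q = q_from_director(bc$p / sqrt(rowSums(bc$p^2)), S_max))
}

#' Stationary Landau-de Gennes Q-tensor field
#'
#' Solves `0 = [a - b tr(Q^2)] Q + K_Q lap Q` componentwise with Dirichlet
#' anchoring data, by damped Newton iteration initialised from the harmonic
#' extension of the boundary values, falling back to pseudo-time gradient
#' flow if Newton stagnates. The scalar order `S = sqrt(2 tr(Q^2))` is
#' bounded by `S_max = sqrt(2a/b)` up to solver tolerance.
#'
#' @param mesh a `drop_mesh`.
#' @param bc boundary values from [boundary_qtensor()].
#' @param a,b Landau coefficients (> 0); `a` sets the condensation strength,
#'   `b` the quartic saturation.
#' @param K_Q elastic constant (length^2 scale; the nematic coherence length
#'   is `sqrt(K_Q / a)`).
#' @param tol nonlinear residual tolerance (RMS).
#' @param max_iter Newton iteration cap.
#' @return a `q_field` with vertex vectors `Qxx`, `Qxy` and parameters.
#' @export
solve_qtensor <- function(mesh, bc, a = 1, b = 2, K_Q = 2.5e-3,
                          tol = 1e-8, max_iter = 50L) {
  if (a <= 0 || b <= 0 || K_Q <= 0) stop("`a`, `b`, `K_Q` must be positive")
  nv <- nrow(mesh$V)
  K <- p1_stiffness(mesh$V, mesh$T)
  mass <- p1_lumped_mass(mesh$V, mesh$T)
  bnd <- sort(unique(c(mesh$boundary_edges$v1, mesh$boundary_edges$v2)))
  ord <- match(bnd, bc$idx)
  if (anyNA(ord)) stop("boundary data must cover all boundary vertices")
  qb <- bc$Q[ord, , drop = FALSE]
  free <- setdiff(seq_len(nv), bnd)

  # initial guess: harmonic extension of the boundary data
  qxx <- p1_dirichlet_solve(K, bnd, qb[, 1L])
  qxy <- p1_dirichlet_solve(K, bnd, qb[, 2L])

  # semi-implicit pseudo-time gradient flow: diffusion implicit (single
  # factorisation), Landau bulk term explicit. Used to bring the iterate
  # into Newton's basin and as the fallback on Newton stagnation.
  nfree <- length(free)
  dt_flow <- 0.25 / a
  Aimp <- Matrix::Diagonal(nfree, mass[free] / dt_flow) +
    K_Q * K[free, free, drop = FALSE]
  Afac <- Matrix::Cholesky(Matrix::forceSymmetric(Aimp))
  Kfb <- K[free, bnd, drop = FALSE]
  imex_steps <- function(qxx, qxy, n_steps, stop_at) {
    for (k in seq_len(n_steps)) {
      tr2 <- 2 * (qxx^2 + qxy^2)
      bulk <- (a - b * tr2)
      rhsx <- mass[free] * (qxx[free] / dt_flow + bulk[free] * qxx[free]) -
        as.vector(Kfb %*% qb[, 1L]) * K_Q
      rhsy <- mass[free] * (qxy[free] / dt_flow + bulk[free] * qxy[free]) -
        as.vector(Kfb %*% qb[, 2L]) * K_Q
      qxx[free] <- as.vector(Matrix::solve(Afac, rhsx))
      qxy[free] <- as.vector(Matrix::solve(Afac, rhsy))
      if (k %% 25L == 0L) {
        r <- residual(qxx, qxy)
        if (res_norm(r) < stop_at) break
      }
    }
    list(qxx = qxx, qxy = qxy)
  }

  residual <- function(qxx, qxy) {
    tr2 <- 2 * (qxx^2 + qxy^2)
    rx <- mass * (a - b * tr2) * qxx - K_Q * as.vector(K %*% qxx)
    ry <- mass * (a - b * tr2) * qxy - K_Q * as.vector(K %*% qxy)
    list(rx = rx, ry = ry)
  }
  res_norm <- function(r) {
    # strong-form RMS residual (weak residual scaled by the lumped mass)
    sqrt(mean(c(r$rx[free] / mass[free], r$ry[free] / mass[free])^2))
  }

  nf <- length(free)
  hist <- numeric(0)
  # pre-relax toward the Landau manifold before Newton
  st <- imex_steps(qxx, qxy, 200L, stop_at = max(tol, 1e-3))
  qxx <- st$qxx; qxy <- st$qxy
  r <- residual(qxx, qxy)
  rn <- res_norm(r)
  it <- 0L
  while (rn > tol && it < max_iter) {
    it <- it + 1L
    # Newton on the free vertices; bulk term uses the lumped mass, so its
    # Jacobian is block-diagonal per vertex
    tr2 <- 2 * (qxx^2 + qxy^2)
    dxx <- mass * ((a - b * tr2) - 4 * b * qxx^2)
    dyy <- mass * ((a - b * tr2) - 4 * b * qxy^2)
    dxy <- mass * (-4 * b * qxx * qxy)
    Kff <- K_Q * K[free, free, drop = FALSE]
    J <- rbind(
      cbind(Matrix::Diagonal(nf, dxx[free]) - Kff, Matrix::Diagonal(nf, dxy[free])),
      cbind(Matrix::Diagonal(nf, dxy[free]), Matrix::Diagonal(nf, dyy[free]) - Kff))
    step <- as.vector(Matrix::solve(J, -c(r$rx[free], r$ry[free])))
    lam <- 1
    repeat {
      qxx2 <- qxx; qxy2 <- qxy
      qxx2[free] <- qxx[free] + lam * step[seq_len(nf)]
      qxy2[free] <- qxy[free] + lam * step[nf + seq_len(nf)]
      r2 <- residual(qxx2, qxy2)
      if (res_norm(r2) < rn || lam < 1 / 64) break
      lam <- lam / 2
    }
    if (res_norm(r2) >= rn) {
      # Newton stagnated: fall back to the semi-implicit gradient flow
      st <- imex_steps(qxx, qxy, 4000L, stop_at = tol)
      qxx <- st$qxx; qxy <- st$qxy
      r <- residual(qxx, qxy)
      rn <- res_norm(r)
      if (rn > tol) {
        stop(sprintf(
          "Q-tensor solver stagnated; residual history: %s",
          paste(signif(c(hist, rn), 3), collapse = " -> ")))
      }
      break
    }
    qxx <- qxx2; qxy <- qxy2; r <- r2; rn <- res_norm(r2)
    hist <- c(hist, rn)
  }
  if (rn > tol) {
    stop(sprintf("Q-tensor Newton did not converge; residual history: %s",
                 paste(signif(hist, 3), collapse = " -> ")))
  }
  structure(list(Qxx = qxx, Qxy = qxy, a = a, b = b, K_Q = K_Q,
                 S_max = sqrt(2 * a / b)),
            class = "q_field")
}

#' @exportS3Method base::print
print.q_field <- function(x, ...) {
  S <- sqrt(2 * (2 * (x$Qxx^2 + x$Qxy^2)))
  cat(sprintf("<q_field: %d vertices, S in [%.3f, %.3f], S_max = %.3f>\n",
              length(x$Qxx), min(S), max(S), x$S_max))
  invisible(x)
}

#' Scalar order parameter of a Q-tensor field
#' @param field a `q_field`.
#' @return vertex vector `S = sqrt(2 tr(Q^2))`.
#' @export
scalar_order <- function(field) {
  sqrt(2 * (2 * (field$Qxx^2 + field$Qxy^2)))
}
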