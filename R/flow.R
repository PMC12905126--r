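#' Instantaneous Stokes flow driven by active stress and capillary traction
#'
#' Solves the incompressible Stokes problem on the current drop domain with
#' the mixed Taylor-Hood pair (quadratic velocity, linear pressure): find
#' `(u, P)` with
#' `div([grad u + grad u^T] - P I) = div(Ca * pp)` in the drop,
#' `u = 0` on the substrate (no-slip, including the contact vertices), and
#' the capillary traction `sigma . n = -C n` on the interface (dimensionless
#' units: lengths in R, velocities in gamma/mu, pressure in gamma/R). The
#' active stress `-Ca * pp` (or `-Ca * Q`) is moved to the right-hand side in
#' the weak form; the traction term fixes the pressure level, so the system
#' has no nullspace.
#'
#' @param mesh a `drop_mesh`.
#' @param curve the `interface_curve` the mesh tracks (provides curvature).
#' @param nematic a `director_field` or `q_field` on the mesh vertices.
#' @param ca active Capillary number; positive = extensile, negative =
#'   contractile.
#' @param traction `"curvature"` assembles the capillary traction from the
#'   discrete nodal curvature; `"laplace_beltrami"` uses the integrated-by-
#'   parts tangential form (useful for stiff fine-mesh runs).
#' @param body_force optional `function(x, y)` returning an n x 2 matrix of
#'   body-force densities (verification hook: method of manufactured
#'   solutions).
#' @param interface_traction optional `function(x, y, nx, ny)` returning an
#'   n x 2 traction that replaces the capillary `-C n` on the interface
#'   (verification hook).
#' @param substrate_velocity optional `function(x, y)` returning an n x 2
#'   Dirichlet velocity on the substrate instead of no-slip (verification
#'   hook).
#' @param contact optional no-penetration contact constraint where the
#'   interface rests on the pinned-corner exclusion wedge: a list with
#'   `nodes` (interface chain positions, indices into the chain) and
#'   `normal` (2-column matrix of wedge-edge normals per chain position).
#'   Penalised weakly: `u . n = 0` on edges whose endpoints are both in
#'   contact, leaving tangential slip free.
#' @return a `flow_state`: velocity `u` (P2 nodes x 2), vertex pressure
#'   `pressure`, plus the P2 connectivity used.
#' @export
solve_stokes <- function(mesh, curve, nematic, ca,
                         traction = c("curvature", "laplace_beltrami"),
                         body_force = NULL, interface_traction = NULL,
                         substrate_velocity = NULL, contact = NULL) {
  traction <- match.arg(traction)
  if (!is.finite(ca)) stop("`ca` must be finite")
  p2 <- p2_connectivity(mesh)
  n2 <- p2$n_nodes; nv <- p2$nv
  g <- tri_geometry(mesh$V, mesh$T)
  if (any(g$area <= 0)) stop(sprintf(
    "degenerate mesh: %d non-positive triangle areas, min angle %.2f deg",
    sum(g$area <= 0), mesh_min_angle(mesh$V, mesh$T)))
  quad <- tri_quadrature()
  T2 <- p2$T2
  m <- nrow(T2)
  A <- active_tensor(nematic)

  # quadrature-point data
  nq <- length(quad$w)
  G <- lapply(seq_len(nq), function(q) p2_gradients(g, quad$lambda[q, ]))
  lam <- quad$lambda
  # active tensor at quadrature points (P1 interpolation)
  a11q <- a12q <- a22q <- vector("list", nq)
  for (q in seq_len(nq)) {
    a11q[[q]] <- lam[q, 1L] * A[mesh$T[, 1L], 1L] + lam[q, 2L] * A[mesh$T[, 2L], 1L] + lam[q, 3L] * A[mesh$T[, 3L], 1L]
    a12q[[q]] <- lam[q, 1L] * A[mesh$T[, 1L], 2L] + lam[q, 2L] * A[mesh$T[, 2L], 2L] + lam[q, 3L] * A[mesh$T[, 3L], 2L]
    a22q[[q]] <- lam[q, 1L] * A[mesh$T[, 1L], 3L] + lam[q, 2L] * A[mesh$T[, 2L], 3L] + lam[q, 3L] * A[mesh$T[, 3L], 3L]
  }

  # ----- viscous block and pressure coupling --------------------------------
  ii_l <- list(); jj_l <- list(); xx_l <- list(); k <- 0L
  wA <- lapply(seq_len(nq), function(q) quad$w[q] * g$area)
  for (a in 1:6) for (b in 1:6) {
    Kg <- Txx <- Txy <- Tyx <- Tyy <- numeric(m)
    for (q in seq_len(nq)) {
      gq <- G[[q]]
      Kg <- Kg + wA[[q]] * (gq$GX[, a] * gq$GX[, b] + gq$GY[, a] * gq$GY[, b])
      Txx <- Txx + wA[[q]] * gq$GX[, b] * gq$GX[, a]
      Txy <- Txy + wA[[q]] * gq$GX[, b] * gq$GY[, a]
      Tyx <- Tyx + wA[[q]] * gq$GY[, b] * gq$GX[, a]
      Tyy <- Tyy + wA[[q]] * gq$GY[, b] * gq$GY[, a]
    }
    ia <- T2[, a]; jb <- T2[, b]
    # A[(a,i),(b,j)] = int [ delta_ij grad(phi_a).grad(phi_b) + d_i phi_b d_j phi_a ]
    k <- k + 1L; ii_l[[k]] <- ia; jj_l[[k]] <- jb; xx_l[[k]] <- Kg + Txx          # xx
    k <- k + 1L; ii_l[[k]] <- ia; jj_l[[k]] <- jb + n2; xx_l[[k]] <- Txy          # test x, trial y
    k <- k + 1L; ii_l[[k]] <- ia + n2; jj_l[[k]] <- jb; xx_l[[k]] <- Tyx          # test y, trial x
    k <- k + 1L; ii_l[[k]] <- ia + n2; jj_l[[k]] <- jb + n2; xx_l[[k]] <- Kg + Tyy
  }
  # pressure blocks: D[c, (a,i)] = int lambda_c d_i phi_a
  off_p <- 2L * n2
  for (a in 1:6) for (cc in 1:3) {
    Dx <- Dy <- numeric(m)
    for (q in seq_len(nq)) {
      gq <- G[[q]]
      Dx <- Dx + wA[[q]] * lam[q, cc] * gq$GX[, a]
      Dy <- Dy + wA[[q]] * lam[q, cc] * gq$GY[, a]
    }
    ic <- mesh$T[, cc]; ja <- T2[, a]
    # momentum rows: -D^T p
    k <- k + 1L; ii_l[[k]] <- ja; jj_l[[k]] <- ic + off_p; xx_l[[k]] <- -Dx
    k <- k + 1L; ii_l[[k]] <- ja + n2; jj_l[[k]] <- ic + off_p; xx_l[[k]] <- -Dy
    # continuity rows: -D u (symmetric saddle)
    k <- k + 1L; ii_l[[k]] <- ic + off_p; jj_l[[k]] <- ja; xx_l[[k]] <- -Dx
    k <- k + 1L; ii_l[[k]] <- ic + off_p; jj_l[[k]] <- ja + n2; xx_l[[k]] <- -Dy
  }
  ndof <- 2L * n2 + nv
  # no-penetration penalty on wedge-contact interface edges (slip allowed)
  if (!is.null(contact) && length(contact$nodes) > 1L) {
    ifc <- mesh$interface_chain
    in_ct <- logical(length(ifc))
    in_ct[contact$nodes] <- TRUE
    je <- which(in_ct[-length(ifc)] & in_ct[-1L])  # chain edge index
    if (length(je) > 0L) {
      kappa <- 1e7
      a <- ifc[je]; b <- ifc[je + 1L]
      ekey <- function(p, q) pmin(p, q) * (nv + 1) + pmax(p, q)
      mid <- nv + match(ekey(a, b), ekey(p2$edges[, 1L], p2$edges[, 2L]))
      Le <- sqrt(rowSums((mesh$V[b, , drop = FALSE] - mesh$V[a, , drop = FALSE])^2))
      nrm <- (contact$normal[je, , drop = FALSE] +
                contact$normal[je + 1L, , drop = FALSE]) / 2
      nrm <- nrm / sqrt(rowSums(nrm^2))
      addp <- function(nodes, w) {
        nx <- nrm[, 1L]; ny <- nrm[, 2L]
        for (blk in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
          k <<- k + 1L
          ii_l[[k]] <<- nodes + blk[1L] * n2
          jj_l[[k]] <<- nodes + blk[2L] * n2
          comp <- (if (blk[1L] == 0L) nx else ny) * (if (blk[2L] == 0L) nx else ny)
          xx_l[[k]] <<- kappa * w * comp
        }
      }
      addp(a, Le / 6)
      addp(b, Le / 6)
      addp(mid, 4 * Le / 6)
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii_l), j = unlist(jj_l), x = unlist(xx_l),
                            dims = c(ndof, ndof))

  # ----- right-hand side -----------------------------------------------------
  rhs <- numeric(ndof)
  # active stress: Ca * int (pp)_{il} d_l phi_a  -> component i of node a
  for (a in 1:6) {
    fx <- fy <- numeric(m)
    for (q in seq_len(nq)) {
      gq <- G[[q]]
      fx <- fx + wA[[q]] * (a11q[[q]] * gq$GX[, a] + a12q[[q]] * gq$GY[, a])
      fy <- fy + wA[[q]] * (a12q[[q]] * gq$GX[, a] + a22q[[q]] * gq$GY[, a])
    }
    rhs <- rhs + ca * (accumulate_at(T2[, a], fx, ndof) +
                         accumulate_at(T2[, a] + n2, fy, ndof))
  }
  # body force (verification hook): int f . v
  if (!is.null(body_force)) {
    for (q in seq_len(nq)) {
      xq <- lam[q, 1L] * mesh$V[mesh$T[, 1L], 1L] + lam[q, 2L] * mesh$V[mesh$T[, 2L], 1L] + lam[q, 3L] * mesh$V[mesh$T[, 3L], 1L]
      yq <- lam[q, 1L] * mesh$V[mesh$T[, 1L], 2L] + lam[q, 2L] * mesh$V[mesh$T[, 2L], 2L] + lam[q, 3L] * mesh$V[mesh$T[, 3L], 2L]
      fq <- body_force(xq, yq)
      Nq <- p2_values(lam[q, ])
      for (a in 1:6) {
        rhs <- rhs + accumulate_at(T2[, a], wA[[q]] * Nq[a] * fq[, 1L], ndof) +
          accumulate_at(T2[, a] + n2, wA[[q]] * Nq[a] * fq[, 2L], ndof)
      }
    }
  }
  # traction on interface edges (capillary, or prescribed for verification)
  tr <- traction_load(mesh, curve, p2, method = traction,
                      override = interface_traction)
  rhs[seq_len(n2)] <- rhs[seq_len(n2)] + tr$fx
  rhs[n2 + seq_len(n2)] <- rhs[n2 + seq_len(n2)] + tr$fy

  # ----- substrate Dirichlet condition on P2 nodes --------------------------
  sub_v <- mesh$substrate_chain
  sub_set <- logical(nv)
  sub_set[sub_v] <- TRUE
  sub_mid <- which(sub_set[p2$edges[, 1L]] & sub_set[p2$edges[, 2L]] &
                     abs(p2$X[nv + seq_len(nrow(p2$edges)), 2L]) < 1e-13) + nv
  dir_nodes <- c(sub_v, sub_mid)
  dir_dofs <- c(dir_nodes, dir_nodes + n2)
  free <- setdiff(seq_len(ndof), dir_dofs)
  sol <- numeric(ndof)
  if (!is.null(substrate_velocity)) {
    ud <- substrate_velocity(p2$X[dir_nodes, 1L], p2$X[dir_nodes, 2L])
    sol[dir_dofs] <- c(ud[, 1L], ud[, 2L])
    rhs_f <- rhs[free] - as.vector(K[free, dir_dofs, drop = FALSE] %*% sol[dir_dofs])
    sol[free] <- as.vector(Matrix::solve(K[free, free, drop = FALSE], rhs_f))
  } else {
    sol[free] <- as.vector(Matrix::solve(K[free, free, drop = FALSE], rhs[free]))
  }

  structure(list(
    u = cbind(sol[seq_len(n2)], sol[n2 + seq_len(n2)]),
    pressure = sol[off_p + seq_len(nv)],
    p2 = p2, ca = ca),
    class = "flow_state")
}

#' @exportS3Method base::print
print.flow_state <- function(x, ...) {
  sp <- sqrt(rowSums(x$u^2))
  cat(sprintf("<flow_state: %d velocity nodes, |u|_max %.4g, pressure in [%.3g, %.3g]>\n",
              nrow(x$u), max(sp), min(x$pressure), max(x$pressure)))
  invisible(x)
}

# Assemble the capillary traction -C n on the interface edges into nodal
# loads on the P2 velocity space.
traction_load <- function(mesh, curve, p2, method = "curvature",
                          override = NULL) {
  nv <- p2$nv
  n2 <- p2$n_nodes
  fx <- fy <- numeric(n2)
  fr <- frame_and_curvature(curve)
  seg <- mesh$iface_seg; frac <- mesh$iface_frac
  Cv <- fr$C[seg] * (1 - frac) + fr$C[pmin(seg + 1L, nrow(fr$t))] * frac
  ifc <- mesh$interface_chain
  Cmap <- numeric(nv); Cmap[ifc] <- Cv
  edges <- p2$edges
  edge_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  ekeys <- edge_key(edges[, 1L], edges[, 2L])
  a <- ifc[-length(ifc)]; b <- ifc[-1L]
  mid <- nv + match(edge_key(a, b), ekeys)
  ax <- mesh$V[a, 1L]; ay <- mesh$V[a, 2L]
  bx <- mesh$V[b, 1L]; by <- mesh$V[b, 2L]
  L <- sqrt((bx - ax)^2 + (by - ay)^2)
  tx <- (bx - ax) / L; ty <- (by - ay) / L
  nx <- -ty; ny <- tx                      # outward (tangent rotated +pi/2)
  if (!is.null(override)) {
    mx <- (ax + bx) / 2; my <- (ay + by) / 2
    ta <- override(ax, ay, nx, ny)
    tb <- override(bx, by, nx, ny)
    tm <- override(mx, my, nx, ny)
    fx <- fx + accumulate_at(a, (L / 6) * ta[, 1L], n2) +
      accumulate_at(b, (L / 6) * tb[, 1L], n2) +
      accumulate_at(mid, (4 * L / 6) * tm[, 1L], n2)
    fy <- fy + accumulate_at(a, (L / 6) * ta[, 2L], n2) +
      accumulate_at(b, (L / 6) * tb[, 2L], n2) +
      accumulate_at(mid, (4 * L / 6) * tm[, 2L], n2)
    return(list(fx = fx, fy = fy))
  }
  if (method == "curvature") {
    Ca_ <- Cmap[a]; Cb_ <- Cmap[b]; Cm_ <- (Ca_ + Cb_) / 2
    # Simpson along each straight edge, P2 trace basis
    fx <- fx + accumulate_at(a, -(L / 6) * Ca_ * nx, n2) +
      accumulate_at(b, -(L / 6) * Cb_ * nx, n2) +
      accumulate_at(mid, -(4 * L / 6) * Cm_ * nx, n2)
    fy <- fy + accumulate_at(a, -(L / 6) * Ca_ * ny, n2) +
      accumulate_at(b, -(L / 6) * Cb_ * ny, n2) +
      accumulate_at(mid, -(4 * L / 6) * Cm_ * ny, n2)
  } else {
    # Laplace-Beltrami form: -int t . d_s(v) ds per component; on straight
    # edges d_s of the P2 trace basis integrates to (-1, 1, 0)/... exactly:
    # int d_s N ds over the edge = N(end) - N(start) = (-1, +1, 0)
    fx <- fx + accumulate_at(a, tx, n2) + accumulate_at(b, -tx, n2)
    fy <- fy + accumulate_at(a, ty, n2) + accumulate_at(b, -ty, n2)
  }
  list(fx = fx, fy = fy)
}

#' Streamfunction of a flow state
#'
#' Solves `-lap psi = omega` (vorticity `omega = dx u_y - dy u_x`) with
#' `psi = 0` on the whole boundary. Intended for steady states, where the
#' boundary is a streamline.
#'
#' @param state a `flow_state`.
#' @param mesh the `drop_mesh` it was computed on.
#' @return numeric vector of vertex streamfunction values.
#' @export
streamfunction <- function(state, mesh) {
  g <- tri_geometry(mesh$V, mesh$T)
  quad <- tri_quadrature()
  p2 <- state$p2
  T2 <- p2$T2
  ux <- state$u[, 1L]; uy <- state$u[, 2L]
  nv <- nrow(mesh$V)
  rhs <- numeric(nv)
  for (q in seq_along(quad$w)) {
    gq <- p2_gradients(g, quad$lambda[q, ])
    dxuy <- dyux <- numeric(nrow(T2))
    for (b in 1:6) {
      dxuy <- dxuy + gq$GX[, b] * uy[T2[, b]]
      dyux <- dyux + gq$GY[, b] * ux[T2[, b]]
    }
    om <- dxuy - dyux
    wq <- quad$w[q] * g$area
    for (cc in 1:3) {
      rhs <- rhs + accumulate_at(mesh$T[, cc], wq * quad$lambda[q, cc] * om, nv)
    }
  }
  K <- p1_stiffness(mesh$V, mesh$T)
  bnd <- sort(unique(c(mesh$boundary_edges$v1, mesh$boundary_edges$v2)))
  p1_dirichlet_solve(K, bnd, numeric(length(bnd)), rhs = rhs)
}

#' Count and locate vortices from the streamfunction
#'
#' Interior local extrema of `psi` with `|psi| >= rel_threshold * max|psi|`;
#' extrema closer than `2 * h_mesh` merge to the strongest. The sign of the
#' extremum gives the rotation sense; adjacent extrema of opposite sign form
#' a counter-rotating pair.
#'
#' @param psi vertex streamfunction from [streamfunction()].
#' @param mesh the `drop_mesh`.
#' @param rel_threshold amplitude cut relative to `max|psi|`.
#' @return list with `count` and data.frame `vortices` (x, y, psi).
#' @export
vortex_census <- function(psi, mesh, rel_threshold = 0.05) {
  mx <- max(abs(psi))
  if (mx == 0) {
    return(list(count = 0L, vortices = data.frame(x = numeric(0), y = numeric(0),
                                                  psi = numeric(0))))
  }
  lo <- local_minima_vertices(mesh, psi, interior_only = TRUE)
  hi <- local_minima_vertices(mesh, -psi, interior_only = TRUE)
  cand <- unique(c(lo, hi))
  cand <- cand[abs(psi[cand]) >= rel_threshold * mx]
  if (length(cand) == 0L) {
    return(list(count = 0L, vortices = data.frame(x = numeric(0), y = numeric(0),
                                                  psi = numeric(0))))
  }
  merged <- merge_extrema(mesh$V[cand, , drop = FALSE], -abs(psi[cand]),
                          radius = 2 * mesh$h_mesh, deepest = TRUE)
  # recover signed psi at merged locations
  sel <- match(paste(merged$xy[, 1L], merged$xy[, 2L]),
               paste(mesh$V[cand, 1L], mesh$V[cand, 2L]))
  v <- data.frame(x = merged$xy[, 1L], y = merged$xy[, 2L], psi = psi[cand[sel]])
  v <- v[order(v$x, v$y), , drop = FALSE]
  list(count = nrow(v), vortices = v)
}

# Normal interface speed projected onto the curve nodes.
# The P2 flux u.n along each interface edge (endpoints + midside node,
# Simpson-exact) is L2-projected onto the piecewise-linear hat basis of the
# curve nodes. Because the hats partition unity, the implied polygon area
# rate sums to the discrete flux through the interface, which vanishes by
# incompressibility -- so normal motion with these speeds conserves area to
# geometric truncation error only.
interface_normal_speed <- function(mesh, state, curve) {
  p2 <- state$p2
  nv <- p2$nv
  ifc <- mesh$interface_chain
  # arclength of each chain vertex along the curve polyline
  ds_seg <- diff(curve$s)
  s_chain <- curve$s[mesh$iface_seg] + mesh$iface_frac * ds_seg[mesh$iface_seg]
  edges <- p2$edges
  ekey <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  a <- ifc[-length(ifc)]; b <- ifc[-1L]
  mid <- nv + match(ekey(a, b), ekey(edges[, 1L], edges[, 2L]))
  ax <- mesh$V[a, 1L]; ay <- mesh$V[a, 2L]
  bx <- mesh$V[b, 1L]; by <- mesh$V[b, 2L]
  L <- sqrt((bx - ax)^2 + (by - ay)^2)
  nx <- -(by - ay) / L; ny <- (bx - ax) / L
  fa <- state$u[a, 1L] * nx + state$u[a, 2L] * ny
  fb <- state$u[b, 1L] * nx + state$u[b, 2L] * ny
  fm <- state$u[mid, 1L] * nx + state$u[mid, 2L] * ny
  sa <- s_chain[-length(s_chain)]; sb <- s_chain[-1L]; sm <- (sa + sb) / 2

  n <- nrow(curve$nodes)
  num <- numeric(n)
  add_pt <- function(s, f, w) {
    k <- pmin(pmax(findInterval(s, curve$s), 1L), n - 1L)
    th <- (s - curve$s[k]) / ds_seg[k]
    num <<- num + accumulate_at(k, w * f * (1 - th), n) +
      accumulate_at(k + 1L, w * f * th, n)
  }
  add_pt(sa, fa, L / 6)
  add_pt(sm, fm, 4 * L / 6)
  add_pt(sb, fb, L / 6)
  # the pinned contact nodes cannot move: hand their flux share to the
  # neighbouring interior nodes so the total interface flux stays balanced
  num[2L] <- num[2L] + num[1L]
  num[n - 1L] <- num[n - 1L] + num[n]
  num[c(1L, n)] <- 0
  # divide by the discrete area gradient (half the neighbour chord), so the
  # implied polygon area rate telescopes to the vanishing discrete flux
  p <- curve$nodes
  lever <- c(1, 0.5 * sqrt(rowSums((p[3:n, , drop = FALSE] -
                                      p[1:(n - 2L), , drop = FALSE])^2)), 1)
  num / lever
}
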