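# Finite-element building blocks on drop meshes: linear (P1) elements for
# scalar problems (director components, streamfunction, Q-tensor) and
# quadratic (P2) velocity elements for the Taylor-Hood Stokes pair.

# Per-triangle geometry: area and gradients of the barycentric coordinates.
tri_geometry <- function(V, T) {
  x1 <- V[T[, 1L], 1L]; y1 <- V[T[, 1L], 2L]
  x2 <- V[T[, 2L], 1L]; y2 <- V[T[, 2L], 2L]
  x3 <- V[T[, 3L], 1L]; y3 <- V[T[, 3L], 2L]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  # grad lambda_i = (b_i, c_i)
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  by <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  list(area = area, bx = bx, by = by)
}

# P1 stiffness matrix, int grad(u).grad(v)
p1_stiffness <- function(V, T) {
  g <- tri_geometry(V, T)
  m <- nrow(T); nv <- nrow(V)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- T[, a]; jj[[k]] <- T[, b]
    xx[[k]] <- g$area * (g$bx[, a] * g$bx[, b] + g$by[, a] * g$by[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nv, nv))
}

# P1 lumped mass vector, int phi_i
p1_lumped_mass <- function(V, T) {
  g <- tri_geometry(V, T)
  accumulate_at(c(T[, 1L], T[, 2L], T[, 3L]), rep(g$area / 3, 3L), nrow(V))
}

accumulate_at <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Solve a scalar P1 Laplace problem with Dirichlet data on given vertices.
# rhs is the assembled load vector (zero for harmonic extension).
p1_dirichlet_solve <- function(K, dir_idx, dir_val, rhs = NULL) {
  nv <- nrow(K)
  free <- setdiff(seq_len(nv), dir_idx)
  u <- numeric(nv)
  u[dir_idx] <- dir_val
  if (is.null(rhs)) rhs <- numeric(nv)
  b <- rhs[free] - as.vector(K[free, dir_idx, drop = FALSE] %*% dir_val)
  if (length(free) > 0L) {
    u[free] <- as.vector(Matrix::solve(K[free, free, drop = FALSE], b))
  }
  u
}

# 7-point symmetric triangle quadrature, exact to polynomial degree 5.
tri_quadrature <- function() {
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  w1 <- 0.132394152788506; w2 <- 0.125939180544827
  lambda <- rbind(
    c(1 / 3, 1 / 3, 1 / 3),
    c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
    c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  list(lambda = lambda, w = c(0.225, w1, w1, w1, w2, w2, w2))
}

# P2 connectivity: unique edges, midpoint nodes appended after the vertices.
# T2 columns: v1 v2 v3 m12 m23 m31.
p2_connectivity <- function(mesh) {
  if (!is.null(mesh$cache$p2) &&
      identical(dim(mesh$cache$p2$T2), c(nrow(mesh$T), 6L))) {
    p2 <- mesh$cache$p2
    # coordinates move with the mesh; recompute midpoints
    p2$X <- rbind(mesh$V, (mesh$V[p2$edges[, 1L], , drop = FALSE] +
                             mesh$V[p2$edges[, 2L], , drop = FALSE]) / 2)
    return(p2)
  }
  T <- mesh$T; nv <- nrow(mesh$V)
  ea <- c(T[, 1L], T[, 2L], T[, 3L])
  eb <- c(T[, 2L], T[, 3L], T[, 1L])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  keyv <- lo * (nv + 1) + hi
  uk <- unique(keyv)
  eid <- match(keyv, uk)
  edges <- cbind(lo[match(uk, keyv)], hi[match(uk, keyv)])
  m <- nrow(T)
  T2 <- cbind(T, matrix(nv + eid, m, 3L))
  X <- rbind(mesh$V, (mesh$V[edges[, 1L], , drop = FALSE] +
                        mesh$V[edges[, 2L], , drop = FALSE]) / 2)
  p2 <- list(edges = edges, T2 = T2, X = X, n_nodes = nv + nrow(edges), nv = nv)
  mesh$cache$p2 <- p2
  p2
}

# Values of the six P2 basis functions at barycentric coordinates lq (3-vector)
p2_values <- function(lq) {
  c(lq[1L] * (2 * lq[1L] - 1), lq[2L] * (2 * lq[2L] - 1), lq[3L] * (2 * lq[3L] - 1),
    4 * lq[1L] * lq[2L], 4 * lq[2L] * lq[3L], 4 * lq[3L] * lq[1L])
}

# Gradients of the six P2 basis functions at a quadrature point for all
# triangles at once: returns list(GX, GY), each m x 6.
p2_gradients <- function(g, lq) {
  GX <- cbind((4 * lq[1L] - 1) * g$bx[, 1L],
              (4 * lq[2L] - 1) * g$bx[, 2L],
              (4 * lq[3L] - 1) * g$bx[, 3L],
              4 * (lq[2L] * g$bx[, 1L] + lq[1L] * g$bx[, 2L]),
              4 * (lq[3L] * g$bx[, 2L] + lq[2L] * g$bx[, 3L]),
              4 * (lq[1L] * g$bx[, 3L] + lq[3L] * g$bx[, 1L]))
  GY <- cbind((4 * lq[1L] - 1) * g$by[, 1L],
              (4 * lq[2L] - 1) * g$by[, 2L],
              (4 * lq[3L] - 1) * g$by[, 3L],
              4 * (lq[2L] * g$by[, 1L] + lq[1L] * g$by[, 2L]),
              4 * (lq[3L] * g$by[, 2L] + lq[2L] * g$by[, 3L]),
              4 * (lq[1L] * g$by[, 3L] + lq[3L] * g$by[, 1L]))
  list(GX = GX, GY = GY)
}
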