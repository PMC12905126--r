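#' Triangulate the drop domain
#'
#' Builds a conforming triangulation of the region bounded by the interface
#' polyline above and the substrate segment `y = 0`, `0 <= x <= 2` below.
#' All curve nodes become mesh vertices (so the mesh boundary polygon equals
#' the curve polygon exactly); interface and substrate edges are additionally
#' graded down to `grade_factor * h_mesh` within `grade_radius` of the two
#' contact points, which resolves the corner stress singularity and the
#' anchoring-mismatch defects that sit there. Where the drop thins into a
#' film, the local target size follows the gap so the film stays resolved.
#'
#' Interior vertices are seeded on a hexagonal lattice (with a tiny
#' deterministic jitter derived from `seed`), triangulated by Bowyer-Watson
#' Delaunay insertion, then improved by Lawson edge flips and smoothing.
#'
#' @param curve an [interface_curve()].
#' @param h_mesh target edge length away from the contact points (<= 0.2).
#' @param seed integer controlling the deterministic lattice jitter.
#' @param grade_factor edge-length reduction factor at the contact points.
#' @param grade_radius distance over which the grading acts.
#' @param min_angle required minimum triangle angle in degrees.
#' @return an object of class `drop_mesh`.
#' @export
build_mesh <- function(curve, h_mesh, seed = 1L, grade_factor = 0.25,
                       grade_radius = 0.2, min_angle = 15) {
  stopifnot(inherits(curve, "interface_curve"))
  if (!is.numeric(h_mesh) || h_mesh <= 0 || h_mesh > 0.2) {
    stop("`h_mesh` must be in (0, 0.2]")
  }
  bad <- polyline_self_intersection(curve$nodes)
  if (!is.null(bad)) {
    stop(sprintf("cannot mesh a self-intersecting curve: segments %d-%d and %d-%d cross",
                 bad[1L], bad[1L] + 1L, bad[2L], bad[2L] + 1L))
  }

  gap <- height_profile(curve)
  size_at <- function(x, y) {
    d <- pmin(sqrt(x^2 + y^2), sqrt((x - 2)^2 + y^2))
    h <- h_mesh * (grade_factor + (1 - grade_factor) * pmin(1, d / grade_radius))
    g <- stats::approx(gap$x, gap$h, xout = pmin(pmax(x, 0), 2), rule = 2)$y
    pmin(h, pmax(0.45 * g, 0.25 * h_mesh * grade_factor))
  }

  # --- boundary vertices -----------------------------------------------------
  iface <- subdivide_chain(curve$nodes, size_at)      # includes curve nodes
  sub_pts <- sample_segment(c(2, 0), c(0, 0), size_at)  # right -> left, open ends
  # closed polygon, counter-trav: interface left->right then substrate back
  nb_i <- nrow(iface$pts)
  poly <- rbind(iface$pts, sub_pts)
  nb <- nrow(poly)

  for (attempt in 1:3) {
    # --- interior seeds ------------------------------------------------------
    seeds <- hex_seeds(poly, size_at, shrink = 0.7^(attempt - 1), seed = seed)
    pts <- rbind(poly, seeds)

    # --- Delaunay + boundary recovery ---------------------------------------
    tri <- delaunay_bw(pts)
    tri <- drop_outside_triangles(pts, tri, poly)
    chain <- c(seq_len(nb), 1L)  # closed boundary vertex chain
    missing <- missing_chain_edges(tri, chain)
    rec <- 0L
    while (length(missing) > 0L && rec < 3L) {
      # remove interior seeds crowding the unrecovered boundary edges, retry
      keep <- rep(TRUE, nrow(seeds))
      for (e in missing) {
        a <- poly[chain[e], ]; b <- poly[chain[e + 1L], ]
        mid <- (a + b) / 2
        r <- sqrt(sum((b - a)^2))
        keep <- keep & ((seeds[, 1L] - mid[1L])^2 + (seeds[, 2L] - mid[2L])^2 > r^2)
      }
      seeds <- seeds[keep, , drop = FALSE]
      pts <- rbind(poly, seeds)
      tri <- delaunay_bw(pts)
      tri <- drop_outside_triangles(pts, tri, poly)
      missing <- missing_chain_edges(tri, chain)
      rec <- rec + 1L
    }
    if (length(missing) > 0L) {
      stop("failed to recover boundary edges in triangulation")
    }

    # --- quality improvement -------------------------------------------------
    for (round in 1:4) {
      tri <- lawson_flips(pts, tri, nb)
      pts <- smooth_interior(pts, tri, nb)
    }
    tri <- lawson_flips(pts, tri, nb)
    if (mesh_min_angle(pts, tri) >= min_angle) break
    if (attempt == 3L) {
      for (round in 1:6) {
        pts <- smooth_interior(pts, tri, nb)
        tri <- lawson_flips(pts, tri, nb)
      }
      if (mesh_min_angle(pts, tri) < min_angle) {
        stop(sprintf("mesh quality %.1f deg below the %.0f deg floor",
                     mesh_min_angle(pts, tri), min_angle))
      }
    }
  }

  # boundary edge tags: substrate iff both endpoints on y = 0
  e1 <- chain[-length(chain)]; e2 <- chain[-1L]
  on_sub <- abs(pts[, 2L]) < 1e-14
  tag <- ifelse(on_sub[e1] & on_sub[e2], "substrate", "interface")
  interface_chain <- seq_len(nb_i)
  substrate_chain <- c(1L, rev(seq.int(nb_i + 1L, nb)), nb_i)  # (0,0) -> (2,0)

  dimnames(pts) <- NULL
  structure(list(
    V = pts, T = orient_ccw(pts, tri),
    boundary_edges = data.frame(v1 = e1, v2 = e2, tag = tag),
    interface_chain = interface_chain,
    substrate_chain = substrate_chain,
    curve_vertex_ids = iface$orig_ids,
    iface_seg = iface$seg, iface_frac = iface$frac,
    h_mesh = h_mesh, seed = seed,
    cache = new.env(parent = emptyenv())
  ), class = "drop_mesh")
}

#' @exportS3Method base::print
print.drop_mesh <- function(x, ...) {
  cat(sprintf("<drop_mesh: %d vertices, %d triangles, h = %.3g, min angle %.1f deg>\n",
              nrow(x$V), nrow(x$T), x$h_mesh, mesh_min_angle(x$V, x$T)))
  invisible(x)
}

#' Total mesh area
#' @param mesh a `drop_mesh`.
#' @return sum of triangle areas.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$V, mesh$T))

#' Minimum triangle angle of a mesh, in degrees
#' @param V vertex matrix (or a `drop_mesh`, with `T` missing).
#' @param T triangle index matrix.
#' @return smallest interior angle over all triangles.
#' @export
mesh_min_angle <- function(V, T) {
  if (inherits(V, "drop_mesh")) { T <- V$T; V <- V$V }
  a2 <- rowSums((V[T[, 2L], , drop = FALSE] - V[T[, 3L], , drop = FALSE])^2)
  b2 <- rowSums((V[T[, 1L], , drop = FALSE] - V[T[, 3L], , drop = FALSE])^2)
  c2 <- rowSums((V[T[, 1L], , drop = FALSE] - V[T[, 2L], , drop = FALSE])^2)
  ang <- function(o2, p2, q2) acos(pmin(1, pmax(-1, (p2 + q2 - o2) / (2 * sqrt(p2 * q2)))))
  m <- pmin(ang(a2, b2, c2), ang(b2, a2, c2), ang(c2, a2, b2))
  min(m) * 180 / pi
}

triangle_areas <- function(V, T) {
  x1 <- V[T[, 1L], 1L]; y1 <- V[T[, 1L], 2L]
  x2 <- V[T[, 2L], 1L]; y2 <- V[T[, 2L], 2L]
  x3 <- V[T[, 3L], 1L]; y3 <- V[T[, 3L], 2L]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

orient_ccw <- function(V, T) {
  a <- triangle_areas(V, T)
  flip <- a < 0
  if (any(flip)) T[flip, c(2L, 3L)] <- T[flip, c(3L, 2L)]
  T
}

# interface height profile h(x): max-y crossing of the curve per column
height_profile <- function(curve, n = 101L) {
  xs <- seq(0, 2, length.out = n)
  p <- curve$nodes
  hs <- vapply(xs, function(x) {
    n1 <- nrow(p)
    x1 <- p[-n1, 1L]; x2 <- p[-1L, 1L]
    hit <- (x1 <= x & x2 > x) | (x2 <= x & x1 > x)
    if (!any(hit)) return(max(p[, 2L]) * 0 + if (x <= 0 || x >= 2) 0.0 else NA_real_)
    tt <- (x - x1[hit]) / (x2[hit] - x1[hit])
    max(p[-n1, 2L][hit] + tt * (p[-1L, 2L][hit] - p[-n1, 2L][hit]))
  }, 0)
  hs[is.na(hs)] <- max(p[, 2L])
  hs[1L] <- hs[2L]; hs[n] <- hs[n - 1L]
  list(x = xs, h = pmax(hs, 1e-6))
}

# Subdivide curve segments so spacing <= local size; original nodes kept.
subdivide_chain <- function(nodes, size_at) {
  n <- nrow(nodes)
  pts <- list(); seg <- integer(0); frac <- numeric(0); orig <- integer(n)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    k <- k + 1L; orig[i] <- k
    pts[[k]] <- nodes[i, ]; seg[k] <- i; frac[k] <- 0
    a <- nodes[i, ]; b <- nodes[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    hl <- size_at((a[1L] + b[1L]) / 2, (a[2L] + b[2L]) / 2)
    m <- max(1L, ceiling(len / hl))
    if (m > 1L) {
      for (j in seq_len(m - 1L)) {
        k <- k + 1L
        f <- j / m
        pts[[k]] <- a + f * (b - a); seg[k] <- i; frac[k] <- f
      }
    }
  }
  k <- k + 1L; orig[n] <- k
  pts[[k]] <- nodes[n, ]; seg[k] <- n - 1L; frac[k] <- 1
  list(pts = do.call(rbind, pts), seg = seg, frac = frac, orig_ids = orig)
}

# graded samples strictly between a and b (endpoints excluded)
sample_segment <- function(a, b, size_at) {
  len <- sqrt(sum((b - a)^2))
  s <- 0; ss <- numeric(0)
  repeat {
    p <- a + (s / len) * (b - a)
    s <- s + size_at(p[1L], p[2L])
    if (s >= len - 1e-9) break
    ss <- c(ss, s)
  }
  if (length(ss) == 0L) return(matrix(numeric(0), ncol = 2L))
  # rescale so the last gap is not tiny
  ss <- ss * (len / (max(ss) + size_at(b[1L], b[2L])))
  t(vapply(ss, function(s) a + (s / len) * (b - a), numeric(2L)))
}

# hexagonal interior seed lattice with size-field thinning
hex_seeds <- function(poly, size_at, shrink = 1, seed = 1L) {
  hmin <- max(min(size_at(c(0.01, 1, 1.99), c(0.01, 0.5, 0.01))), 1e-4)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  # candidate lattice at the finest scale, thinned greedily by the size field
  h0 <- hmin * shrink
  ny <- max(2L, ceiling((yr[2L] - yr[1L]) / (h0 * sqrt(3) / 2)))
  rows <- lapply(seq_len(ny), function(iy) {
    y <- yr[1L] + (iy - 0.5) * (yr[2L] - yr[1L]) / ny
    off <- if (iy %% 2L == 0L) h0 / 2 else 0
    xs <- seq(xr[1L] + off, xr[2L], by = h0)
    cbind(xs, y)
  })
  cand <- do.call(rbind, rows)
  # deterministic jitter to break lattice degeneracies
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cand <- cand + matrix(stats::runif(length(cand), -0.08, 0.08), ncol = 2L) * h0
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  inside <- point_in_polygon(cand, poly)
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0L) return(matrix(numeric(0), ncol = 2L))
  hc <- size_at(cand[, 1L], cand[, 2L]) * shrink
  # keep clear of the boundary
  db <- nearest_dist(cand, poly)
  ok <- db > 0.65 * hc
  cand <- cand[ok, , drop = FALSE]; hc <- hc[ok]
  if (nrow(cand) == 0L) return(matrix(numeric(0), ncol = 2L))
  thin_points(cand, 0.88 * hc)
}

# greedy Poisson-disk thinning with a background grid
thin_points <- function(p, r) {
  n <- nrow(p)
  cell <- max(r)
  gx <- floor(p[, 1L] / cell); gy <- floor(p[, 2L] / cell)
  key <- paste(gx, gy)
  grid <- split(seq_len(n), key)
  keykeep <- new.env(parent = emptyenv())
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(gx[i] + dx, gy[i] + dy)
      ids <- keykeep[[k]]
      if (!is.null(ids)) {
        d2 <- (p[ids, 1L] - p[i, 1L])^2 + (p[ids, 2L] - p[i, 2L])^2
        if (any(d2 < (0.5 * (r[ids] + r[i]))^2)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      keep[i] <- TRUE
      k <- paste(gx[i], gy[i])
      keykeep[[k]] <- c(keykeep[[k]], i)
    }
  }
  p[keep, , drop = FALSE]
}

nearest_dist <- function(p, q) {
  # distance from each row of p to the nearest row of q (block-wise)
  n <- nrow(p); out <- numeric(n)
  step <- max(1L, floor(2e6 / nrow(q)))
  for (i0 in seq(1L, n, by = step)) {
    i1 <- min(n, i0 + step - 1L)
    d2 <- outer(p[i0:i1, 1L], q[, 1L], "-")^2 + outer(p[i0:i1, 2L], q[, 2L], "-")^2
    out[i0:i1] <- sqrt(apply(d2, 1L, min))
  }
  out
}

point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  inside <- rep(FALSE, nrow(p))
  x <- p[, 1L]; y <- p[, 2L]
  for (e in seq_len(n)) {
    x1 <- poly[e, 1L]; y1 <- poly[e, 2L]
    x2 <- poly[j[e], 1L]; y2 <- poly[j[e], 2L]
    hit <- ((y1 <= y & y2 > y) | (y2 <= y & y1 > y))
    if (any(hit)) {
      xi <- x1 + (y[hit] - y1) / (y2 - y1) * (x2 - x1)
      flip <- xi > x[hit]
      inside[hit][flip] <- !inside[hit][flip]
    }
  }
  inside
}

# ---------------------------------------------------------------------------
# Bowyer-Watson Delaunay triangulation
# ---------------------------------------------------------------------------

delaunay_bw <- function(P) {
  n <- nrow(P)
  xr <- range(P[, 1L]); yr <- range(P[, 2L])
  dx <- diff(xr); dy <- diff(yr); dmax <- max(dx, dy, 1)
  cx <- mean(xr); cy <- mean(yr)
  super <- rbind(c(cx - 30 * dmax, cy - 20 * dmax),
                 c(cx + 30 * dmax, cy - 20 * dmax),
                 c(cx, cy + 30 * dmax))
  V <- rbind(P, super)
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1L, 3L)
  cc <- circumcircles(V, tri)
  for (i in seq_len(n)) {
    px <- V[i, 1L]; py <- V[i, 2L]
    bad <- which((px - cc[, 1L])^2 + (py - cc[, 2L])^2 <= cc[, 3L] * (1 + 1e-12))
    if (length(bad) == 0L) stop("Delaunay insertion failed (point outside hull)")
    # cavity boundary: edges of bad triangles appearing exactly once
    bt <- tri[bad, , drop = FALSE]
    ea <- c(bt[, 1L], bt[, 2L], bt[, 3L])
    eb <- c(bt[, 2L], bt[, 3L], bt[, 1L])
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    keyv <- lo * (n + 4) + hi
    cnt <- table(keyv)
    once <- as.numeric(names(cnt))[cnt == 1L]
    selb <- keyv %in% once
    newt <- cbind(ea[selb], eb[selb], i)
    tri <- rbind(tri[-bad, , drop = FALSE], newt)
    cc <- rbind(cc[-bad, , drop = FALSE], circumcircles(V, newt))
  }
  keep <- tri[, 1L] <= n & tri[, 2L] <= n & tri[, 3L] <= n
  tri[keep, , drop = FALSE]
}

circumcircles <- function(V, T) {
  ax <- V[T[, 1L], 1L]; ay <- V[T[, 1L], 2L]
  bx <- V[T[, 2L], 1L]; by <- V[T[, 2L], 2L]
  cx <- V[T[, 3L], 1L]; cy <- V[T[, 3L], 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[d == 0] <- .Machine$double.xmin
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  cbind(ux, uy, r2)
}

drop_outside_triangles <- function(V, T, poly) {
  cen <- cbind((V[T[, 1L], 1L] + V[T[, 2L], 1L] + V[T[, 3L], 1L]) / 3,
               (V[T[, 1L], 2L] + V[T[, 2L], 2L] + V[T[, 3L], 2L]) / 3)
  T[point_in_polygon(cen, poly), , drop = FALSE]
}

missing_chain_edges <- function(T, chain) {
  nvert <- max(T)
  ea <- c(T[, 1L], T[, 2L], T[, 3L])
  eb <- c(T[, 2L], T[, 3L], T[, 1L])
  have <- unique(pmin(ea, eb) * (nvert + 1) + pmax(ea, eb))
  a <- chain[-length(chain)]; b <- chain[-1L]
  want <- pmin(a, b) * (nvert + 1) + pmax(a, b)
  which(!(want %in% have))
}

# Lawson edge flips toward the (constrained) Delaunay triangulation;
# edges between boundary vertices (index <= nb) that lie on the boundary
# chain are never flipped (they are always chain edges since both incident
# triangles exist only for interior edges).
lawson_flips <- function(V, T, nb, max_sweeps = 25L) {
  for (sweep in seq_len(max_sweeps)) {
    m <- nrow(T)
    ea <- c(T[, 1L], T[, 2L], T[, 3L])
    eb <- c(T[, 2L], T[, 3L], T[, 1L])
    eo <- c(T[, 3L], T[, 1L], T[, 2L])   # opposite vertex
    et <- rep(seq_len(m), 3L)
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    keyv <- lo * (nrow(V) + 1) + hi
    ord <- order(keyv)
    keyv <- keyv[ord]; et <- et[ord]; eo <- eo[ord]; lo <- lo[ord]; hi <- hi[ord]
    dup <- which(keyv[-1L] == keyv[-length(keyv)])
    if (length(dup) == 0L) return(T)
    # candidate interior edges
    i1 <- dup; i2 <- dup + 1L
    a <- lo[i1]; b <- hi[i1]; c <- eo[i1]; d <- eo[i2]
    t1 <- et[i1]; t2 <- et[i2]
    viol <- incircle(V[a, , drop = FALSE], V[b, , drop = FALSE],
                     V[c, , drop = FALSE], V[d, , drop = FALSE])
    todo <- which(viol)
    if (length(todo) == 0L) return(T)
    used <- logical(m); nflip <- 0L
    for (k in todo) {
      if (used[t1[k]] || used[t2[k]]) next
      # flip edge (a,b) -> (c,d)
      T[t1[k], ] <- c(a[k], d[k], c[k])
      T[t2[k], ] <- c(d[k], b[k], c[k])
      used[t1[k]] <- TRUE; used[t2[k]] <- TRUE
      nflip <- nflip + 1L
    }
    T <- orient_ccw(V, T)
    if (nflip == 0L) return(T)
  }
  T
}

# is d strictly inside the circumcircle of CCW triangle (a,b,c)?
incircle <- function(a, b, c, d) {
  # ensure (a,b,c) is CCW
  s <- (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
       (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
  sw <- s < 0
  tmp <- b; b[sw, ] <- c[sw, ]; c[sw, ] <- tmp[sw, ]
  adx <- a[, 1L] - d[, 1L]; ady <- a[, 2L] - d[, 2L]
  bdx <- b[, 1L] - d[, 1L]; bdy <- b[, 2L] - d[, 2L]
  cdx <- c[, 1L] - d[, 1L]; cdy <- c[, 2L] - d[, 2L]
  det <- (adx^2 + ady^2) * (bdx * cdy - cdx * bdy) -
         (bdx^2 + bdy^2) * (adx * cdy - cdx * ady) +
         (cdx^2 + cdy^2) * (adx * bdy - bdx * ady)
  det > 1e-14
}

smooth_interior <- function(V, T, nb, relax = 0.8) {
  m <- nrow(T); nv <- nrow(V)
  ea <- c(T[, 1L], T[, 2L], T[, 3L])
  eb <- c(T[, 2L], T[, 3L], T[, 1L])
  A <- Matrix::sparseMatrix(i = c(ea, eb), j = c(eb, ea), x = 1,
                            dims = c(nv, nv))
  A <- (A > 0) * 1
  deg <- Matrix::rowSums(A)
  avg <- as.matrix(A %*% V) / pmax(deg, 1)
  idx <- (nb + 1L):nv
  if (length(idx) > 0L && idx[1L] <= nv) {
    V[idx, ] <- (1 - relax) * V[idx, , drop = FALSE] + relax * avg[idx, , drop = FALSE]
  }
  V
}

#' Deform a mesh to follow an updated interface curve
#'
#' Moves the mesh's interface vertices onto the new curve (same segment
#' fractions as at build time) and propagates the displacement into the
#' interior by harmonic extension, reusing a cached factorisation of the
#' graph Laplacian. Used between full rebuilds; the caller is responsible
#' for triggering a rebuild when quality degrades.
#'
#' @param mesh a `drop_mesh` built from a curve with the same node count.
#' @param curve the updated `interface_curve`.
#' @return the deformed `drop_mesh` (quality not re-checked here).
#' @export
deform_mesh <- function(mesh, curve) {
  nodes <- curve$nodes
  seg <- mesh$iface_seg; frac <- mesh$iface_frac
  newpos <- nodes[seg, , drop = FALSE] * (1 - frac) +
    nodes[pmin(seg + 1L, nrow(nodes)), , drop = FALSE] * frac
  nv <- nrow(mesh$V)
  ifc <- mesh$interface_chain
  disp <- matrix(0, nv, 2L)
  disp[ifc, ] <- newpos - mesh$V[ifc, , drop = FALSE]
  bnd <- sort(unique(c(mesh$boundary_edges$v1, mesh$boundary_edges$v2)))
  int <- setdiff(seq_len(nv), bnd)
  if (length(int) > 0L) {
    if (is.null(mesh$cache$Lfac)) {
      K <- p1_stiffness(mesh$V, mesh$T)
      mesh$cache$Kib <- K[int, bnd, drop = FALSE]
      mesh$cache$Lfac <- Matrix::Cholesky(Matrix::forceSymmetric(K[int, int]))
      mesh$cache$int <- int; mesh$cache$bnd <- bnd
    }
    rhs <- -mesh$cache$Kib %*% disp[bnd, , drop = FALSE]
    disp[int, ] <- as.matrix(Matrix::solve(mesh$cache$Lfac, rhs))
  }
  mesh$V <- mesh$V + disp
  mesh$T <- orient_ccw(mesh$V, mesh$T)
  mesh
}

#' Interpolate vertex fields at arbitrary points
#'
#' Piecewise-linear (P1) interpolation: each query point is located in a
#' containing triangle and the vertex values are blended barycentrically.
#' Points outside the mesh get the value of the nearest vertex.
#'
#' @param mesh a `drop_mesh`.
#' @param values numeric vector (or matrix, one column per field) of vertex
#'   values.
#' @param pts n x 2 matrix of query points.
#' @return interpolated values (vector or matrix matching `values`).
#' @export
interp_p1 <- function(mesh, values, pts) {
  vals <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = 2L)
  g <- tri_geometry(mesh$V, mesh$T)
  T <- mesh$T
  x1 <- mesh$V[T[, 1L], 1L]; y1 <- mesh$V[T[, 1L], 2L]
  out <- matrix(NA_real_, nrow(pts), ncol(vals))
  for (i in seq_len(nrow(pts))) {
    dx <- pts[i, 1L] - x1; dy <- pts[i, 2L] - y1
    l2 <- g$bx[, 2L] * dx + g$by[, 2L] * dy
    l3 <- g$bx[, 3L] * dx + g$by[, 3L] * dy
    l1 <- 1 - l2 - l3
    k <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)[1L]
    if (is.na(k)) {
      j <- which.min((mesh$V[, 1L] - pts[i, 1L])^2 + (mesh$V[, 2L] - pts[i, 2L])^2)
      out[i, ] <- vals[j, ]
    } else {
      out[i, ] <- l1[k] * vals[T[k, 1L], ] + l2[k] * vals[T[k, 2L], ] +
        l3[k] * vals[T[k, 3L], ]
    }
  }
  if (is.matrix(values)) out else out[, 1L]
}
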