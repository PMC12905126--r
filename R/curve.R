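#' Interface curves for a pinned 2D drop
#'
#' An `interface_curve` is the only dynamical state of the simulation: an
#' ordered polyline of the liquid-air interface of a drop pinned to the
#' substrate segment `0 <= x <= 2`, `y = 0` (lengths in units of the initial
#' drop radius). Nodes run from the left contact point `(0, 0)` over the apex
#' to the right contact point `(2, 0)`; both contact nodes are immutable.
#'
#' @param nodes numeric matrix with two columns (x, y), ordered from the left
#'   contact point to the right contact point.
#' @param check validate the invariants (pinned endpoints, interior nodes
#'   above the substrate, no self-intersection)?
#' @return an object of class `interface_curve` with fields `nodes` and the
#'   cumulative arclength `s`.
#' @export
interface_curve <- function(nodes, check = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 2L) stop("`nodes` must be an n x 2 matrix of (x, y)")
  n <- nrow(nodes)
  if (n < 4L) stop("an interface curve needs at least 4 nodes")
  if (check) {
    if (max(abs(nodes[1L, ] - c(0, 0))) > 1e-12 ||
        max(abs(nodes[n, ] - c(2, 0))) > 1e-12) {
      stop("contact nodes must be exactly (0, 0) and (2, 0)")
    }
    if (any(nodes[2:(n - 1L), 2L] <= 0)) {
      stop("all interior interface nodes must satisfy y > 0")
    }
    if (any(rowSums(abs(diff(nodes))) == 0)) {
      stop("duplicate consecutive nodes in interface curve")
    }
    bad <- polyline_self_intersection(nodes)
    if (!is.null(bad)) {
      stop(sprintf("interface polyline self-intersects: segments %d-%d and %d-%d cross",
                   bad[1L], bad[1L] + 1L, bad[2L], bad[2L] + 1L))
    }
  }
  # snap contact-node roundoff (leave non-pinned test curves alone)
  if (max(abs(nodes[1L, ] - c(0, 0))) < 1e-9) nodes[1L, ] <- c(0, 0)
  if (max(abs(nodes[n, ] - c(2, 0))) < 1e-9) nodes[n, ] <- c(2, 0)
  ds <- sqrt(rowSums(diff(nodes)^2))
  structure(list(nodes = nodes, s = c(0, cumsum(ds))),
            class = "interface_curve")
}

#' Initial semicircular drop shape
#'
#' Nodes on the circle of radius 1 centred at (1, 0), equally spaced in arc
#' angle, with the contact nodes exactly at (0, 0) and (2, 0).
#'
#' @param n_boundary number of interface nodes (>= 16).
#' @return an `interface_curve`.
#' @examples
#' curve <- initial_semicircle(64)
#' enclosed_area(curve)  # ~ pi / 2
#' @export
initial_semicircle <- function(n_boundary = 128L) {
  n_boundary <- as.integer(n_boundary)
  if (is.na(n_boundary) || n_boundary < 16L) {
    stop("`n_boundary` must be at least 16 to resolve the drop shape")
  }
  theta <- seq(pi, 0, length.out = n_boundary)
  nodes <- cbind(1 + cos(theta), sin(theta))
  nodes[1L, ] <- c(0, 0)
  nodes[n_boundary, ] <- c(2, 0)
  # clamp roundoff so interior y stays strictly positive
  nodes[, 2L] <- pmax(nodes[, 2L], 0)
  nodes[2:(n_boundary - 1L), 2L] <- pmax(nodes[2:(n_boundary - 1L), 2L], 1e-15)
  interface_curve(nodes)
}

#' @exportS3Method base::print
print.interface_curve <- function(x, ...) {
  cat(sprintf("<interface_curve: %d nodes, length %.4f, area %.6f, apex %.4f>\n",
              nrow(x$nodes), x$s[length(x$s)], enclosed_area(x), max(x$nodes[, 2L])))
  invisible(x)
}

#' Enclosed drop area
#'
#' Area of the polygon bounded by the interface polyline above and the
#' substrate segment below (shoelace formula).
#'
#' @param curve an `interface_curve`, or a plain n x 2 matrix describing a
#'   closed polygon.
#' @return scalar area.
#' @export
enclosed_area <- function(curve) {
  p <- if (inherits(curve, "interface_curve")) curve$nodes else as.matrix(curve)
  abs(polygon_signed_area(p))
}

polygon_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

#' Tangent, normal and curvature along the interface
#'
#' The unit tangent points along increasing arclength (left contact to right
#' contact); the unit normal is the tangent rotated by +pi/2, which points out
#' of the fluid. Curvature uses the circumscribed circle through each node and
#' its two neighbours (one-sided at the pinned contact nodes), signed so that
#' the unit semicircle has C = +1; C is twice the mean curvature entering the
#' capillary traction.
#'
#' @param curve an `interface_curve`.
#' @return list with matrices `t`, `n` (n x 2) and vector `C`.
#' @export
frame_and_curvature <- function(curve) {
  p <- curve$nodes
  n <- nrow(p)
  if (any(rowSums(abs(diff(p))) == 0)) stop("duplicate consecutive nodes")
  # tangents: central differences in the interior, one-sided at the ends
  dfwd <- rbind(diff(p), p[n, ] - p[n - 1L, ])
  dctr <- rbind(p[2L, ] - p[1L, ],
                p[3:n, ] - p[1:(n - 2L), ],
                p[n, ] - p[n - 1L, ])
  tt <- dctr / sqrt(rowSums(dctr^2))
  nn <- cbind(-tt[, 2L], tt[, 1L])
  # circumscribed-circle curvature through (i-1, i, i+1); one-sided at ends
  im <- c(1L, 1:(n - 2L), n - 2L)
  ic <- c(2L, 2:(n - 1L), n - 1L)
  ip <- c(3L, 3:n, n)
  a <- p[ic, ] - p[im, ]
  b <- p[ip, ] - p[ic, ]
  c2 <- p[ip, ] - p[im, ]
  cross <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  denom <- sqrt(rowSums(a^2) * rowSums(b^2) * rowSums(c2^2))
  C <- -2 * cross / pmax(denom, .Machine$double.xmin)
  C[denom == 0] <- 0
  list(t = tt, n = nn, C = C)
}

#' Redistribute interface nodes at equal arclength
#'
#' Nodes are re-placed at equal arclength along the piecewise-linear
#' interpolant of the input polyline; the pinned contact nodes are unchanged,
#' and the shape change is bounded by the corner-cutting error of the chords,
#' O(spacing^2 x curvature).
#'
#' @param curve an `interface_curve`.
#' @param n number of nodes in the output (default: same as input).
#' @return an `interface_curve` with equispaced nodes.
#' @export
redistribute <- function(curve, n = NULL) {
  p <- curve$nodes
  s <- curve$s
  if (is.null(n)) n <- nrow(p)
  sq <- seq(0, s[length(s)], length.out = n)
  x <- stats::approx(s, p[, 1L], xout = sq, ties = "ordered")$y
  y <- stats::approx(s, p[, 2L], xout = sq, ties = "ordered")$y
  nodes <- cbind(x, pmax(y, 0))
  nodes[1L, ] <- c(0, 0)
  nodes[n, ] <- c(2, 0)
  nodes[2:(n - 1L), 2L] <- pmax(nodes[2:(n - 1L), 2L], 1e-15)
  interface_curve(nodes, check = FALSE)
}

#' Mirror asymmetry of the drop shape
#'
#' Area of the symmetric difference between the drop region and its
#' reflection about the midplane x = 1, normalised by the drop area. Zero for
#' mirror-symmetric shapes; the value is identical for a curve and its
#' reflection by construction (the vertical scanlines are placed symmetrically
#' about x = 1 and interval arithmetic along each scanline is exact).
#'
#' @param curve an `interface_curve`.
#' @param n_columns number of vertical scanlines over `0 < x < 2`.
#' @return scalar in `[0, 1]`.
#' @export
mirror_asymmetry <- function(curve, n_columns = 800L) {
  poly <- curve$nodes  # closed implicitly along the substrate
  m <- as.integer(n_columns)
  xs <- 2 * (seq_len(m) - 0.5) / m      # symmetric about x = 1
  ivals <- lapply(xs, function(x) polygon_column_intervals(poly, x))
  lenA <- vapply(ivals, interval_total_len, 0)
  lenI <- numeric(m)
  for (j in seq_len(m)) {
    lenI[j] <- interval_intersect_len(ivals[[j]], ivals[[m + 1L - j]])
  }
  dx <- 2 / m
  area <- sum(lenA) * dx
  if (area <= 0) return(0)
  sym_diff <- sum(lenA + lenA[m:1L] - 2 * lenI) * dx
  max(0, sym_diff / area)
}

# y-intervals of the drop polygon cut by the vertical line at x.
# Half-open crossing rule keeps the count even at polygon vertices.
polygon_column_intervals <- function(poly, x) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
  hit <- (x1 <= x & x2 > x) | (x2 <= x & x1 > x)
  if (!any(hit)) return(matrix(numeric(0), ncol = 2L))
  tt <- (x - x1[hit]) / (x2[hit] - x1[hit])
  ys <- sort(y1[hit] + tt * (y2[hit] - y1[hit]))
  k <- length(ys)
  if (k %% 2L == 1L) ys <- ys[-k]  # degenerate grazing; drop the odd crossing
  matrix(ys, ncol = 2L, byrow = TRUE)
}

interval_total_len <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  sum(iv[, 2L] - iv[, 1L])
}

interval_intersect_len <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot
}

#' Reflect a curve about the midplane x = 1
#'
#' @param curve an `interface_curve`.
#' @return the mirrored `interface_curve` (node order reversed so the
#'   orientation convention is preserved).
#' @export
reflect_curve <- function(curve) {
  p <- curve$nodes[nrow(curve$nodes):1L, , drop = FALSE]
  p[, 1L] <- 2 - p[, 1L]
  interface_curve(p, check = FALSE)
}

# First properly crossing non-adjacent segment pair, or NULL.
polyline_self_intersection <- function(p) {
  n <- nrow(p) - 1L  # segments i: p[i] -> p[i+1]
  if (n < 3L) return(NULL)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (segments_cross_any(p[i, ], p[i + 1L, ], p[js, , drop = FALSE],
                           p[js + 1L, , drop = FALSE])) {
      for (jj in js) {
        if (segments_cross_any(p[i, ], p[i + 1L, ], p[jj, , drop = FALSE],
                               p[jj + 1L, , drop = FALSE])) return(c(i, jj))
      }
    }
  }
  NULL
}

segments_cross_any <- function(a, b, cs, ds) {
  d1 <- orient2(cs, ds, matrix(a, nrow(cs), 2L, byrow = TRUE))
  d2 <- orient2(cs, ds, matrix(b, nrow(cs), 2L, byrow = TRUE))
  am <- matrix(a, nrow(cs), 2L, byrow = TRUE)
  bm <- matrix(b, nrow(cs), 2L, byrow = TRUE)
  d3 <- orient2(am, bm, cs)
  d4 <- orient2(am, bm, ds)
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

orient2 <- function(a, b, c) {
  (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
    (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
}

#' Hausdorff distance between two polylines
#'
#' Symmetric point-to-segment Hausdorff distance, used to compare steady
#' shapes (e.g. mirror pairs or duality pairs of anchoring conditions).
#'
#' @param a,b `interface_curve` objects or n x 2 matrices.
#' @return scalar distance.
#' @export
hausdorff_distance <- function(a, b) {
  pa <- if (inherits(a, "interface_curve")) a$nodes else as.matrix(a)
  pb <- if (inherits(b, "interface_curve")) b$nodes else as.matrix(b)
  max(directed_hausdorff(pa, pb), directed_hausdorff(pb, pa))
}

directed_hausdorff <- function(pa, pb) {
  # max over points of pa of distance to polyline pb
  n <- nrow(pb) - 1L
  dmax <- 0
  for (i in seq_len(nrow(pa))) {
    q <- pa[i, ]
    e <- pb[2:(n + 1L), , drop = FALSE] - pb[1:n, , drop = FALSE]
    w <- cbind(q[1L] - pb[1:n, 1L], q[2L] - pb[1:n, 2L])
    tt <- pmin(pmax(rowSums(w * e) / pmax(rowSums(e^2), 1e-300), 0), 1)
    px <- pb[1:n, 1L] + tt * e[, 1L]
    py <- pb[1:n, 2L] + tt * e[, 2L]
    d <- min((q[1L] - px)^2 + (q[2L] - py)^2)
    dmax <- max(dmax, d)
  }
  sqrt(dmax)
}
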