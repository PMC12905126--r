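#' Anchoring specification by winding numbers
#'
#' The boundary-polarized active units make `w * pi/2` counterclockwise
#' quarter turns relative to the boundary tangent: `w_s` quarter turns from
#' `e_x` at the substrate and `w_i` quarter turns from the interface tangent
#' at the liquid-air interface. Winding numbers are reduced mod 4 on
#' construction; the substrate value must land in {0, 1} (planar or
#' homeotropic substrate anchoring).
#'
#' @param w_s integer winding number at the substrate (0 or 1 after mod-4).
#' @param w_i integer winding number at the interface (0..3 after mod-4).
#' @return an `anchoring_spec` object.
#' @export
anchoring_spec <- function(w_s = 0L, w_i = 0L) {
  w_s <- as.integer(w_s) %% 4L
  w_i <- as.integer(w_i) %% 4L
  if (!w_s %in% c(0L, 1L)) {
    stop("`w_s` must reduce to 0 (planar) or 1 (homeotropic) mod 4")
  }
  structure(list(w_s = w_s, w_i = w_i), class = "anchoring_spec")
}

rot_quarter <- function(w) {
  th <- (w %% 4L) * pi / 2
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Boundary director values from the anchoring specification
#'
#' Substrate vertices carry `R(w_s pi/2) e_x`; interface vertices carry
#' `R(w_i pi/2) t_hat`, with the tangent taken from the interface curve and
#' interpolated to the (possibly subdivided) mesh boundary. The two contact
#' vertices receive the substrate value (substrate precedence).
#'
#' @param mesh a `drop_mesh` built from `curve`.
#' @param curve the `interface_curve` the mesh tracks.
#' @param anchoring an [anchoring_spec()].
#' @return list with integer vector `idx` (boundary vertex ids) and matrix
#'   `p` (their director values).
#' @export
boundary_director <- function(mesh, curve, anchoring) {
  stopifnot(inherits(anchoring, "anchoring_spec"))
  fr <- frame_and_curvature(curve)
  seg <- mesh$iface_seg; frac <- mesh$iface_frac
  tt <- fr$t[seg, , drop = FALSE] * (1 - frac) +
    fr$t[pmin(seg + 1L, nrow(fr$t)), , drop = FALSE] * frac
  tt <- tt / sqrt(rowSums(tt^2))
  Ri <- rot_quarter(anchoring$w_i)
  pi_vals <- tt %*% t(Ri)
  ps <- as.vector(rot_quarter(anchoring$w_s) %*% c(1, 0))

  ifc <- mesh$interface_chain
  sub <- mesh$substrate_chain
  idx <- c(ifc, sub)
  p <- rbind(pi_vals, matrix(ps, length(sub), 2L, byrow = TRUE))
  # substrate precedence at the two contact vertices (they appear in both
  # chains; later rows win below)
  keep <- !duplicated(rev(idx))
  keep <- rev(keep)
  list(idx = idx[keep], p = p[keep, , drop = FALSE])
}

#' Quasi-static director field: componentwise harmonic extension
#'
#' In the strong elastic limit the director relaxes instantaneously to the
#' minimiser of the one-constant Frank energy, i.e. each Cartesian component
#' solves the Laplace equation with the anchoring Dirichlet data. No unit-norm
#' constraint is applied in the bulk: `|p|` dips towards zero at topological
#' defects, which naturally regularises the active stress there.
#'
#' @param mesh a `drop_mesh`.
#' @param bc boundary values from [boundary_director()] (or any list with
#'   `idx` and `p` covering all boundary vertices).
#' @param normalize if `TRUE`, renormalise `p / max(|p|, 0.1)` in the bulk
#'   (sensitivity studies only; default off).
#' @return a `director_field`: matrix `p` (vertices x 2).
#' @export
solve_director <- function(mesh, bc, normalize = FALSE) {
  nv <- nrow(mesh$V)
  if (nv == 0L || nrow(mesh$T) == 0L) stop("empty mesh")
  bnd <- sort(unique(c(mesh$boundary_edges$v1, mesh$boundary_edges$v2)))
  if (!all(bnd %in% bc$idx)) stop("boundary data must cover all boundary vertices")
  K <- p1_stiffness(mesh$V, mesh$T)
  px <- p1_dirichlet_solve(K, bc$idx, bc$p[, 1L])
  py <- p1_dirichlet_solve(K, bc$idx, bc$p[, 2L])
  p <- cbind(px, py)
  if (normalize) {
    nrm <- pmax(sqrt(rowSums(p^2)), 0.1)
    p <- p / nrm
  }
  structure(list(p = p, normalize = normalize), class = "director_field")
}

#' @exportS3Method base::print
print.director_field <- function(x, ...) {
  nrm <- sqrt(rowSums(x$p^2))
  cat(sprintf("<director_field: %d vertices, |p| in [%.3f, %.3f]>\n",
              nrow(x$p), min(nrm), max(nrm)))
  invisible(x)
}

# vertex arrays (a11, a12, a22) of the nematic tensor entering the active
# stress: pp for a director field, Q for a Q-tensor field
active_tensor <- function(nematic) {
  if (inherits(nematic, "director_field")) {
    cbind(nematic$p[, 1L]^2, nematic$p[, 1L] * nematic$p[, 2L], nematic$p[, 2L]^2)
  } else if (inherits(nematic, "q_field")) {
    cbind(nematic$Qxx, nematic$Qxy, -nematic$Qxx)
  } else {
    stop("nematic must be a director_field or q_field")
  }
}

#' Locate orientational defects as minima of |p|
#'
#' Topological defects of the harmonic director appear as isolated dips of
#' the director magnitude. This census returns local minima of `|p|` below
#' `threshold` over the mesh vertex graph (including boundary vertices, so
#' the contact-point defects of parallel anchoring are counted); minima
#' closer than `2 * h_mesh` are merged to the deepest.
#'
#' The default threshold of 0.75 is chosen to count the quarter-turn
#' anchoring-mismatch defects at the contact corners: a `pi/2` jump in the
#' boundary data makes the harmonic `|p|` dip only to `1/sqrt(2)`, while a
#' `pi` mismatch or a bulk defect drives `|p|` towards zero.
#'
#' @param field a `director_field`.
#' @param mesh the `drop_mesh` the field lives on.
#' @param threshold report minima with `|p|` below this value (in (0, 1)).
#' @return data.frame with columns `x`, `y`, `p_norm`.
#' @export
defect_census <- function(field, mesh, threshold = 0.75) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0, 1)")
  nrm <- sqrt(rowSums(field$p^2))
  loc <- local_minima_vertices(mesh, nrm)
  loc <- loc[nrm[loc] < threshold]
  merged <- merge_extrema(mesh$V[loc, , drop = FALSE], nrm[loc],
                          radius = 2 * mesh$h_mesh, deepest = TRUE)
  data.frame(x = merged$xy[, 1L], y = merged$xy[, 2L], p_norm = merged$val)
}

local_minima_vertices <- function(mesh, val, interior_only = FALSE) {
  nv <- nrow(mesh$V)
  T <- mesh$T
  ea <- c(T[, 1L], T[, 2L], T[, 3L])
  eb <- c(T[, 2L], T[, 3L], T[, 1L])
  i <- c(ea, eb); j <- c(eb, ea)
  has_lower <- unique(i[val[j] < val[i]])
  cand <- setdiff(seq_len(nv), has_lower)
  if (interior_only) {
    bnd <- unique(c(mesh$boundary_edges$v1, mesh$boundary_edges$v2))
    cand <- setdiff(cand, bnd)
  }
  cand
}

merge_extrema <- function(xy, val, radius, deepest = TRUE) {
  if (nrow(xy) == 0L) return(list(xy = xy, val = val))
  ord <- order(val, decreasing = !deepest)
  xy <- xy[ord, , drop = FALSE]; val <- val[ord]
  keep <- logical(length(val))
  for (i in seq_along(val)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- which(keep)
    d2 <- (xy[prev, 1L] - xy[i, 1L])^2 + (xy[prev, 2L] - xy[i, 2L])^2
    keep[i] <- all(d2 > radius^2)
  }
  list(xy = xy[keep, , drop = FALSE], val = val[keep])
}
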