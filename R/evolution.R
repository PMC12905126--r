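#' Simulation configuration
#'
#' Collects every knob of a run. Dimensionless units throughout: lengths in
#' the initial drop radius R, time in viscocapillary units `mu R / gamma`,
#' velocity in `gamma / mu`, pressure in `gamma / R`.
#'
#' @param ca active Capillary number `Ca = alpha / (gamma / R)`; positive is
#'   extensile, negative contractile.
#' @param anchoring an [anchoring_spec()] or [anchoring_schedule()].
#' @param nematic_model `"director"` (polar boundary data, componentwise
#'   harmonic bulk field) or `"qtensor"` (Landau-de Gennes).
#' @param h_mesh target mesh edge length (also sets the interface node
#'   spacing).
#' @param n_interface number of interface nodes; default `ceiling(pi/h) + 1`.
#' @param dt_max largest admissible time step. The default `0.5 * h_mesh`
#'   respects the explicit capillary stability limit, which scales with the
#'   interface node spacing.
#' @param cfl_factor advective step fraction in `(0, 1]`.
#' @param t_end final time.
#' @param steady_tol steady-state tolerance (relative `|u|_max` drift per
#'   unit time and maximum interface normal speed).
#' @param landau list with `a`, `b`, `K_Q` for the Q-tensor model.
#' @param mesh_seed integer seed for the deterministic mesh lattice jitter.
#' @param cadence diagnostics output interval.
#' @param traction `"curvature"` or `"laplace_beltrami"` capillary assembly.
#' @param area_projection enforce exact area conservation by a uniform
#'   normal correction each step (the discrete normal motion conserves area
#'   only to truncation error).
#' @param normalize_director renormalise the bulk director (sensitivity
#'   studies; default off, matching the quasi-static harmonic model).
#' @param remesh_disp_factor rebuild the mesh after the interface has moved
#'   this many `h_mesh` since the last build (between rebuilds the mesh
#'   follows the interface by harmonic deformation).
#' @param pin_guard_deg opening angle (degrees) of the exclusion wedge at
#'   each pinned contact point. The interface may overhang above the
#'   substrate but must not wet it beyond the pins; without the wedge,
#'   strongly spreading drops push nodes onto the wall and crawl outwards,
#'   which amounts to depinning.
#' @param min_angle mesh quality floor in degrees.
#' @param stop_when_steady stop once the steady-state detector has fired
#'   (and no anchoring switch is pending).
#' @param fast_forward_steady once steady and a switch is pending, advance
#'   time to the switch directly (the state is a fixed point to tolerance).
#' @param record_censuses include vortex and defect counts in the records
#'   (costs one Poisson solve per record).
#' @param verbose print progress.
#' @return a `sim_config` object.
#' @export
sim_config <- function(ca = 0,
                       anchoring = anchoring_spec(0L, 0L),
                       nematic_model = c("director", "qtensor"),
                       h_mesh = 0.05,
                       n_interface = NULL,
                       dt_max = NULL,
                       cfl_factor = 0.5,
                       t_end = 50,
                       steady_tol = 1e-3,
                       landau = list(a = 1, b = 2, K_Q = 2.5e-3),
                       mesh_seed = 1L,
                       cadence = 0.25,
                       traction = c("curvature", "laplace_beltrami"),
                       area_projection = TRUE,
                       normalize_director = FALSE,
                       remesh_disp_factor = 2,
                       pin_guard_deg = 60,
                       min_angle = 15,
                       stop_when_steady = TRUE,
                       fast_forward_steady = TRUE,
                       record_censuses = TRUE,
                       verbose = FALSE) {
  nematic_model <- match.arg(nematic_model)
  traction <- match.arg(traction)
  if (!(inherits(anchoring, "anchoring_spec") ||
        inherits(anchoring, "anchoring_schedule"))) {
    stop("`anchoring` must be an anchoring_spec or anchoring_schedule")
  }
  if (is.null(n_interface)) n_interface <- max(17L, ceiling(pi / h_mesh) + 1L)
  if (is.null(dt_max)) dt_max <- 0.5 * h_mesh
  if (!(dt_max > 0)) stop("`dt_max` must be positive")
  if (!(cfl_factor > 0 && cfl_factor <= 1)) stop("`cfl_factor` must be in (0, 1]")
  if (!(steady_tol > 0)) stop("`steady_tol` must be positive")
  structure(list(
    ca = ca, anchoring = anchoring, nematic_model = nematic_model,
    h_mesh = h_mesh, n_interface = as.integer(n_interface),
    dt_max = dt_max, cfl_factor = cfl_factor, t_end = t_end,
    steady_tol = steady_tol, landau = landau,
    mesh_seed = as.integer(mesh_seed), cadence = cadence,
    traction = traction, area_projection = area_projection,
    normalize_director = normalize_director,
    remesh_disp_factor = remesh_disp_factor,
    pin_guard_deg = pin_guard_deg, min_angle = min_angle,
    stop_when_steady = stop_when_steady,
    fast_forward_steady = fast_forward_steady,
    record_censuses = record_censuses, verbose = verbose),
    class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  anc <- anchoring_at(x$anchoring, 0)
  cat(sprintf("<sim_config: Ca = %g, w_s = %d, w_i(0) = %d, model = %s, h = %g, t_end = %g>\n",
              x$ca, anc$w_s, anc$w_i, x$nematic_model, x$h_mesh, x$t_end))
  invisible(x)
}

#' Time-dependent interfacial anchoring schedule
#'
#' Piecewise-constant interfacial winding number: `w_i` takes value
#' `w_i_values[k]` on `[times[k], times[k+1])`. The substrate anchoring is
#' fixed. Switch times must be strictly increasing and start at 0.
#'
#' @param w_s fixed substrate winding number.
#' @param times switch times (first must be 0).
#' @param w_i_values interfacial winding numbers, same length as `times`.
#' @return an `anchoring_schedule`.
#' @export
anchoring_schedule <- function(w_s, times, w_i_values) {
  if (length(times) != length(w_i_values) || length(times) < 1L) {
    stop("`times` and `w_i_values` must have equal positive length")
  }
  if (times[1L] != 0) stop("the first schedule entry must be at t = 0")
  if (any(diff(times) <= 0)) stop("switch times must be strictly increasing")
  structure(list(w_s = as.integer(w_s), times = as.numeric(times),
                 w_i = as.integer(w_i_values)),
            class = "anchoring_schedule")
}

#' Resolve the anchoring at a given time
#' @param anchoring an `anchoring_spec` or `anchoring_schedule`.
#' @param t time.
#' @return an `anchoring_spec`.
#' @export
anchoring_at <- function(anchoring, t) {
  if (inherits(anchoring, "anchoring_spec")) return(anchoring)
  k <- findInterval(t + 1e-12, anchoring$times)
  anchoring_spec(anchoring$w_s, anchoring$w_i[max(k, 1L)])
}

schedule_switch_times <- function(anchoring) {
  if (inherits(anchoring, "anchoring_spec")) return(numeric(0))
  anchoring$times[-1L]
}

# solve the quasi-static fields on the current geometry; where the interface
# rests on the pinned-corner wedge, iterate the contact set once so that
# only compressive contacts stay constrained
solve_fields <- function(curve, mesh, config, anc) {
  if (config$nematic_model == "director") {
    bc <- boundary_director(mesh, curve, anc)
    nem <- solve_director(mesh, bc, normalize = config$normalize_director)
  } else {
    L <- config$landau
    bc <- boundary_qtensor(mesh, curve, anc, S_max = sqrt(2 * L$a / L$b))
    nem <- solve_qtensor(mesh, bc, a = L$a, b = L$b, K_Q = L$K_Q)
  }
  contact <- detect_contact(mesh, config$pin_guard_deg)
  flow <- solve_stokes(mesh, curve, nem, ca = config$ca,
                       traction = config$traction, contact = contact)
  if (!is.null(contact)) {
    ifc <- mesh$interface_chain
    s <- rowSums(flow$u[ifc[contact$nodes], , drop = FALSE] *
                   contact$normal[contact$nodes, , drop = FALSE])
    adhesive <- s < -1e-8
    if (any(adhesive)) {
      contact$nodes <- contact$nodes[!adhesive]
      flow <- solve_stokes(mesh, curve, nem, ca = config$ca,
                           traction = config$traction,
                           contact = if (length(contact$nodes) > 1L) contact)
    }
  }
  list(nematic = nem, flow = flow)
}

# Interface chain vertices resting on the pinned-corner exclusion wedge,
# with the unit normal pointing into the excluded region. The guard projects
# violating nodes exactly onto the wedge edge, so a tight band suffices and
# keeps the contact set stable across remeshes.
detect_contact <- function(mesh, deg, band = 1e-4) {
  th <- deg * pi / 180
  X <- mesh$V[mesh$interface_chain, , drop = FALSE]
  nrm <- matrix(0, nrow(X), 2L)
  left <- X[, 1L] < -1e-9 & (X[, 2L] + X[, 1L] * tan(th)) < band
  right <- X[, 1L] > 2 + 1e-9 & (X[, 2L] - (X[, 1L] - 2) * tan(th)) < band
  if (any(left)) {
    nrm[left, ] <- matrix(c(-sin(th), -cos(th)), sum(left), 2L, byrow = TRUE)
  }
  if (any(right)) {
    nrm[right, ] <- matrix(c(sin(th), -cos(th)), sum(right), 2L, byrow = TRUE)
  }
  nodes <- which(left | right)
  if (length(nodes) < 2L) return(NULL)
  list(nodes = nodes, normal = nrm)
}

#' Advance the interface by one explicit time step
#'
#' One quasi-static cycle: resolve the anchoring at time `t`, reuse or
#' rebuild the mesh, solve the nematic and Stokes problems, move each
#' interface node by `dt (u . n) n` (normal-only motion; tangential motion
#' is a reparameterisation absorbed by [redistribute()]), keep the contact
#' nodes pinned, optionally project the area, and redistribute.
#'
#' @param curve current `interface_curve`.
#' @param config a [sim_config()].
#' @param t current time.
#' @param state internal carry-over (mesh and accumulators) from the
#'   previous step; pass `NULL` to start.
#' @param dt_limit upper bound on the step (used to land exactly on
#'   anchoring switches, record times, and `t_end`).
#' @return list with `curve`, `flow`, `nematic`, `mesh`, `dt`, `un` (nodal
#'   normal speeds of the flow), `un_eff` (actual nodal normal motion per
#'   unit time after the pinning constraint and area projection),
#'   `area_move` (polygon area right after the normal move) and the updated
#'   `state`.
#' @export
drop_step <- function(curve, config, t, state = NULL, dt_limit = Inf) {
  if (is.null(state)) {
    state <- list(mesh = NULL, disp = 0, area0 = enclosed_area(curve),
                  warned_thin = FALSE)
  }
  anc <- anchoring_at(config$anchoring, t)

  mesh <- state$mesh
  rebuild <- is.null(mesh)
  if (!rebuild) {
    mesh <- deform_mesh(mesh, curve)
    if (state$disp > config$remesh_disp_factor * config$h_mesh ||
        mesh_min_angle(mesh$V, mesh$T) < config$min_angle) rebuild <- TRUE
  }
  if (rebuild) {
    mesh <- build_mesh(curve, config$h_mesh, seed = config$mesh_seed,
                       min_angle = config$min_angle)
    state$disp <- 0
  }

  fields <- solve_fields(curve, mesh, config, anc)
  flow <- fields$flow

  # flux-projected nodal normal velocity on the interface (conserves the
  # enclosed area to geometric truncation error)
  fr <- frame_and_curvature(curve)
  uv <- flow$u[mesh$curve_vertex_ids, , drop = FALSE]
  un <- interface_normal_speed(mesh, flow, curve)
  sp <- sqrt(rowSums(uv^2))
  ds <- stats::median(diff(curve$s))
  umax <- max(sp, config$cfl_factor * ds / config$dt_max)
  dt <- min(config$dt_max, config$cfl_factor * ds / umax, dt_limit)

  n <- nrow(curve$nodes)
  new_nodes <- curve$nodes + dt * un * fr$n
  new_nodes[1L, ] <- c(0, 0)
  new_nodes[n, ] <- c(2, 0)
  new_nodes <- pin_guard(new_nodes, config$pin_guard_deg)

  area_move <- abs(polygon_signed_area(new_nodes))
  if (config$area_projection) {
    for (pass in 1:2) {
      A <- abs(polygon_signed_area(new_nodes))
      L <- sum(sqrt(rowSums(diff(new_nodes)^2)))
      delta <- (state$area0 - A) / L
      new_nodes[2:(n - 1L), ] <- new_nodes[2:(n - 1L), ] + delta * fr$n[2:(n - 1L), ]
      new_nodes <- pin_guard(new_nodes, config$pin_guard_deg)
    }
  }

  # effective interface normal speed: actual node motion per unit time after
  # the pinning constraint (the flow may press against the exclusion wedge
  # at a constrained equilibrium; the interface itself is then stationary)
  un_eff <- rowSums((new_nodes - curve$nodes) * fr$n) / dt

  new_nodes <- excise_loops(new_nodes)
  bad <- polyline_self_intersection(new_nodes)
  if (!is.null(bad)) {
    stop(sprintf(paste0("interface self-intersection after move at t = %.4f ",
                        "(segments %d and %d); state: Ca = %g, w_s = %d, w_i = %d"),
                 t, bad[1L], bad[2L], config$ca, anc$w_s, anc$w_i))
  }
  new_curve <- redistribute(interface_curve(new_nodes, check = FALSE),
                            n = nrow(curve$nodes))

  # thin-film resolution warning (the mesh size field already follows the gap)
  hmin <- min_film_height(new_curve)
  if (!state$warned_thin && hmin < 2 * config$h_mesh && hmin > 0) {
    warning(sprintf("interface height %.3g below 2*h_mesh at t = %.3f; mesh is refined locally to follow the film", hmin, t))
    state$warned_thin <- TRUE
  }

  state$mesh <- mesh
  state$disp <- state$disp + dt * max(abs(un))
  list(curve = new_curve, flow = flow, nematic = fields$nematic, mesh = mesh,
       dt = dt, un = un, un_eff = un_eff, area_move = area_move, state = state)
}

# The contact line stays pinned: the interface may overhang above the
# substrate but must not wet it beyond the pins. Nodes falling into the
# exclusion wedge (opening angle `deg` from the wall, hinged at each contact
# point) are projected perpendicularly back onto the wedge edge; overhangs
# above the wedge (mushroom caps) are untouched.
pin_guard <- function(nodes, deg = 15) {
  n <- nrow(nodes)
  th <- deg * pi / 180
  idx <- 2:(n - 1L)
  x <- nodes[idx, 1L]; y <- nodes[idx, 2L]
  y <- pmax(y, 1e-12)
  # left pin: wedge between the outward wall direction (-1, 0) and the edge
  # direction (-cos th, sin th)
  out <- x < 0 & y < -x * tan(th)
  if (any(out)) {
    e <- c(-cos(th), sin(th))
    proj <- pmax(x[out] * e[1L] + y[out] * e[2L], 0)
    x[out] <- proj * e[1L]
    y[out] <- proj * e[2L] + 1e-12
  }
  out <- x > 2 & y < (x - 2) * tan(th)
  if (any(out)) {
    e <- c(cos(th), sin(th))
    proj <- pmax((x[out] - 2) * e[1L] + y[out] * e[2L], 0)
    x[out] <- 2 + proj * e[1L]
    y[out] <- proj * e[2L] + 1e-12
  }
  nodes[idx, 1L] <- x
  nodes[idx, 2L] <- y
  nodes
}

# Excise small self-intersection loops near the interface ends (folds thrown
# up where the pin guard blocks wall-wetting); larger crossings still abort.
excise_loops <- function(nodes, max_span = 8L) {
  for (pass in 1:4) {
    bad <- polyline_self_intersection(nodes)
    if (is.null(bad)) return(nodes)
    if (bad[2L] - bad[1L] > max_span) return(nodes)
    a1 <- nodes[bad[1L], ]; a2 <- nodes[bad[1L] + 1L, ]
    b1 <- nodes[bad[2L], ]; b2 <- nodes[bad[2L] + 1L, ]
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    tpar <- ((b1[1L] - a1[1L]) * d2[2L] - (b1[2L] - a1[2L]) * d2[1L]) / den
    pint <- a1 + tpar * d1
    nodes <- rbind(nodes[seq_len(bad[1L]), , drop = FALSE], pint,
                   nodes[(bad[2L] + 1L):nrow(nodes), , drop = FALSE])
  }
  nodes
}

# smallest interface height over the central part of the footprint,
# used for film/pinch-off detection
min_film_height <- function(curve, x_range = c(0.3, 1.7)) {
  p <- curve$nodes
  sel <- p[, 1L] > x_range[1L] & p[, 1L] < x_range[2L]
  if (!any(sel)) return(Inf)
  min(p[sel, 2L])
}

#' Run a drop simulation to steady state or `t_end`
#'
#' Integrates the interface from the semicircular rest state (`u = 0`,
#' `P = 1` initially) under the quasi-static nematic Stokes flow, emitting a
#' diagnostics record every `cadence` time units. Anchoring switches in a
#' schedule are hit exactly (the step is clamped); the steady-state detector
#' is restarted after each switch. Deterministic given the configuration.
#'
#' @param config a [sim_config()].
#' @param init_curve optional initial `interface_curve` (default: the
#'   semicircle at the configured resolution).
#' @return a `drop_run` with `records` (one row per diagnostics sample),
#'   `phases` (per anchoring phase: start, w_i, steady detection time),
#'   final `curve`, `mesh`, `flow`, `nematic`, the `config`, and `status`.
#' @export
simulate_drop <- function(config, init_curve = NULL) {
  stopifnot(inherits(config, "sim_config"))
  curve <- if (is.null(init_curve)) initial_semicircle(config$n_interface) else init_curve
  t <- 0
  state <- NULL
  switches <- schedule_switch_times(config$anchoring)
  switches <- switches[switches <= config$t_end]
  next_record <- 0
  records <- list()
  status <- "t_end"
  phase_start <- 0
  phases <- data.frame(t_start = 0,
                       w_i = anchoring_at(config$anchoring, 0)$w_i,
                       steady_time = NA_real_)
  last <- NULL

  add_record <- function(t, curve, res) {
    er <- entropy_rates(res$flow, res$nematic, config$ca, res$mesh)
    nv <- nd <- NA_integer_
    if (config$record_censuses) {
      psi <- streamfunction(res$flow, res$mesh)
      nv <- vortex_census(psi, res$mesh)$count
      if (inherits(res$nematic, "director_field")) {
        nd <- nrow(defect_census(res$nematic, res$mesh))
      }
    }
    data.frame(t = t,
               u_max = max_speed(res$flow),
               normal_speed_max = max(abs(res$un_eff)),
               area = enclosed_area(curve),
               asymmetry = mirror_asymmetry(curve),
               s_dot_v = er$s_dot_v, s_dot_a = er$s_dot_a,
               s_dot_tot = er$s_dot_tot,
               n_vortices = nv, n_defects = nd,
               w_i = anchoring_at(config$anchoring, t)$w_i,
               dt = res$dt)
  }

  open_phase <- function(t) {
    if (config$verbose) message(sprintf("t = %.3f: anchoring switch", t))
    phases <<- rbind(phases, data.frame(
      t_start = t, w_i = anchoring_at(config$anchoring, t)$w_i,
      steady_time = NA_real_))
    phase_start <<- t
  }

  repeat {
    t_stop <- min(config$t_end, if (length(switches)) switches[1L] else Inf)
    res <- drop_step(curve, config, t, state, dt_limit = t_stop - t)
    state <- res$state
    if (t >= next_record - 1e-9) {
      records[[length(records) + 1L]] <- add_record(t, curve, res)
      next_record <- next_record + config$cadence
    }
    last <- res
    curve <- res$curve
    t <- t + res$dt

    # event handling -------------------------------------------------------
    recdf <- do.call(rbind, records)
    phase_rows <- recdf[recdf$t >= phase_start - 1e-9, , drop = FALSE]
    tstar <- steady_state_time(phase_rows, tol = config$steady_tol)
    phases$steady_time[nrow(phases)] <- tstar

    if (min_film_height(curve) < 0.25 * config$h_mesh) {
      status <- "pinchoff"
      break
    }
    if (length(switches) && t >= switches[1L] - 1e-9) {
      switches <- switches[-1L]
      open_phase(t)
      next
    }
    if (t >= config$t_end - 1e-9) { status <- "t_end"; break }
    if (!is.na(tstar)) {
      if (length(switches) == 0L) {
        if (config$stop_when_steady) { status <- "steady"; break }
      } else if (config$fast_forward_steady && switches[1L] - t > config$cadence) {
        # the state is a fixed point to tolerance: replay it up to the switch
        while (next_record < switches[1L] - 1e-9) {
          rec <- records[[length(records)]]
          rec$t <- next_record
          records[[length(records) + 1L]] <- rec
          next_record <- next_record + config$cadence
        }
        t <- switches[1L]
        switches <- switches[-1L]
        open_phase(t)
      }
    }
    if (config$verbose && length(records) %% 20L == 0L) {
      message(sprintf("t = %.3f  |u|max = %.4f  dt = %.4g", t,
                      max_speed(res$flow), res$dt))
    }
  }

  records[[length(records) + 1L]] <- add_record(t, curve, last)
  recdf <- do.call(rbind, records)
  phase_rows <- recdf[recdf$t >= phase_start, , drop = FALSE]
  phases$steady_time[nrow(phases)] <- steady_state_time(phase_rows,
                                                        tol = config$steady_tol)
  if (status == "t_end" && !is.na(phases$steady_time[nrow(phases)])) {
    status <- "steady"
  }
  structure(list(records = recdf, phases = phases, curve = curve,
                 mesh = last$mesh, flow = last$flow, nematic = last$nematic,
                 config = config, t_final = t, status = status),
            class = "drop_run")
}

#' First time the steady-state criterion holds
#'
#' The drop is called steady at the first sample time `t*` such that over
#' the whole window `[t*, t* + 1]` the relative drift of the maximum speed,
#' `|d|u|_max/dt| / max(|u|_max, tol)`, stays below `tol` per unit time and
#' the maximum interface normal speed stays below `tol`.
#'
#' @param records data.frame with columns `t`, `u_max`, `normal_speed_max`
#'   (as produced by [simulate_drop()]).
#' @param tol tolerance (default `1e-3`).
#' @return the detection time, or `NA` if the criterion never holds.
#' @export
steady_state_time <- function(records, tol = 1e-3) {
  if (is.null(records) || nrow(records) < 2L) return(NA_real_)
  t <- records$t
  u <- records$u_max
  ns <- records$normal_speed_max
  n <- length(t)
  dudt <- c(diff(u) / pmax(diff(t), 1e-12), 0)
  rel <- abs(dudt) / pmax(u, tol)
  ok <- rel < tol & ns < tol
  ok[n] <- ns[n] < tol  # no forward difference at the last sample
  for (i in seq_len(n)) {
    if (t[i] + 1 > t[n] + 1e-9) break
    win <- which(t >= t[i] - 1e-9 & t <= t[i] + 1 + 1e-9)
    if (all(ok[win[-length(win)]]) && ns[win[length(win)]] < tol) {
      return(t[i])
    }
  }
  NA_real_
}

#' Continue a finished run with a new interfacial winding number
#'
#' Switches the anchoring discontinuously and keeps integrating from the
#' run's final shape; the nematic and flow are recomputed quasi-statically
#' from the geometry (the interface shape is the only state).
#'
#' @param run a `drop_run`.
#' @param new_w_i new interfacial winding number.
#' @param t_end additional integration horizon (absolute time).
#' @return a new `drop_run` starting at the switched configuration (its
#'   `records$t` restart at 0 at the switch).
#' @export
apply_schedule_switch <- function(run, new_w_i, t_end = 20) {
  anc0 <- anchoring_at(run$config$anchoring, run$t_final)
  cfg <- run$config
  cfg$anchoring <- anchoring_spec(anc0$w_s, new_w_i)
  cfg$t_end <- t_end
  simulate_drop(cfg, init_curve = run$curve)
}

#' @exportS3Method base::print
print.drop_run <- function(x, ...) {
  cat(sprintf("<drop_run: Ca = %g, %d records to t = %.3f, status = %s>\n",
              x$config$ca, nrow(x$records), x$t_final, x$status))
  st <- x$phases$steady_time
  for (i in seq_len(nrow(x$phases))) {
    cat(sprintf("  phase %d (w_i = %d, from t = %.2f): steady at %s\n",
                i, x$phases$w_i[i], x$phases$t_start[i],
                if (is.na(st[i])) "-" else sprintf("%.2f", st[i])))
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.drop_run <- function(object, ...) {
  r <- object$records
  n <- nrow(r)
  cat(sprintf("Drop run: Ca = %g, model = %s, h = %g\n", object$config$ca,
              object$config$nematic_model, object$config$h_mesh))
  cat(sprintf("  final time %.3f (%s); |u|_max = %.4f; area drift %.3g%%\n",
              object$t_final, object$status, r$u_max[n],
              100 * abs(r$area[n] - r$area[1L]) / r$area[1L]))
  cat(sprintf("  morphology: %s; asymmetry %.4f; vortices %s; defects %s\n",
              classify_morphology(object$curve), r$asymmetry[n],
              r$n_vortices[n], r$n_defects[n]))
  invisible(object)
}

#' @exportS3Method
plot.drop_run <- function(x, which = c("shape", "history"), ...) {
  which <- match.arg(which)
  if (which == "shape") {
    p <- x$curve$nodes
    plot(p[, 1L], p[, 2L], type = "l", asp = 1, xlab = "x", ylab = "y",
         main = sprintf("Ca = %g, final shape", x$config$ca), ...)
    graphics::segments(0, 0, 2, 0, lwd = 2)
  } else {
    r <- x$records
    plot(r$t, r$u_max, type = "l", xlab = "t", ylab = expression(abs(u)[max]),
         main = "maximum speed", ...)
  }
  invisible(x)
}
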