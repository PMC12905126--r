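# Structured outputs: VTK snapshots, CSV time series, config files, manifests.

#' Write the interface polyline as CSV
#'
#' Columns: arclength `s`, `x`, `y`, curvature `C`.
#'
#' @param curve an `interface_curve`.
#' @param path output file.
#' @export
write_interface_csv <- function(curve, path) {
  fr <- frame_and_curvature(curve)
  utils::write.csv(data.frame(s = curve$s, x = curve$nodes[, 1L],
                              y = curve$nodes[, 2L], C = fr$C),
                   path, row.names = FALSE)
}

#' Read an interface CSV back into a curve
#' @param path file written by [write_interface_csv()].
#' @return an `interface_curve`.
#' @export
read_interface_csv <- function(path) {
  d <- utils::read.csv(path)
  interface_curve(cbind(d$x, d$y), check = FALSE)
}

#' Write a mesh snapshot with fields as a legacy-ASCII VTK unstructured grid
#'
#' Vertex fields written as POINT_DATA: `director` (vector), `velocity`
#' (vector, vertex part of the P2 solution), `pressure`, `streamfunction`,
#' `vorticity`, and for the Q-tensor model `Qxx`, `Qxy`, `S`.
#'
#' @param mesh a `drop_mesh`.
#' @param path output `.vtk` file.
#' @param nematic optional `director_field` or `q_field`.
#' @param flow optional `flow_state`.
#' @export
write_vtk <- function(mesh, path, nematic = NULL, flow = NULL) {
  V <- mesh$V; T <- mesh$T
  nv <- nrow(V); nt <- nrow(T)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("active drop snapshot")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", nv))
  writeLines(sprintf("%.10g %.10g 0", V[, 1L], V[, 2L]), con)
  wl(sprintf("CELLS %d %d", nt, 4L * nt))
  writeLines(sprintf("3 %d %d %d", T[, 1L] - 1L, T[, 2L] - 1L, T[, 3L] - 1L), con)
  wl(sprintf("CELL_TYPES %d", nt))
  writeLines(rep("5", nt), con)
  wl(sprintf("POINT_DATA %d", nv))
  wvec <- function(name, m) {
    wl(sprintf("VECTORS %s double", name))
    writeLines(sprintf("%.10g %.10g 0", m[, 1L], m[, 2L]), con)
  }
  wscal <- function(name, v) {
    wl(sprintf("SCALARS %s double 1", name))
    wl("LOOKUP_TABLE default")
    writeLines(sprintf("%.10g", v), con)
  }
  if (inherits(nematic, "director_field")) {
    wvec("director", nematic$p)
  } else if (inherits(nematic, "q_field")) {
    wscal("Qxx", nematic$Qxx)
    wscal("Qxy", nematic$Qxy)
    wscal("S", scalar_order(nematic))
    # principal director of Q (up to sign)
    th <- atan2(nematic$Qxy, nematic$Qxx) / 2
    wvec("director", cbind(cos(th), sin(th)))
  }
  if (!is.null(flow)) {
    wvec("velocity", flow$u[seq_len(nv), , drop = FALSE])
    wscal("pressure", flow$pressure)
    psi <- streamfunction(flow, mesh)
    wscal("streamfunction", psi)
    wscal("vorticity", vertex_vorticity(flow, mesh))
  }
  invisible(path)
}

# lumped-mass L2 projection of the vorticity onto the vertices
vertex_vorticity <- function(state, mesh) {
  g <- tri_geometry(mesh$V, mesh$T)
  quad <- tri_quadrature()
  T2 <- state$p2$T2
  nv <- nrow(mesh$V)
  num <- numeric(nv)
  for (q in seq_along(quad$w)) {
    gq <- p2_gradients(g, quad$lambda[q, ])
    om <- numeric(nrow(T2))
    for (b in 1:6) {
      om <- om + gq$GX[, b] * state$u[T2[, b], 2L] -
        gq$GY[, b] * state$u[T2[, b], 1L]
    }
    wq <- quad$w[q] * g$area
    for (cc in 1:3) {
      num <- num + accumulate_at(mesh$T[, cc], wq * quad$lambda[q, cc] * om, nv)
    }
  }
  num / p1_lumped_mass(mesh$V, mesh$T)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` comments; dotted keys address nested
#' entries (`landau.a = 1`). Keys must match [sim_config()] arguments
#' (`anchoring.w_s`, `anchoring.w_i` set a fixed anchoring;
#' `schedule.times` / `schedule.w_i` a comma-separated schedule).
#'
#' @param path config file.
#' @param overrides named list applied on top of the file values.
#' @return a `sim_config`.
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("malformed config line: ", ln)
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    kv[[key]] <- val
  }
  for (nm in names(overrides)) kv[[nm]] <- overrides[[nm]]
  build_config_from_kv(kv)
}

build_config_from_kv <- function(kv) {
  num <- function(x) as.numeric(strsplit(x, ",")[[1L]])
  args <- list()
  known <- c("ca", "nematic_model", "h_mesh", "n_interface", "dt_max",
             "cfl_factor", "t_end", "steady_tol", "mesh_seed", "cadence",
             "traction", "area_projection", "normalize_director",
             "remesh_disp_factor", "min_angle", "stop_when_steady",
             "fast_forward_steady", "record_censuses", "verbose",
             "anchoring.w_s", "anchoring.w_i", "schedule.times", "schedule.w_i",
             "landau.a", "landau.b", "landau.K_Q")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  landau <- list(a = 1, b = 2, K_Q = 2.5e-3)
  for (p in c("a", "b", "K_Q")) {
    k <- paste0("landau.", p)
    if (!is.null(kv[[k]])) landau[[p]] <- num(kv[[k]])
  }
  args$landau <- landau
  w_s <- if (!is.null(kv[["anchoring.w_s"]])) as.integer(kv[["anchoring.w_s"]]) else 0L
  if (!is.null(kv[["schedule.times"]])) {
    args$anchoring <- anchoring_schedule(w_s, num(kv[["schedule.times"]]),
                                         as.integer(num(kv[["schedule.w_i"]])))
  } else {
    w_i <- if (!is.null(kv[["anchoring.w_i"]])) as.integer(kv[["anchoring.w_i"]]) else 0L
    args$anchoring <- anchoring_spec(w_s, w_i)
  }
  for (k in c("ca", "h_mesh", "dt_max", "cfl_factor", "t_end", "steady_tol",
              "cadence", "remesh_disp_factor", "min_angle")) {
    if (!is.null(kv[[k]])) args[[k]] <- num(kv[[k]])
  }
  for (k in c("n_interface", "mesh_seed")) {
    if (!is.null(kv[[k]])) args[[k]] <- as.integer(kv[[k]])
  }
  for (k in c("nematic_model", "traction")) {
    if (!is.null(kv[[k]])) args[[k]] <- kv[[k]]
  }
  for (k in c("area_projection", "normalize_director", "stop_when_steady",
              "fast_forward_steady", "record_censuses", "verbose")) {
    if (!is.null(kv[[k]])) args[[k]] <- as.logical(kv[[k]])
  }
  do.call(sim_config, args)
}

config_as_list <- function(config) {
  anc <- config$anchoring
  out <- unclass(config)
  out$anchoring <- if (inherits(anc, "anchoring_spec")) {
    list(type = "fixed", w_s = anc$w_s, w_i = anc$w_i)
  } else {
    list(type = "schedule", w_s = anc$w_s, times = anc$times, w_i = anc$w_i)
  }
  out
}

#' Execute a run and write its outputs to a directory
#'
#' Writes `timeseries.csv` (one diagnostics record per row),
#' `interface.csv` (final shape), `final.vtk` (fields on the final mesh) and
#' `manifest.json` (resolved configuration, wall times, file checksums).
#' Re-running with the manifest's configuration reproduces the numeric
#' outputs bit-identically on the same platform.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return the `drop_run`, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  run <- simulate_drop(config)
  files <- c(timeseries = file.path(out_dir, "timeseries.csv"),
             interface = file.path(out_dir, "interface.csv"),
             vtk = file.path(out_dir, "final.vtk"))
  utils::write.csv(run$records, files[["timeseries"]], row.names = FALSE)
  write_interface_csv(run$curve, files[["interface"]])
  write_vtk(run$mesh, files[["vtk"]], nematic = run$nematic, flow = run$flow)
  manifest <- list(
    config = config_as_list(config),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    package_version = as.character(utils::packageVersion("activedrop")),
    status = run$status, t_final = run$t_final,
    phases = run$phases,
    files = lapply(as.list(files), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' Sweep the (Ca, anchoring) state diagram
#'
#' One run per grid point; failures are recorded and the sweep continues.
#' Results are independent of execution order (each run is self-contained).
#'
#' @param ca_values numeric vector of active Capillary numbers.
#' @param anchorings data.frame with columns `w_s`, `w_i`.
#' @param base_config `sim_config` supplying everything but `ca`/`anchoring`.
#' @param out_csv optional path for the aggregated table.
#' @return data.frame with one row per grid point: parameters, `u_max`,
#'   entropy rates, vortex count, morphology label, steady time, status.
#' @export
sweep_state_diagram <- function(ca_values, anchorings, base_config,
                                out_csv = NULL) {
  rows <- list()
  for (i in seq_len(nrow(anchorings))) {
    for (ca in ca_values) {
      cfg <- base_config
      cfg$ca <- ca
      cfg$anchoring <- anchoring_spec(anchorings$w_s[i], anchorings$w_i[i])
      res <- tryCatch(simulate_drop(cfg), error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          ca = ca, w_s = anchorings$w_s[i], w_i = anchorings$w_i[i],
          u_max = NA_real_, s_dot_v = NA_real_, s_dot_a = NA_real_,
          s_dot_tot = NA_real_, n_vortices = NA_integer_,
          asymmetry = NA_real_, morphology = NA_character_,
          steady_time = NA_real_, status = paste("error:", conditionMessage(res)))
        next
      }
      r <- res$records[nrow(res$records), ]
      rows[[length(rows) + 1L]] <- data.frame(
        ca = ca, w_s = anchorings$w_s[i], w_i = anchorings$w_i[i],
        u_max = r$u_max, s_dot_v = r$s_dot_v, s_dot_a = r$s_dot_a,
        s_dot_tot = r$s_dot_tot, n_vortices = r$n_vortices,
        asymmetry = r$asymmetry, morphology = classify_morphology(res$curve),
        steady_time = res$phases$steady_time[nrow(res$phases)],
        status = res$status)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Run a time-dependent anchoring protocol
#'
#' Convenience wrapper: runs [simulate_drop()] with an
#' [anchoring_schedule()] and returns per-phase summaries alongside the run
#' (the asymmetry and `|u|_max` time series live in `run$records`).
#'
#' @param schedule an `anchoring_schedule`.
#' @param config a `sim_config` (its `anchoring` is replaced).
#' @param out_dir optional output directory (same files as
#'   [run_simulation()]).
#' @return list with the `drop_run` and a `phases` data.frame augmented with
#'   the steady shape classification per phase.
#' @export
run_protocol <- function(schedule, config, out_dir = NULL) {
  stopifnot(inherits(schedule, "anchoring_schedule"))
  if (any(schedule_switch_times(schedule) > config$t_end)) {
    stop("schedule switch times beyond t_end")
  }
  cfg <- config
  cfg$anchoring <- schedule
  run <- if (is.null(out_dir)) simulate_drop(cfg) else run_simulation(cfg, out_dir)
  list(run = run, phases = run$phases)
}
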