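# Shared fixtures, built once per test session. Meshes are deterministic
# (fixed seed), so caching them does not couple tests.
.fixtures <- new.env(parent = emptyenv())

semi_mesh <- function(h = 0.1, n = 32L) {
  key <- sprintf("mesh_%g_%d", h, n)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_mesh(initial_semicircle(n), h)
  }
  .fixtures[[key]]
}

director_on <- function(mesh, curve, w_s, w_i) {
  solve_director(mesh, boundary_director(mesh, curve, anchoring_spec(w_s, w_i)))
}

# flow_state with a prescribed velocity field (for diagnostics oracles)
fake_flow <- function(mesh, ufun) {
  p2 <- activedrop:::p2_connectivity(mesh)
  X <- p2$X
  structure(list(u = ufun(X[, 1L], X[, 2L]),
                 pressure = numeric(nrow(mesh$V)), p2 = p2, ca = 0),
            class = "flow_state")
}

const_director <- function(mesh, px, py) {
  structure(list(p = cbind(rep(px, nrow(mesh$V)), rep(py, nrow(mesh$V))),
                 normalize = FALSE), class = "director_field")
}

# short coarse run used by several tests
quick_run <- function(ca, w_s = 0L, w_i = 0L, h = 0.1, t_end = 6,
                      censuses = FALSE, ...) {
  cfg <- sim_config(ca = ca, anchoring = anchoring_spec(w_s, w_i),
                    h_mesh = h, t_end = t_end, record_censuses = censuses, ...)
  simulate_drop(cfg)
}
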