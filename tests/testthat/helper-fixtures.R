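# shared builders for desk-scale test configurations

desk_config <- function(n_ap2 = 25, seed = 1, duration = 3e6, ...) {
  over <- list(...)
  rates <- rate_table(
    k_cc_gated = over$k_cc_gated %||% 45.65,
    k_cc_free = over$k_cc_free %||% 0,
    k_ap2_clat = over$k_ap2_clat %||% (0.0012 * 2000),
    koff_cc = over$koff_cc %||% 30,
    koff_ap2_clat = over$koff_ap2_clat %||% 20)
  simulation_config(
    box_edge = over$box_edge %||% 500, dt = 3,
    n_clathrin = over$n_clathrin %||% 60,
    n_ap2 = n_ap2, rates = rates,
    duration = duration,
    frame_interval = over$frame_interval %||% 5e4,
    seed = seed,
    reaction_radius = over$reaction_radius %||% 2.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force transitive closure: independent oracle for connected components
brute_force_components <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  diag(adj) <- TRUE
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      adj[edges[k, 1], edges[k, 2]] <- TRUE
      adj[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  comp
}

# shoelace polygon area for the hull oracle
shoelace_area <- function(xy) {
  k <- nrow(xy)
  i2 <- c(2:k, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}
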