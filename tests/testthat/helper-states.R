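# Builders for small hand-made lattice states, and an independent
# brute-force Hamiltonian used as the oracle for the incremental energy
# kernel. The oracle recomputes everything from the raw grid and parameter
# vectors; it shares no code with the engine.

# state with an empty lattice and no cells
empty_state <- function(W = 20, H = 20, params = default_params()) {
  woundcpm:::new_state(as.integer(W), as.integer(H), params)
}

# paint a rectangular cell of the given type; returns its id
add_rect_cell <- function(sim, type_name, xs, ys, tvol = NULL) {
  id <- woundcpm:::new_cell_record(sim, cell_types()[[type_name]],
                                   tvol = tvol)
  sim$grid[xs, ys] <- id
  woundcpm:::resync_bookkeeping(sim)
  id
}

# independent full-Hamiltonian oracle: volume + surface (4-neighbour faces)
# + contact (8-neighbour unordered unlike pairs); no chemotaxis
oracle_H <- function(grid, type, tvol, lamv, tsurf, lams, J) {
  W <- nrow(grid); H <- ncol(grid)
  ids <- sort(unique(grid[grid > 0]))
  total <- 0
  for (id in ids) {
    mask <- grid == id
    v <- sum(mask)
    s <- 0
    for (x in seq_len(W)) for (y in seq_len(H)) {
      if (!mask[x, y]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        nx <- x + d[1]; ny <- y + d[2]
        if (nx < 1 || nx > W || ny < 1 || ny > H) next
        if (grid[nx, ny] != id) s <- s + 1
      }
    }
    total <- total + lamv[id] * (v - tvol[id])^2 + lams[id] * (s - tsurf[id])^2
  }
  ## contact: each unordered 8-neighbour pair of unlike occupants once
  for (x in seq_len(W)) for (y in seq_len(H)) {
    a <- grid[x, y]
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      nx <- x + d[1]; ny <- y + d[2]
      if (nx < 1 || nx > W || ny < 1 || ny > H) next
      b <- grid[nx, ny]
      if (a == b) next
      ta <- if (a == 0) 0L else type[a]
      tb <- if (b == 0) 0L else type[b]
      total <- total + J[ta + 1L, tb + 1L]
    }
  }
  total
}

oracle_H_state <- function(sim) {
  n <- sim$n_ids
  oracle_H(sim$grid, sim$type[seq_len(n)], sim$tvol[seq_len(n)],
           sim$lamv[seq_len(n)], sim$tsurf[seq_len(n)],
           sim$lams[seq_len(n)], sim$params$energy$J)
}

# tiny scenario used where only mechanics matter, not trajectory shape
tiny_scenario <- function(lattice = c(48L, 48L), days = 1) {
  scenario_config("healthy", lattice = lattice, days = days)
}

# cached runs shared across acceptance tests (computed once per suite run)
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

healthy_replicates_100 <- function() {
  cached_run("healthy100", lapply(1:3, function(s)
    run_simulation(scenario_config("healthy", lattice = c(100L, 100L)),
                   seed = s)$timeseries))
}
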