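# Independent oracles used by the equivalence tests. These deliberately use
# naive algorithms (27-image enumeration, depth-first search, full-state
# energy recomputation in R) so they share no code with the engine.

# brute-force periodic distance: minimum over all 27 image translations
brute_min_image <- function(p1, p2, L) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p1 - (p2 + L * c(ix, iy, iz))
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# connected-component sizes of a chain-level bond graph via recursive DFS
dfs_components <- function(n_chains, edges) {
  adj <- vector("list", n_chains)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- rep(FALSE, n_chains)
  sizes <- integer(0)
  for (s in seq_len(n_chains)) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# full-state energy recomputed in plain R from coordinates and a bond list:
# -eps_hb per registered bond plus the square-well adsorption term per bead
r_state_energy <- function(coords, bonds, np, cfg) {
  e <- -cfg$eps_hb * nrow(bonds)
  if (nrow(np) > 0) {
    np <- unname(as.matrix(np))
    for (b in seq_len(nrow(coords))) {
      for (k in seq_len(nrow(np))) {
        r <- brute_min_image(coords[b, ], as.numeric(np[k, 1:3]),
                             cfg$box_length)
        R_in <- np[k, 4] / 2
        if (r >= R_in && r < R_in + np[k, 6]) e <- e - np[k, 5]
      }
    }
  }
  unname(e)
}

# apply a proposal plus its reported bond changes to a state copy
apply_proposal <- function(state, proposal, evaluation) {
  st <- state
  st$coords[proposal$beads, ] <- proposal$new_coords
  bonds <- st$bonds
  rm_rows <- integer(0)
  if (nrow(evaluation$bonds_broken) > 0) {
    for (i in seq_len(nrow(evaluation$bonds_broken))) {
      hit <- which(bonds[, 1] == evaluation$bonds_broken[i, 1] &
                   bonds[, 2] == evaluation$bonds_broken[i, 2])
      rm_rows <- c(rm_rows, hit)
    }
  }
  if (length(rm_rows) > 0) bonds <- bonds[-rm_rows, , drop = FALSE]
  if (nrow(evaluation$bonds_formed) > 0) {
    bonds <- rbind(bonds, evaluation$bonds_formed)
  }
  st$bonds <- bonds
  st
}

# small sparse configuration used across simulator tests
tiny_config <- function(...) {
  sim_config(box_length = 15, n_chains = 4, n_relax_steps = 100,
             n_production_steps = 2000, n_analysis_steps = 1000,
             snapshot_stride = 500, n_replicates = 2, ...)
}
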