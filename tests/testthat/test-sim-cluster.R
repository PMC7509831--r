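# build a minimal state carrying only what clustering needs
cluster_state <- function(cfg, bonds) {
  n_beads <- cfg$n_chains * cfg$chain_length
  coords <- matrix(runif(3 * n_beads, 0, cfg$box_length), ncol = 3)
  structure(
    list(coords = coords, np = matrix(numeric(0), ncol = 6),
         bonds = bonds, energy = 0, step = 0L, config = cfg),
    class = "sim_state"
  )
}

test_that("no bonds means all aggregates are single chains", {
  cfg <- tiny_config()
  st <- cluster_state(cfg, matrix(integer(0), ncol = 2))
  expect_identical(cluster_chains(st), rep(1L, cfg$n_chains))
})

test_that("bond connectivity is transitive across chains", {
  cfg <- sim_config(box_length = 15, n_chains = 4, chain_length = 3,
                    n_relax_steps = 10, n_production_steps = 100,
                    n_analysis_steps = 50)
  # chains A-B and B-C bonded via bead pairs; D isolated
  bonds <- rbind(c(1L, 4L),   # chain 1 bead 1 - chain 2 bead 1
                 c(5L, 8L))   # chain 2 bead 2 - chain 3 bead 2
  st <- cluster_state(cfg, bonds)
  expect_identical(cluster_chains(st), c(3L, 1L))
})

test_that("cluster sizes match brute-force connected components on random graphs", {
  set.seed(42)
  cfg <- sim_config(box_length = 40, n_chains = 20, chain_length = 3,
                    n_relax_steps = 10, n_production_steps = 100,
                    n_analysis_steps = 50)
  for (trial in 1:100) {
    n_edges <- sample(0:25, 1)
    chain_edges <- matrix(sample.int(cfg$n_chains, 2 * n_edges,
                                     replace = TRUE),
                          ncol = 2)
    chain_edges <- chain_edges[chain_edges[, 1] != chain_edges[, 2], ,
                               drop = FALSE]
    # translate chain pairs to arbitrary bead pairs of those chains
    bead_edges <- cbind(
      (chain_edges[, 1] - 1L) * cfg$chain_length +
        sample.int(cfg$chain_length, nrow(chain_edges), replace = TRUE),
      (chain_edges[, 2] - 1L) * cfg$chain_length +
        sample.int(cfg$chain_length, nrow(chain_edges), replace = TRUE)
    )
    st <- cluster_state(cfg, bead_edges)
    expect_identical(cluster_chains(st),
                     as.integer(dfs_components(cfg$n_chains, chain_edges)))
  }
})

test_that("chains sharing a nanoparticle shell merge only when asked", {
  np <- tibble::tibble(diameter = 4, adsorption_energy = 2,
                       shell_thickness = 0.5)
  cfg <- sim_config(box_length = 20, n_chains = 2, chain_length = 3,
                    nanoparticles = np, n_relax_steps = 10,
                    n_production_steps = 100, n_analysis_steps = 50)
  # nanoparticle at the centre; one bead of each chain inside its shell
  np_mat <- matrix(c(10, 10, 10, 4, 2, 0.5), nrow = 1)
  coords <- rbind(
    c(12.2, 10, 10), c(13.2, 10, 10), c(14.2, 10, 10),  # bead 1 in shell
    c(10, 12.2, 10), c(10, 13.2, 10), c(10, 14.2, 10)   # bead 4 in shell
  )
  st <- structure(
    list(coords = coords, np = np_mat,
         bonds = matrix(integer(0), ncol = 2), energy = 0, step = 0L,
         config = cfg),
    class = "sim_state"
  )
  expect_identical(cluster_chains(st, merge_np_contact = FALSE), c(1L, 1L))
  expect_identical(cluster_chains(st, merge_np_contact = TRUE), 2L)
})
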