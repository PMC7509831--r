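# helper: distance from a proposal's moved bead to a neighbour bead
prop_bond_len <- function(state, proposal, i, neighbour_bead) {
  minimum_image_distance(proposal$new_coords[i, ],
                         state$coords[neighbour_bead, ],
                         state$config$box_length)
}

only_move <- function(type) {
  w <- c(pivot = 0, crankshaft = 0, kink_jump = 0, translation = 0)
  w[type] <- 1
  w
}

test_that("smallest pivot on a 3-bead chain moves exactly one end bead", {
  cfg <- sim_config(box_length = 20, n_chains = 3, chain_length = 3,
                    move_weights = only_move("pivot"),
                    n_relax_steps = 10, n_production_steps = 100,
                    n_analysis_steps = 50)
  st <- init_system(cfg, seed = 2)
  sizes <- integer(0)
  for (seed in 1:200) {
    pr <- propose_move(st, seed = seed)
    expect_identical(pr$type, "pivot")
    expect_lte(length(pr$beads), 2)
    sizes <- c(sizes, length(pr$beads))
    if (length(pr$beads) == 1) {
      # middle-bead pivot: the single moved bead is a chain end and its bond
      # to the middle bead is preserved
      local <- (pr$beads - 1) %% cfg$chain_length
      expect_true(local %in% c(0, 2))
      mid <- pr$beads + ifelse(local == 0, 1L, -1L)
      expect_equal(prop_bond_len(st, pr, 1, mid), cfg$bond_length,
                   tolerance = 1e-9)
    }
  }
  expect_true(any(sizes == 1))
})

test_that("kink-jump preserves both adjacent bond lengths in every sample", {
  cfg <- tiny_config(move_weights = only_move("kink_jump"))
  st <- init_system(cfg, seed = 4)
  worst <- 0
  for (seed in 1:10000) {
    pr <- propose_move(st, seed = seed)
    expect_length(pr$beads, 1)
    b <- pr$beads
    d_prev <- prop_bond_len(st, pr, 1, b - 1L)
    d_next <- prop_bond_len(st, pr, 1, b + 1L)
    worst <- max(worst, abs(d_prev - cfg$bond_length),
                 abs(d_next - cfg$bond_length))
  }
  expect_lt(worst, 1e-9)
})

test_that("crankshaft rotates one interior bead preserving its bonds", {
  cfg <- tiny_config(move_weights = only_move("crankshaft"))
  st <- init_system(cfg, seed = 4)
  for (seed in 1:500) {
    pr <- propose_move(st, seed = seed)
    expect_length(pr$beads, 1)
    local <- (pr$beads - 1) %% cfg$chain_length
    expect_true(local >= 1 && local <= cfg$chain_length - 2)
    expect_equal(prop_bond_len(st, pr, 1, pr$beads - 1L), cfg$bond_length,
                 tolerance = 1e-9)
    expect_equal(prop_bond_len(st, pr, 1, pr$beads + 1L), cfg$bond_length,
                 tolerance = 1e-9)
  }
})

test_that("translation displaces the whole chain rigidly within one diameter", {
  cfg <- tiny_config(move_weights = only_move("translation"))
  st <- init_system(cfg, seed = 4)
  L <- cfg$box_length
  for (seed in 1:100) {
    pr <- propose_move(st, seed = seed)
    expect_length(pr$beads, cfg$chain_length)
    disp <- pr$new_coords - st$coords[pr$beads, ]
    disp <- disp - L * round(disp / L)
    # one shared displacement vector, each component within +/- bead_diameter
    expect_lt(max(abs(sweep(disp, 2, disp[1, ]))), 1e-9)
    expect_lte(max(abs(disp)), cfg$bead_diameter + 1e-12)
  }
})

test_that("move proposals are deterministic in the seed", {
  cfg <- tiny_config()
  st <- init_system(cfg, seed = 4)
  expect_identical(propose_move(st, seed = 123), propose_move(st, seed = 123))
})
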