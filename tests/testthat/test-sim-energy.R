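# hand-built two-chain state with exactly one bead pair inside the bond
# cutoff (beads 1 and 4 at distance 1.1), registered as a bond
crafted_state <- function() {
  cfg <- sim_config(box_length = 20, n_chains = 2, chain_length = 3,
                    n_relax_steps = 10, n_production_steps = 100,
                    n_analysis_steps = 50)
  coords <- rbind(
    c(5, 5, 5), c(6, 5, 5), c(7, 5, 5),                      # chain 1
    c(5, 6.1, 5), c(5.866, 6.6, 5), c(6.732, 7.1, 5)         # chain 2
  )
  structure(
    list(coords = coords, np = matrix(numeric(0), ncol = 6),
         bonds = matrix(c(1L, 4L), ncol = 2), energy = -cfg$eps_hb,
         step = 0L, config = cfg),
    class = "sim_state"
  )
}

test_that("a move changing nothing within cutoffs has zero energy change", {
  st <- crafted_state()
  null_prop <- list(type = "translation", chain = 2L, beads = 4:6,
                    new_coords = st$coords[4:6, ])
  ev <- evaluate_move(st, null_prop)
  expect_true(ev$feasible)
  expect_identical(ev$delta_energy, 0)
  expect_identical(nrow(ev$bonds_broken), 0L)
  expect_identical(nrow(ev$bonds_formed), 0L)
})

test_that("breaking exactly one bond with eps_hb = 4 costs +4 kT", {
  st <- crafted_state()
  away <- sweep(st$coords[4:6, ], 2, c(0, 5, 0), `+`)
  ev <- evaluate_move(st, list(type = "translation", chain = 2L,
                               beads = 4:6, new_coords = away))
  expect_true(ev$feasible)
  expect_equal(ev$delta_energy, 4)
  expect_equal(ev$bonds_broken, matrix(c(1L, 4L), ncol = 2))
  expect_identical(nrow(ev$bonds_formed), 0L)
})

test_that("overlap moves are infeasible with infinite energy change", {
  st <- crafted_state()
  onto <- st$coords[4:6, ]
  onto[1, ] <- st$coords[2, ] + c(0.3, 0, 0)  # inside bead 2's hard core
  ev <- evaluate_move(st, list(type = "translation", chain = 2L,
                               beads = 4:6, new_coords = onto))
  expect_false(ev$feasible)
  expect_identical(ev$delta_energy, Inf)
  expect_false(metropolis_accept(ev$delta_energy, u = 1e-300))
})

test_that("incremental energy change matches full recomputation on random proposals", {
  np <- tibble::tibble(diameter = c(4, 3), adsorption_energy = c(2, 1.5),
                       shell_thickness = 0.5)
  cfg <- sim_config(box_length = 12, n_chains = 30, nanoparticles = np,
                    n_relax_steps = 10, n_production_steps = 100,
                    n_analysis_steps = 50)
  st <- init_system(cfg, seed = 21)
  e_before <- r_state_energy(st$coords, st$bonds, st$np, cfg)
  expect_equal(e_before, st$energy, tolerance = 1e-10)
  n_checked <- 0
  for (seed in 1:3000) {
    if (n_checked >= 500) break
    pr <- propose_move(st, seed = seed)
    ev <- evaluate_move(st, pr)
    if (!ev$feasible) next
    n_checked <- n_checked + 1
    st2 <- apply_proposal(st, pr, ev)
    e_after <- r_state_energy(st2$coords, st2$bonds, st2$np, cfg)
    expect_equal(e_after - e_before, ev$delta_energy, tolerance = 1e-8)
  }
  expect_gte(n_checked, 500)
})

test_that("Metropolis criterion: downhill accepted, infinity rejected, e^-1 rate", {
  expect_true(all(metropolis_accept(c(-3, -0.1, 0), u = rep(1 - 1e-12, 3))))
  expect_false(metropolis_accept(Inf, u = 1e-300))
  set.seed(77)
  n <- 1e5
  acc <- metropolis_accept(rep(1, n))
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(acc) - p), 3 * se)
})
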