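test_that("non-interacting limit: no bonds ever form when eps_hb is zero", {
  cfg <- tiny_config(eps_hb = 0)
  rep_out <- run_simulation(cfg, replicate = 1)
  expect_identical(rep_out$mean_chains_per_aggregate, 1)
  expect_identical(nrow(rep_out$state$bonds), 0L)
  expect_true(all(rep_out$snapshots$n_aggregates == cfg$n_chains))
})

test_that("aggregation occurs at strong bond strength without nanoparticles", {
  cfg <- sim_config(box_length = 14, n_chains = 40, eps_hb = 4,
                    n_relax_steps = 1000, n_production_steps = 2e4,
                    n_analysis_steps = 5000, snapshot_stride = 1000)
  rep_out <- run_simulation(cfg, replicate = 1)
  expect_gt(rep_out$mean_chains_per_aggregate, 1)
})

test_that("simulation runs are deterministic in (config, seed)", {
  cfg <- tiny_config()
  a <- run_simulation(cfg, replicate = 2)
  b <- run_simulation(cfg, replicate = 2)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$state$coords, b$state$coords)
  expect_identical(a$state$bonds, b$state$bonds)
  expect_identical(a$mean_chains_per_aggregate, b$mean_chains_per_aggregate)
  c <- run_simulation(cfg, replicate = 3)
  expect_false(identical(a$state$coords, c$state$coords))
})

test_that("energy bookkeeping stays consistent and invariants hold after a run", {
  np <- tibble::tibble(diameter = 4, adsorption_energy = 2,
                       shell_thickness = 0.5)
  cfg <- sim_config(box_length = 12, n_chains = 25, nanoparticles = np,
                    n_relax_steps = 1000, n_production_steps = 1e4,
                    n_analysis_steps = 2000, snapshot_stride = 1000)
  # debug mode compares incremental vs recomputed energy every 1000 steps
  rep_out <- run_simulation(cfg, replicate = 1, debug_energy = TRUE)
  st <- rep_out$state
  expect_silent(check_state(st))
  expect_equal(st$energy, full_system_energy(st), tolerance = 1e-8)
  expect_equal(st$energy, r_state_energy(st$coords, st$bonds, st$np, cfg),
               tolerance = 1e-8)
})

test_that("without interactions every non-overlapping proposal is neutral", {
  cfg <- sim_config(box_length = 30, n_chains = 3, eps_hb = 0,
                    n_relax_steps = 100, n_production_steps = 2000,
                    n_analysis_steps = 1000, snapshot_stride = 500)
  st <- init_system(cfg, seed = 8)
  for (seed in 1:300) {
    ev <- evaluate_move(st, propose_move(st, seed = seed))
    if (ev$feasible) {
      # zero energy change, hence accepted with probability one
      expect_identical(ev$delta_energy, 0)
      expect_true(metropolis_accept(ev$delta_energy, u = 1 - 1e-12))
    } else {
      expect_identical(ev$delta_energy, Inf)
    }
  }
  # only intra-chain overlap rejections remain; most proposals go through
  rep_out <- run_simulation(cfg, replicate = 1)
  expect_gt(rep_out$acceptance_rate, 0.75)
})

test_that("snapshots cover the analysis window at the configured stride", {
  cfg <- tiny_config()
  rep_out <- run_simulation(cfg, replicate = 1)
  n_steps <- cfg$n_relax_steps + cfg$n_production_steps
  expect_equal(nrow(rep_out$snapshots),
               cfg$n_analysis_steps / cfg$snapshot_stride)
  expect_true(all(rep_out$snapshots$step > n_steps - cfg$n_analysis_steps))
  expect_equal(max(rep_out$snapshots$step), n_steps)
  # cluster sizes in every snapshot sum to the number of chains
  expect_true(all(vapply(rep_out$snapshots$sizes, sum, numeric(1)) ==
                    cfg$n_chains))
})
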