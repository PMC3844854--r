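# Network wiring, condition presets, and simulation determinism.

test_that("configuration enforces structural invariants", {
  expect_error(network_config(n_gp = 20, gp_fanout = 20), "smaller than n_gp")
  cfg <- network_config(condition = "parkinsonian", seed = 5)
  expect_equal(cfg$protocol$active_rate, 60)
  expect_equal(cfg$analysis_window_start, 6500)
  expect_output(print(cfg), "parkinsonian")
})

test_that("condition resolution follows the three-parameter change", {
  expect_equal(unname(apply_condition("healthy")), c(30, 0.1, 0.5))
  expect_equal(unname(apply_condition("parkinsonian")), c(60, 0.2, 1.0))
})

test_that("connectivity has exact out-degrees and no self-connections", {
  cfg <- network_config(seed = 3)
  g <- build_connectivity(cfg, seed = 3)
  out_deg <- table(g$gp_edges$pre)
  expect_true(all(out_deg == 20))
  expect_false(any(g$gp_edges$pre == g$gp_edges$post))
  # no duplicated targets per source
  expect_false(any(duplicated(g$gp_edges[, c("pre", "post")])))
  expect_equal(nrow(g$stn_edges), 50 * 2)
  expect_true(all(g$gp_edges$g_syn >= 0))
})

test_that("in-degree distribution matches uniform random target choice", {
  cfg <- network_config(seed = 1)
  indeg <- unlist(lapply(1:20, function(s) {
    g <- build_connectivity(cfg, seed = s)
    tabulate(g$gp_edges$post, nbins = 100)
  }))
  # each neuron is hit with probability 20/99 by each of 99 sources
  expect_equal(mean(indeg), 20, tolerance = 3 * sqrt(20 * (79 / 99)) /
                 sqrt(2000) / 20)
  expect_lt(abs(stats::sd(indeg) - sqrt(99 * (20 / 99) * (79 / 99))), 0.6)
})

test_that("scaling presets keep fan-outs constant", {
  cfg <- network_config(n_gp = 200, n_stn = 100, seed = 2)
  g <- build_connectivity(cfg, seed = 2)
  expect_true(all(table(g$gp_edges$pre) == 20))
  expect_equal(nrow(g$stn_edges), 200)
})

test_that("decoupled network reproduces isolated pacemaking rates", {
  cfg <- network_config(n_gp = 5, n_stn = 0, gp_fanout = 2, g_gg = 0,
                        duration = 3000, seed = 3,
                        downregulation = downregulation_params(enabled = FALSE))
  sim <- simulate_network(cfg)
  iso <- simulate_isolated(sim$population,
                          protocol = data.frame(duration = 3000, I_ext = 0))
  for (i in 1:5) {
    r_net <- sum(sim$spikes[[i]]$times > 500) / 2.5
    r_iso <- sum(iso$spikes[[i]]$times > 500) / 2.5
    expect_equal(r_net, r_iso, tolerance = 0.06)
  }
})

test_that("simulation is bit-reproducible from the master seed", {
  cfg <- network_config(n_gp = 12, n_stn = 6, gp_fanout = 3,
                        duration = 2600, seed = 17)
  a <- simulate_network(cfg)
  b <- simulate_network(cfg)
  expect_identical(lapply(a$spikes, `[[`, "times"),
                   lapply(b$spikes, `[[`, "times"))
  expect_identical(a$sub_seeds, b$sub_seeds)
  expect_identical(a$connectivity$gp_edges, b$connectivity$gp_edges)
})

test_that("trial batteries derive independent trials from one master seed", {
  cfg <- network_config(n_gp = 8, n_stn = 4, gp_fanout = 2,
                        duration = 1300, seed = 23)
  bat1 <- run_trial_battery(cfg, n_trials = 2)
  bat2 <- run_trial_battery(cfg, n_trials = 2)
  expect_identical(lapply(bat1[[1]]$spikes, `[[`, "times"),
                   lapply(bat2[[1]]$spikes, `[[`, "times"))
  # different trials use different wiring
  expect_false(identical(bat1[[1]]$connectivity$gp_edges,
                         bat1[[2]]$connectivity$gp_edges))
})

test_that("STN drive entrains network firing to the slow-wave cycle", {
  # small, strongly driven network: active-phase firing should dominate
  cfg <- network_config(n_gp = 10, n_stn = 10, gp_fanout = 2,
                        condition = "parkinsonian", duration = 5200,
                        seed = 31, g_sg = 0.4)
  sim <- simulate_network(cfg)
  ts <- unlist(lapply(sim$spikes, `[[`, "times"))
  ts <- ts[ts > 1300]
  act <- sum(ts %% 1300 < 500) / (4 * 0.5)
  ina <- sum(ts %% 1300 >= 500) / (4 * 0.8)
  expect_gt(act, ina)
})
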