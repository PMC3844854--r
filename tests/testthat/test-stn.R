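# SWA protocols and the stochastic STN spike-train generator.

test_that("protocol presets carry the stated cycle geometry and rates", {
  h <- swa_protocol("healthy")
  expect_equal(c(h$period, h$inactive_duration, h$active_duration),
               c(1300, 800, 500))
  expect_equal(c(h$inactive_rate, h$active_rate), c(0.5, 30))
  expect_equal(swa_protocol("parkinsonian")$active_rate, 60)
  b <- swa_protocol("beta")
  expect_equal(c(b$period, b$inactive_duration, b$active_duration),
               c(70, 40, 30))
  expect_error(swa_protocol("custom", period = 100, active_duration = 10,
                            inactive_duration = 50, active_rate = 1,
                            inactive_rate = 1), "must equal period")
})

test_that("slow-wave phase is anchored at active onset and periodic", {
  h <- swa_protocol("healthy")
  expect_equal(swa_phase(0, h), 0)
  expect_equal(swa_phase(1300, h), 0)
  expect_equal(swa_phase(500, h), 2 * pi * 500 / 1300)  # phase boundary
  expect_equal(swa_phase(650, h), pi)
  expect_equal(active_phase_range(h)[2], 2 * pi * 500 / 1300)
  expect_error(swa_phase(-1, h))
})

test_that("generated trains realize the per-phase target rates", {
  h <- swa_protocol("healthy")
  tr <- generate_stn_train(h, 13000, n_units = 50, seed = 42)
  pr <- rowMeans(vapply(tr, phase_rates, numeric(3), protocol = h))
  # within 5% plus two standard errors of the finite-sample count
  n_act <- pr[["active"]] * 50 * 5  # ~ spikes in active windows
  expect_lt(abs(pr[["active"]] - 30), 0.05 * 30 + 2 * 30 / sqrt(n_act))
  n_ina <- max(pr[["inactive"]] * 50 * 8, 1)
  expect_lt(abs(pr[["inactive"]] - 0.5), 0.05 * 0.5 + 2 * 0.5 / sqrt(n_ina))
  p <- swa_protocol("parkinsonian")
  trp <- generate_stn_train(p, 13000, n_units = 50, seed = 43)
  prp <- rowMeans(vapply(trp, phase_rates, numeric(3), protocol = p))
  n_act <- prp[["active"]] * 50 * 5
  expect_lt(abs(prp[["active"]] - 60), 0.05 * 60 + 2 * 60 / sqrt(n_act))
})

test_that("inter-spike intervals respect the absolute refractory period", {
  tr <- generate_stn_train(swa_protocol("parkinsonian"), 13000, n_units = 10,
                           seed = 7)
  isi <- unlist(lapply(tr, function(s) diff(s$times)))
  expect_gte(min(isi), stn_generator_params()$refractory)
})

test_that("generation is reproducible from the seed and zero rate is silent", {
  h <- swa_protocol("healthy")
  a <- generate_stn_train(h, 5200, n_units = 3, seed = 11)
  b <- generate_stn_train(h, 5200, n_units = 3, seed = 11)
  expect_identical(lapply(a, `[[`, "times"), lapply(b, `[[`, "times"))
  z <- swa_protocol("custom", period = 1300, active_duration = 500,
                    inactive_duration = 800, active_rate = 0,
                    inactive_rate = 0)
  expect_length(generate_stn_train(z, 5200, seed = 1)[[1]]$times, 0)
})

test_that("independent units are uncorrelated at short lags but share the slow rhythm", {
  h <- swa_protocol("healthy")
  tr <- generate_stn_train(h, 26000, n_units = 2, seed = 19)
  chk <- cross_check_independence(tr[[1]], tr[[2]], protocol = h)
  # short window (within active phases): flat at 1
  expect_lte(sum(chk$short$bins$normalized < chk$short$ci_lower |
                   chk$short$bins$normalized > chk$short$ci_upper), 5)
  # long window: oscillation at the protocol period, peaks well above 1
  long <- chk$long$bins
  in_phase <- abs(((long$lag + 650) %% 1300) - 650) < 200
  expect_gt(mean(long$normalized[in_phase]), 1.3)
  expect_lt(mean(long$normalized[!in_phase]), 1)
})

test_that("a train against itself shows the refractory trough at zero lag", {
  tr <- generate_stn_train(swa_protocol("parkinsonian"), 13000, n_units = 1,
                           seed = 3)[[1]]
  cg <- correlogram(tr, tr, bin_width = 1, n_bins = 10)
  zero_bins <- abs(cg$bins$lag) < 2
  expect_equal(sum(cg$bins$count[zero_bins]), 0)  # no self-pairs inside 2 ms
})
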