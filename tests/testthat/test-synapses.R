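# Double-exponential conductance synapses.

gp_syn <- synapse_params("gp_gp")
stn_syn <- synapse_params("stn_gp")

test_that("presets carry the stated time constants and condition scaling", {
  expect_equal(c(gp_syn$tau_o, gp_syn$tau_c, gp_syn$e_rev), c(5, 40, -80))
  expect_equal(c(stn_syn$tau_o, stn_syn$tau_c, stn_syn$e_rev), c(0.2, 60, 0))
  expect_equal(synapse_params("gp_gp", "parkinsonian")$g_mean, 1.0)
  expect_equal(synapse_params("gp_gp", "beta_high_inhibition")$g_mean, 3.0)
  expect_equal(synapse_params("stn_gp", "parkinsonian")$g_mean, 0.2)
  expect_equal(gp_syn$g_sd_fraction, 0.3)
})

test_that("state decays exponentially and spikes increment both variables", {
  expect_equal(synapse_rhs(list(o = 0, c = 0), gp_syn), c(do = 0, dc = 0))
  expect_equal(synapse_rhs(list(o = 1, c = 0), gp_syn)[["do"]], -0.2)
  st <- on_presynaptic_spike(list(o = 0.3, c = 0.7))
  expect_equal(c(st$o, st$c), c(1.3, 1.7))
  st2 <- on_presynaptic_spike(list(o = 0, c = 0), n = 2)
  expect_equal(c(st2$o, st2$c), c(2, 2))
})

test_that("synaptic current vanishes at the reversal potential", {
  st <- list(o = 0.2, c = 0.9)
  expect_equal(synaptic_current(st, 0.5, -80, v_post = -80), 0)
  expect_lt(synaptic_current(st, 0.5, -80, v_post = -60), 0)
  expect_equal(synaptic_current(st, 0.5, -80, -60),
               (0.9 - 0.2) * 0.5 * (-80 + 60))
})

test_that("single-spike conductance peaks at the closed-form time", {
  tstar <- synapse_peak_time(gp_syn)
  expect_equal(tstar, log(8) / (1 / 5 - 1 / 40), tolerance = 1e-12)
  expect_equal(tstar, 11.8825, tolerance = 1e-4)
  # the peak time depends only on the time constants, not on g_syn
  tt <- seq(0, 100, by = 0.01)
  fac <- synapse_peak_time(gp_syn, tt)
  expect_equal(tt[which.max(fac)], tstar, tolerance = 0.02)
  expect_true(all(fac >= 0))  # tau_o < tau_c with equal increments
  fac_stn <- synapse_peak_time(stn_syn, tt)
  expect_equal(tt[which.max(fac_stn)], synapse_peak_time(stn_syn),
               tolerance = 0.02)
})

test_that("well-separated spikes superpose linearly", {
  # Eq. is linear: o/c after spikes at t1, t2 equal the sum of single-spike
  # exponentials
  t_spk <- c(0, 30)
  t_eval <- 55
  o_sum <- sum(exp(-(t_eval - t_spk) / gp_syn$tau_o))
  c_sum <- sum(exp(-(t_eval - t_spk) / gp_syn$tau_c))
  # step the pair manually with exact exponential updates
  o <- 0; cc <- 0; t <- 0
  for (ts in c(t_spk, t_eval)) {
    o <- o * exp(-(ts - t) / gp_syn$tau_o)
    cc <- cc * exp(-(ts - t) / gp_syn$tau_c)
    t <- ts
    if (ts != t_eval) { o <- o + 1; cc <- cc + 1 }
  }
  expect_equal(o, o_sum, tolerance = 1e-12)
  expect_equal(cc, c_sum, tolerance = 1e-12)
})

test_that("unitary conductance draws are truncated Gaussian", {
  set.seed(8)
  g <- sample_unitary_conductances(1e4, gp_syn)
  expect_true(all(g >= 0))
  expect_lt(abs(mean(g) - 0.5), 3 * 0.15 / sqrt(1e4) + 1e-3)
})

test_that("a unitary inhibitory synapse gives a ~0.5 mV IPSP at -65 mV", {
  expect_equal(calibrate_unitary_ipsp(0), 0, tolerance = 1e-3)
  amp <- vapply(c(0.5, 1.5, 3), calibrate_unitary_ipsp, numeric(1))
  expect_gt(amp[1], 0.3)
  expect_lt(amp[1], 0.8)
  expect_true(all(diff(amp) > 0))  # amplitude increases with conductance
})
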