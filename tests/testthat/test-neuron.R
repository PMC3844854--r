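# Population sampling, spike detection, isolated-neuron phenomenology.

test_that("population sampling is truncated Gaussian around table means", {
  pop1 <- sample_population(1, seed = 4)
  fixed <- c("naf", "kv2", "kv3", "kv4f", "kv4s", "kcnq", "hva")
  expect_equal(unlist(pop1[1, fixed]), mean_conductances()[fixed],
               ignore_attr = TRUE)
  pop <- sample_population(1e4, seed = 4)
  expect_true(all(pop$nap >= 0) && all(pop$hcnf >= 0))
  # truncation at zero shifts the mean slightly above nominal; allow for it
  se <- 0.5 * 17.7 / sqrt(1e4)
  expect_lt(abs(mean(pop$nap) - mean(pmax(0, stats::rnorm(1e5, 17.7, 8.85)))),
            4 * se)
  expect_lt(abs(mean(pop$hcnf) - 177), 4 * 0.3 * 177 / sqrt(1e4))
  expect_identical(sample_population(50, seed = 9),
                   sample_population(50, seed = 9))
  expect_error(sample_population(0), ">= 1")
})

test_that("spike detection interpolates upward zero crossings", {
  expect_equal(detect_spikes(c(1, 2), c(-10, 10))$times, 1.5)
  expect_length(detect_spikes(seq(0, 100), rep(-60, 101))$times, 0)
  # sine crossing upward k times
  t <- seq(0, 1049.5, by = 0.5)
  v <- 30 * sin(2 * pi * t / 100)
  expect_length(detect_spikes(t, v)$times, 10)
  # downward crossings are not spikes
  expect_length(detect_spikes(c(0, 1), c(10, -10))$times, 0)
  expect_error(detect_spikes(numeric(0), numeric(0)), "empty")
  expect_error(detect_spikes(c(2, 1), c(-1, 1)), "increasing")
})

test_that("mean-parameter neuron pacemakes regularly near 22 Hz", {
  r <- quick_rate(mean_conductances(), window = 2000)
  expect_gt(r, 18)
  expect_lt(r, 28)
  # regularity: CV of ISIs is small for an unperturbed pacemaker
  res <- simulate_isolated(mean_conductances(),
                           protocol = data.frame(duration = 2500, I_ext = 0),
                           kinetics = kin)
  ts <- res$spikes[[1]]$times
  isi <- diff(ts[ts > 500])
  expect_lt(stats::sd(isi) / mean(isi), 0.05)
})

test_that("firing rate is non-decreasing in depolarizing current", {
  rates <- vapply(c(0, 100, 300, 700), function(i)
    quick_rate(mean_conductances(), I_ext = i, window = 1000), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[length(rates)], 100)  # fast driven firing is possible
})

test_that("HCN carries depolarizing current and speeds pacemaking", {
  # sign property: below the HCN reversal the current is depolarizing
  for (v in c(-90, -70, -40)) {
    i_hcn <- channel_current(chans$hcnf, c(m = 0.5), v) +
      channel_current(chans$hcns, c(m = 0.5), v)
    if (v < -30) expect_gt(i_hcn, 0) else expect_lt(i_hcn, 0)
  }
  g0 <- mean_conductances()
  g0[c("hcnf", "hcns")] <- 0
  expect_lt(quick_rate(g0), quick_rate(mean_conductances()))
})

test_that("hyperpolarization produces an HCN-dependent sag and rebound", {
  prot <- data.frame(duration = c(1000, 1000, 1500), I_ext = c(0, -300, 0))
  res <- simulate_isolated(mean_conductances(), protocol = prot,
                           kinetics = kin, record = 1, sample_dt = 0.5)
  tr <- res$traces[[1]]
  seg <- tr[tr$t > 1000 & tr$t < 2000, ]
  sag <- seg$v[nrow(seg)] - min(seg$v)
  expect_gt(sag, 3)  # prominent sag with HCN intact
  reb <- res$spikes[[1]]$times
  reb <- reb[reb > 2000][1] - 2000
  g0 <- mean_conductances()
  g0[c("hcnf", "hcns")] <- 0
  prot0 <- data.frame(duration = c(1000, 1000, 1500), I_ext = c(0, -100, 0))
  res0 <- simulate_isolated(g0, protocol = prot0, kinetics = kin,
                            record = 1, sample_dt = 0.5)
  tr0 <- res0$traces[[1]]
  seg0 <- tr0[tr0$t > 1000 & tr0$t < 2000, ]
  sag0 <- seg0$v[nrow(seg0)] - min(seg0$v)
  expect_lt(sag0, 0.5)  # sag is lost without HCN
  reb0 <- res0$spikes[[1]]$times
  reb0 <- reb0[reb0 > 2000][1] - 2000
  expect_gt(reb0, reb)  # rebound is delayed without HCN
})

test_that("spike train constructor enforces ordering and interval", {
  expect_error(spike_train(c(3, 2, 5), c(0, 10)), "increasing")
  expect_error(spike_train(c(2, 12), c(0, 10)), "outside")
  s <- spike_train(c(1, 2, 3), c(0, 10), id = "u1")
  expect_s3_class(s, "spike_train")
  expect_output(print(s), "3 spikes")
})
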