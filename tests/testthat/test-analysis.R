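# Phase categorization, firing statistics and normalized correlograms.

pr <- swa_protocol("healthy")

test_that("phase confidence is 1 for aligned spikes and 0 for antipodal pairs", {
  aligned <- spike_train(seq(100, 12800, by = 1300), c(0, 13000))
  pv <- phase_vector(aligned, pr)
  expect_equal(pv$confidence, 1, tolerance = 1e-12)
  expect_equal(pv$mean_phase, swa_phase(100, pr), tolerance = 1e-9)
  anti <- spike_train(sort(c(seq(100, 12800, by = 1300),
                             seq(750, 12800, by = 1300))), c(0, 13000))
  expect_equal(phase_vector(anti, pr)$confidence, 0, tolerance = 1e-9)
})

test_that("confidence is invariant under a global phase rotation", {
  set.seed(5)
  ts <- sort(stats::runif(60, 0, 13000))
  a <- phase_vector(spike_train(ts, c(0, 13000)), pr)
  for (shift in c(130, 325, 650)) {
    b <- phase_vector(spike_train(sort((ts + shift) %% 13000),
                                  c(0, 13000)), pr)
    expect_equal(b$confidence, a$confidence, tolerance = 1e-9)
    expect_equal((b$mean_phase - a$mean_phase) %% (2 * pi),
                 swa_phase(shift, pr), tolerance = 1e-9)
  }
})

test_that("categorization applies QU, NM and TA/TI rules in order", {
  # fewer than one spike per cycle -> QU regardless of phase locking
  few <- spike_train(seq(100, 12800, by = 1500), c(0, 13000))
  expect_equal(categorize(few, pr)$label, "QU")
  # aligned spikes in the active phase -> TA; inactive phase -> TI
  ta <- spike_train(sort(outer(seq(50, 450, by = 100),
                               seq(0, 12000, by = 1300), "+")[TRUE]),
                    c(0, 13000))
  expect_equal(categorize(ta, pr)$label, "TA")
  ti <- spike_train(sort(outer(seq(600, 1200, by = 150),
                               seq(0, 12000, by = 1300), "+")[TRUE]),
                    c(0, 13000))
  expect_equal(categorize(ti, pr)$label, "TI")
  # near-uniform spiking at a healthy rate -> NM
  nm <- spike_train(seq(10, 12990, by = 80), c(0, 13000))
  expect_equal(categorize(nm, pr)$label, "NM")
  # every neuron receives exactly one label
  for (tr in list(few, ta, ti, nm))
    expect_length(categorize(tr, pr)$label, 1)
  expect_error(categorize(nm, pr, window = c(5000, 5000)), "empty")
})

test_that("firing statistics: rate by counting, CV of inter-spike intervals", {
  per <- spike_train(seq(50, 12950, by = 100), c(0, 13000))
  fs <- firing_stats(per)
  expect_equal(fs[["rate"]], 10, tolerance = 0.01)
  expect_equal(fs[["cv"]], 0, tolerance = 1e-12)
  set.seed(2)
  poi <- poisson_train(40, 2e5)
  expect_equal(firing_stats(poi)[["cv"]], 1, tolerance = 0.05)
  two <- spike_train(c(1, 2), c(0, 10))
  expect_true(is.na(firing_stats(two)[["cv"]]))
})

test_that("correlogram counts equal exhaustive pair enumeration", {
  set.seed(31)
  a <- poisson_train(40, 1000, id = 1)  # ~40 spikes
  b <- poisson_train(35, 1000, id = 2)
  cg <- correlogram(a, b, bin_width = 5, n_bins = 12)
  # brute-force oracle: all pairwise lags, binned by hand
  lags <- as.vector(outer(b$times, a$times, "-"))
  breaks <- seq(-60, 60, by = 5)
  oracle <- as.integer(table(cut(lags[lags >= -60 & lags <= 60], breaks)))
  expect_identical(cg$bins$count, oracle)
  # auto-correlogram excludes exactly the zero-lag self-pairs
  ca <- correlogram(a, a, bin_width = 5, n_bins = 12)
  lags_a <- as.vector(outer(a$times, a$times, "-"))
  lags_a <- lags_a[abs(lags_a) > 1e-12]
  oracle_a <- as.integer(table(cut(lags_a[abs(lags_a) <= 60], breaks)))
  expect_identical(ca$bins$count, oracle_a)
})

test_that("normalized correlogram of independent Poisson trains is flat at 1", {
  set.seed(77)
  a <- poisson_train(20, 6e4, id = 1)
  b <- poisson_train(20, 6e4, id = 2)
  cg <- correlogram(a, b, bin_width = 3, n_bins = 30)
  expect_lt(abs(mean(cg$bins$normalized) - 1), 0.05)
  outside <- sum(cg$bins$normalized < cg$ci_lower |
                   cg$bins$normalized > cg$ci_upper)
  expect_lte(outside, 7)  # ~3 of 60 expected outside a 95% band
  # normalization identity X' = T X / (2 h N_A N_B)
  expect_equal(cg$bins$normalized,
               cg$T * cg$bins$count / (2 * cg$h * cg$n_a * cg$n_b))
})

test_that("a shifted copy of a train produces a peak at the shift", {
  set.seed(13)
  a <- poisson_train(30, 5000, id = 1)
  b <- spike_train(a$times + 7, c(0, 5007), id = 2)
  cg <- correlogram(a, b, bin_width = 2, n_bins = 10)
  expect_equal(cg$bins$lag[which.max(cg$bins$count)], 7)
  expect_error(correlogram(a, spike_train(numeric(0), c(0, 5000))), "empty")
})

test_that("phase histograms conserve spikes and expose group structure", {
  trains <- list(
    spike_train(sort(outer(seq(50, 450, by = 40),
                           seq(0, 12000, by = 1300), "+")[TRUE]), c(0, 13000),
                id = 1),
    spike_train(seq(10, 12990, by = 80), c(0, 13000), id = 2))
  reps <- lapply(trains, categorize, protocol = pr)
  hh <- phase_histogram(reps, trains, pr,
                        labels = vapply(reps, `[[`, "", "label"))
  for (lb in names(hh)) {
    idx <- which(vapply(reps, `[[`, "", "label") == lb)
    expect_equal(sum(hh[[lb]]$count),
                 sum(lengths(lapply(trains[idx], `[[`, "times"))))
  }
  # uniform spiking: flat histogram, tiny resultant
  unif <- hh[[reps[[2]]$label]]
  expect_lt(stats::sd(unif$count) / mean(unif$count), 0.35)
  expect_error(phase_histogram(reps, trains, pr, labels = "QU"), "no neurons")
})

test_that("group summaries average per-trial category tables", {
  # two fabricated "trials" with known composition
  fake_trial <- function(seed) {
    set.seed(seed)
    trains <- c(
      lapply(1:3, function(i) spike_train(
        sort(outer(seq(50, 450, by = 100), seq(0, 12000, by = 1300),
                   "+")[TRUE] + stats::runif(50, 0, 20)),
        c(0, 13000), id = i)),
      lapply(4:5, function(i) spike_train(seq(10 + i, 12990, by = 80),
                                          c(0, 13000), id = i)))
    structure(list(spikes = trains,
                   config = network_config(n_gp = 5, n_stn = 0, gp_fanout = 1,
                                           duration = 13000,
                                           analysis_window_start = 0)),
              class = "simulation_result")
  }
  battery <- structure(list(fake_trial(1), fake_trial(2)),
                       class = "trial_battery")
  gs <- group_summary(battery)
  ta <- gs$per_label[gs$per_label$label == "TA", ]
  expect_equal(ta$count_mean, 3)
  expect_equal(ta$pct_mean, 60)
  nm <- gs$per_label[gs$per_label$label == "NM", ]
  expect_equal(nm$count_mean, 2)
  expect_equal(gs$n_trials, 2)
  expect_length(pool_label_stat(battery, "TA", "confidence"), 6)
  # single-trial battery: s.d. fields are flagged NA
  gs1 <- group_summary(structure(list(fake_trial(1)), class = "trial_battery"))
  expect_true(all(is.na(gs1$per_label$count_sd)))
})
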