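## Analysis of simulated spike trains.
##
## Phase categorization: every spike contributes a unit phasor exp(i*theta)
## at its slow-wave phase; the resultant's argument is the neuron's mean
## firing phase and its length, normalized by the spike count, is the phase
## confidence c in [0, 1].  Neurons are labelled QU (quiet, < 1 spike per
## SWA cycle), NM (not modulated, c < 0.1), TA (mean phase in the active
## part of the cycle) or TI (mean phase in the inactive part).

#' Phase vector of a spike train
#'
#' Computes the complex resultant `omega = sum(exp(1i * theta(s)))` over
#' in-window spikes, the confidence `c = |omega| / n_spikes`, and the mean
#' phase `Arg(omega)` mapped to `[0, 2*pi)`.
#'
#' @param train a [spike_train()].
#' @param protocol a [swa_protocol()].
#' @param window length-2 analysis window `[t0, t1)`; defaults to the
#'   train's full interval.
#' @return List with `omega`, `n_spikes`, `confidence`, `mean_phase`
#'   (NA when there are no spikes).
#' @export
phase_vector <- function(train, protocol, window = train$interval) {
  ts <- train$times[train$times >= window[1] & train$times < window[2]]
  n <- length(ts)
  if (n == 0)
    return(list(omega = complex(real = 0, imaginary = 0), n_spikes = 0L,
                confidence = NA_real_, mean_phase = NA_real_))
  om <- sum(exp(1i * swa_phase(ts, protocol)))
  mp <- Arg(om) %% (2 * pi)
  list(omega = om, n_spikes = n, confidence = Mod(om) / n, mean_phase = mp)
}

#' Categorize a neuron by slow-wave phase
#'
#' Applies the categorization rules on the analysis window: neurons firing
#' fewer than one spike per SWA cycle are QU; otherwise confidence < 0.1
#' gives NM; otherwise the label is TA or TI according to whether the mean
#' phase falls in the active or inactive part of the cycle.
#'
#' @inheritParams phase_vector
#' @param c_threshold confidence threshold separating NM from TA/TI.
#' @return Object of class `category_report`: `id`, `label`, `phase`
#'   (the phase vector), `rate` (Hz), `cv` (ISI coefficient of variation,
#'   NA when fewer than 3 spikes).
#' @export
#' @examples
#' pr <- swa_protocol("healthy")
#' tr <- spike_train(seq(100, 12900, by = 650), c(0, 13000))
#' categorize(tr, pr)$label
categorize <- function(train, protocol, window = train$interval,
                       c_threshold = 0.1) {
  if (window[2] <= window[1]) stop("empty analysis window")
  pv <- phase_vector(train, protocol, window)
  fs <- firing_stats(train, window)
  n_cycles <- (window[2] - window[1]) / protocol$period
  label <- if (pv$n_spikes < n_cycles) "QU"
  else if (pv$confidence < c_threshold) "NM"
  else {
    apr <- active_phase_range(protocol)
    if (pv$mean_phase >= apr[1] && pv$mean_phase < apr[2]) "TA" else "TI"
  }
  structure(list(id = train$id, label = label, phase = pv,
                 rate = fs[["rate"]], cv = fs[["cv"]]),
            class = "category_report")
}

#' @export
print.category_report <- function(x, ...) {
  cat(sprintf("<category_report> unit %s: %s (rate %.2f Hz, c %.3f)\n",
              as.character(x$id), x$label, x$rate,
              if (is.na(x$phase$confidence)) NA else x$phase$confidence))
  invisible(x)
}

#' Firing rate and ISI regularity
#'
#' Rate is the in-window spike count divided by the window length; the
#' coefficient of variation is the sample standard deviation of the
#' inter-spike intervals divided by their mean (undefined, NA, with fewer
#' than three spikes).
#'
#' @inheritParams phase_vector
#' @param window length-2 analysis window.
#' @return Named numeric: `rate` (Hz), `cv`, `n_spikes`.
#' @export
firing_stats <- function(train, window = train$interval) {
  ts <- train$times[train$times >= window[1] & train$times < window[2]]
  rate <- 1000 * length(ts) / (window[2] - window[1])
  cv <- if (length(ts) >= 3) {
    isi <- diff(ts)
    stats::sd(isi) / mean(isi)
  } else NA_real_
  c(rate = rate, cv = cv, n_spikes = length(ts))
}

#' Brillinger-normalized cross/auto-correlogram
#'
#' Symmetric lag histogram of spike-time differences `b - a`, with counts
#' normalized as `X' = T * X / (2 * h * N_A * N_B)` where `T` is the length
#' of the common observation interval, `h` half the bin width and `N_A`,
#' `N_B` the spike counts.  Under independence the expected normalized
#' value is 1; the 95% bounds are `1 +- 1.96 / sqrt(E[X])` with
#' `E[X] = 2 * h * N_A * N_B / T` (Poisson approximation).  When the same
#' train is passed twice, zero-lag self-pairs are excluded
#' (auto-correlogram).
#'
#' @param a,b [spike_train()] objects with overlapping intervals.
#' @param bin_width histogram bin width (ms).
#' @param n_bins number of bins on each side of zero lag.
#' @return Object of class `correlogram`: data.frame `bins` with `lag`
#'   (bin center, ms), `count`, `normalized`, plus fields `ci_lower`,
#'   `ci_upper`, `T`, `h`, `n_a`, `n_b`.
#' @export
#' @examples
#' a <- spike_train(sort(runif(100, 0, 1000)), c(0, 1000))
#' cg <- correlogram(a, a, bin_width = 3, n_bins = 10)
correlogram <- function(a, b, bin_width = 3, n_bins = 30) {
  t0 <- max(a$interval[1], b$interval[1])
  t1 <- min(a$interval[2], b$interval[2])
  if (t1 <= t0) stop("observation intervals do not overlap")
  sa <- a$times[a$times >= t0 & a$times < t1]
  sb <- b$times[b$times >= t0 & b$times < t1]
  if (!length(sa) || !length(sb)) stop("empty spike train")
  auto <- identical(a$times, b$times)
  max_lag <- bin_width * n_bins
  breaks <- seq(-max_lag, max_lag, by = bin_width)
  counts <- integer(2 * n_bins)
  # sliding window over sorted trains: pairs with |lag| <= max_lag
  j_lo <- 1
  for (i in seq_along(sa)) {
    while (j_lo <= length(sb) && sb[j_lo] < sa[i] - max_lag) j_lo <- j_lo + 1
    j <- j_lo
    while (j <= length(sb) && sb[j] <= sa[i] + max_lag) {
      lag <- sb[j] - sa[i]
      if (!(auto && i == j)) {
        k <- findInterval(lag, breaks, rightmost.closed = TRUE)
        if (k >= 1 && k <= 2 * n_bins) counts[k] <- counts[k] + 1L
      }
      j <- j + 1
    }
  }
  T_ <- t1 - t0
  h <- bin_width / 2
  ex <- 2 * h * length(sa) * length(sb) / T_
  norm <- T_ * counts / (2 * h * length(sa) * length(sb))
  structure(list(
    bins = data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
                      count = counts, normalized = norm),
    ci_lower = 1 - 1.96 / sqrt(ex), ci_upper = 1 + 1.96 / sqrt(ex),
    T = T_, h = h, n_a = length(sa), n_b = length(sb), auto = auto),
    class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(
    "<correlogram%s> %d bins of %g ms, N = %d x %d, T = %g ms, 95%% CI [%.3f, %.3f]\n",
    if (x$auto) " (auto)" else "", nrow(x$bins), 2 * x$h, x$n_a, x$n_b,
    x$T, x$ci_lower, x$ci_upper))
  invisible(x)
}

# concatenate the active-phase windows of a train into contiguous time, so
# that within-phase correlation structure can be assessed with a stationary
# normalization
.active_concat <- function(train, protocol) {
  ts <- train$times
  keep <- (ts %% protocol$period) < protocol$active_duration
  ts <- ts[keep]
  tmap <- floor(ts / protocol$period) * protocol$active_duration +
    (ts %% protocol$period)
  n_cycles <- ceiling(train$interval[2] / protocol$period)
  spike_train(sort(tmap), c(0, n_cycles * protocol$active_duration),
              id = train$id)
}

#' Independence check for a pair of spike trains
#'
#' Computes a short-window correlogram (default 30 bins of 3 ms) and a
#' long-window correlogram (400 bins of 20 ms).  For independently
#' generated slow-wave-modulated trains the short-window correlogram is
#' statistically flat at 1 while the long-window correlogram oscillates at
#' the protocol period.
#'
#' When a protocol is supplied, the short-window correlogram is computed
#' within the active bursting periods (active-phase windows concatenated
#' into contiguous time).  This is necessary for the flat-at-1 reading:
#' two independent but commonly slow-wave-modulated trains have an expected
#' whole-train normalized correlation well above 1 at every lag, because
#' the normalization uses time-averaged rates while both units concentrate
#' their spikes in the same phase windows.
#'
#' @param a,b [spike_train()] objects.
#' @param protocol optional [swa_protocol()]; if given, the short-window
#'   correlogram is restricted to active phases.
#' @param short_bins,short_width,long_bins,long_width correlogram shapes.
#' @return List with `short` and `long` correlograms and
#'   `frac_outside` (fraction of short-window bins outside the 95% band).
#' @export
cross_check_independence <- function(a, b, protocol = NULL,
                                     short_bins = 30, short_width = 3,
                                     long_bins = 400, long_width = 20) {
  if (!is.null(protocol)) {
    sa <- .active_concat(a, protocol)
    sb <- .active_concat(b, protocol)
  } else {
    sa <- a; sb <- b
  }
  short <- correlogram(sa, sb, bin_width = short_width, n_bins = short_bins)
  long <- correlogram(a, b, bin_width = long_width, n_bins = long_bins)
  fo <- mean(short$bins$normalized < short$ci_lower |
               short$bins$normalized > short$ci_upper)
  list(short = short, long = long, frac_outside = fo)
}

#' Spike-phase histograms by category
#'
#' Pools in-window spikes of all neurons with each label and bins them by
#' position in the slow-wave cycle (default 65 ms bins).  Also reports each
#' group's mean phase and average confidence.
#'
#' @param reports list of `category_report`s (one per neuron).
#' @param trains list of [spike_train()]s (same order).
#' @param protocol a [swa_protocol()].
#' @param window analysis window.
#' @param bin_width_ms histogram bin width in ms of cycle time.
#' @param labels which labels to include.
#' @return Named list per label: data.frame (`t0`, `t1`, `phase`, `count`)
#'   plus attributes `mean_phase` and `mean_confidence`.
#' @export
phase_histogram <- function(reports, trains, protocol,
                            window = NULL, bin_width_ms = 65,
                            labels = c("TI", "TA", "NM")) {
  labs <- vapply(reports, function(r) r$label, character(1))
  out <- list()
  for (lb in labels) {
    idx <- which(labs == lb)
    if (!length(idx)) stop("no neurons with label ", lb)
    ts <- unlist(lapply(idx, function(i) {
      w <- if (is.null(window)) trains[[i]]$interval else window
      tt <- trains[[i]]$times
      tt[tt >= w[1] & tt < w[2]]
    }))
    ct <- ts %% protocol$period
    breaks <- seq(0, protocol$period, by = bin_width_ms)
    if (breaks[length(breaks)] < protocol$period)
      breaks <- c(breaks, protocol$period)
    hh <- hist(ct, breaks = breaks, plot = FALSE)
    df <- data.frame(t0 = breaks[-length(breaks)], t1 = breaks[-1],
                     phase = 2 * pi * hh$mids / protocol$period,
                     count = hh$counts)
    om <- sum(exp(1i * 2 * pi * ct / protocol$period))
    attr(df, "mean_phase") <- Arg(om) %% (2 * pi)
    attr(df, "mean_confidence") <-
      mean(vapply(reports[idx], function(r) r$phase$confidence, numeric(1)),
           na.rm = TRUE)
    out[[lb]] <- df
  }
  out
}

#' Categorize every neuron of a simulation result
#'
#' @param result a `simulation_result` from [simulate_network()].
#' @param window analysis window; defaults to
#'   `[analysis_window_start, duration)` from the config.
#' @return List of `category_report`s.
#' @export
categorize_result <- function(result, window = NULL) {
  cfg <- result$config
  if (is.null(window)) window <- c(cfg$analysis_window_start, cfg$duration)
  lapply(result$spikes, categorize, protocol = cfg$protocol, window = window)
}

#' Per-category summary across a trial battery
#'
#' For each trial, categorizes all neurons and tabulates counts, firing
#' rates, CVs and confidences per label; then averages across trials.
#'
#' @param battery a `trial_battery` from [run_trial_battery()] (or a list
#'   of `simulation_result`s).
#' @param window analysis window passed to [categorize_result()].
#' @return Object of class `group_summary`: data.frame `per_label` with
#'   mean and s.d. across trials of count, percentage, rate, CV and
#'   confidence per label, plus `per_trial` (list of per-trial tables).
#' @export
group_summary <- function(battery, window = NULL) {
  labels <- c("TA", "TI", "NM", "QU")
  per_trial <- lapply(battery, function(res) {
    reps <- categorize_result(res, window)
    labs <- vapply(reps, function(r) r$label, character(1))
    do.call(rbind, lapply(labels, function(lb) {
      idx <- which(labs == lb)
      data.frame(
        label = lb, count = length(idx),
        pct = 100 * length(idx) / length(reps),
        rate = if (length(idx))
          mean(vapply(reps[idx], function(r) r$rate, numeric(1))) else NA_real_,
        cv = if (length(idx))
          mean(vapply(reps[idx], function(r) r$cv, numeric(1)),
               na.rm = TRUE) else NA_real_,
        confidence = if (length(idx))
          mean(vapply(reps[idx], function(r) r$phase$confidence, numeric(1)),
               na.rm = TRUE) else NA_real_)
    }))
  })
  agg <- do.call(rbind, lapply(labels, function(lb) {
    rows <- do.call(rbind, lapply(per_trial, function(tb) tb[tb$label == lb, ]))
    n <- nrow(rows)
    data.frame(
      label = lb,
      count_mean = mean(rows$count), count_sd = if (n > 1) stats::sd(rows$count) else NA_real_,
      pct_mean = mean(rows$pct), pct_sd = if (n > 1) stats::sd(rows$pct) else NA_real_,
      rate_mean = mean(rows$rate, na.rm = TRUE),
      rate_sd = if (n > 1) stats::sd(rows$rate) else NA_real_,
      cv_mean = mean(rows$cv, na.rm = TRUE),
      confidence_mean = mean(rows$confidence, na.rm = TRUE))
  }))
  structure(list(per_label = agg, per_trial = per_trial,
                 n_trials = length(battery)), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %d trial(s)\n", x$n_trials))
  print(x$per_label, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pooled per-neuron statistics for one label across a battery
#'
#' @param battery a `trial_battery`.
#' @param label one of `"TA"`, `"TI"`, `"NM"`, `"QU"`.
#' @param field `"rate"`, `"cv"`, or `"confidence"`.
#' @param window analysis window.
#' @return Numeric vector pooling all neurons with the label over all
#'   trials.
#' @export
pool_label_stat <- function(battery, label, field = "rate", window = NULL) {
  unlist(lapply(battery, function(res) {
    reps <- categorize_result(res, window)
    labs <- vapply(reps, function(r) r$label, character(1))
    vapply(reps[labs == label], function(r)
      switch(field, rate = r$rate, cv = r$cv,
             confidence = r$phase$confidence), numeric(1))
  }))
}
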