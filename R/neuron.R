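## Isolated GP neuron simulation: population sampling, current-injection
## protocols, spike detection.

# conductance matrix (n x 10, canonical channel order) from a population
# data.frame or a single named vector
.g_matrix <- function(g) {
  if (is.null(dim(g))) g <- as.data.frame(as.list(g))
  missing <- setdiff(.channel_names, names(g))
  if (length(missing))
    stop("missing conductances: ", paste(missing, collapse = ", "))
  as.matrix(g[, .channel_names, drop = FALSE])
}

#' Mean maximal conductances of the model GP neuron
#'
#' Named vector of the fixed (Table) maximal conductances in nS.
#'
#' @return Named numeric vector over the ten channels.
#' @export
mean_conductances <- function() {
  stats::setNames(.channel_table$g_max, .channel_table$name)
}

#' Sample a heterogeneous GP population
#'
#' Draws per-neuron maximal conductances.  NaP is Gaussian with a 50%
#' coefficient of variation and both HCN channels with 30%, all truncated at
#' zero (conductances cannot be negative); all other channels are fixed at
#' their mean values.
#'
#' @param n number of neurons (>= 1).
#' @param seed optional integer seed; if supplied, `set.seed(seed)` is
#'   called first and the seed is stored as an attribute.
#' @param cv_nap,cv_hcn coefficients of variation for NaP and the HCN pair.
#' @return A data.frame with one row per neuron and one column per channel
#'   (nS), with attribute `seed`.
#' @export
#' @examples
#' pop <- sample_population(5, seed = 1)
#' colMeans(pop)
sample_population <- function(n, seed = NULL, cv_nap = 0.5, cv_hcn = 0.3) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- mean_conductances()
  pop <- as.data.frame(lapply(g, rep, times = n))
  pop$nap  <- pmax(0, stats::rnorm(n, g[["nap"]],  cv_nap * g[["nap"]]))
  pop$hcnf <- pmax(0, stats::rnorm(n, g[["hcnf"]], cv_hcn * g[["hcnf"]]))
  pop$hcns <- pmax(0, stats::rnorm(n, g[["hcns"]], cv_hcn * g[["hcns"]]))
  attr(pop, "seed") <- seed
  pop
}

#' Spike train object
#'
#' Ordered spike times with their observation interval.
#'
#' @param times numeric vector of spike times (ms), strictly increasing.
#' @param interval numeric length-2 observation interval `[t0, t1)`.
#' @param id optional unit identifier.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times, interval, id = NA) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < interval[1] || times[length(times)] > interval[2]))
    stop("spikes outside observation interval")
  structure(list(times = times, interval = as.numeric(interval), id = id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes on [%g, %g) ms (%.2f Hz)\n",
              as.character(x$id), length(x$times), x$interval[1],
              x$interval[2],
              1000 * length(x$times) / diff(x$interval)))
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of 0 mV; the spike time is linearly
#' interpolated between the bracketing samples.
#'
#' @param times sample times (ms), strictly increasing.
#' @param v membrane potential samples (mV).
#' @param id unit identifier for the returned train.
#' @return A [spike_train()].
#' @export
#' @examples
#' detect_spikes(c(1, 2), c(-10, 10))$times  # 1.5
detect_spikes <- function(times, v, id = NA) {
  if (length(times) == 0) stop("empty trace")
  if (length(times) != length(v)) stop("times and v lengths differ")
  if (is.unsorted(times, strictly = TRUE))
    stop("sample times must be strictly increasing")
  n <- length(v)
  if (n < 2) return(spike_train(numeric(0), c(times[1], times[1]), id))
  up <- which(v[-n] < 0 & v[-1] >= 0)
  ts <- times[up] + (times[up + 1] - times[up]) * (0 - v[up]) / (v[up + 1] - v[up])
  spike_train(ts, c(times[1], times[n]), id)
}

# shared low-level call into the compiled isolated-population engine
.run_isolated <- function(gmat, protocol, kinetics, membrane, calcium,
                          v0 = NULL, trace_idx = integer(0), sample_dt = 0.1,
                          hmax = 1, downreg = NULL) {
  if (is.null(v0)) v0 <- membrane$E_leak
  dur <- cumsum(protocol$duration)
  dr <- c(0, 0.2, 0.6, 0.5, 0.1)
  if (!is.null(downreg))
    dr <- c(as.numeric(downreg$enabled), downreg$T_HCN, downreg$k_HCN,
            downreg$theta, downreg$sigma)
  cpp_simulate_population(
    gmat,
    c(membrane$C, membrane$g_leak, membrane$E_leak),
    .channel_table$e_rev,
    .kinetics_matrix(kinetics),
    c(calcium$epsilon, calcium$k_ca),
    dr,
    c(5, 40, -80), c(0.2, 60, 0),
    dur, protocol$I_ext,
    duration = dur[length(dur)], v0 = v0, ca0 = 0,
    hmax = hmax, control_dt = 1,
    trace_idx = as.integer(trace_idx - 1L), sample_dt = sample_dt)
}

#' Simulate isolated GP neurons under a current-injection protocol
#'
#' Integrates each neuron independently (no synapses) with the adaptive
#' Runge--Kutta--Fehlberg solver (absolute/relative tolerance 1e-5, maximum
#' step 1 ms).  The protocol is a sequence of `(duration, I_ext)` steps
#' applied to every neuron.
#'
#' @param g conductances: a named vector (one neuron) or a population
#'   data.frame/matrix from [sample_population()].
#' @param protocol data.frame with columns `duration` (ms, > 0) and `I_ext`
#'   (pA).  Default: 2 s with no injected current.
#' @param kinetics gate kinetics ([load_gate_kinetics()]).
#' @param membrane,calcium parameter objects.
#' @param record integer indices of neurons whose voltage traces to keep.
#' @param sample_dt trace sampling interval (ms).
#' @param v0 initial membrane potential (mV); gates start at steady state.
#' @return List with `spikes` (list of [spike_train()]), `traces` (list of
#'   data.frames `t`, `v` for recorded neurons), `ghcn_final` (n x 2).
#' @export
#' @examples
#' \donttest{
#' res <- simulate_isolated(mean_conductances(),
#'                          protocol = data.frame(duration = 500, I_ext = 0))
#' length(res$spikes[[1]]$times)
#' }
simulate_isolated <- function(g,
                              protocol = data.frame(duration = 2000, I_ext = 0),
                              kinetics = load_gate_kinetics(),
                              membrane = gp_membrane_params(),
                              calcium = gp_calcium_params(),
                              record = integer(0),
                              sample_dt = 0.1,
                              v0 = NULL) {
  if (any(protocol$duration <= 0)) stop("protocol durations must be > 0")
  gmat <- .g_matrix(g)
  out <- .run_isolated(gmat, protocol, kinetics, membrane, calcium,
                       v0 = v0, trace_idx = record, sample_dt = sample_dt)
  total <- sum(protocol$duration)
  spikes <- lapply(seq_len(nrow(gmat)), function(i)
    spike_train(out$spikes[[i]], c(0, total), id = i))
  traces <- lapply(out$traces, function(tr) data.frame(t = tr$t, v = tr$v))
  list(spikes = spikes, traces = traces, ghcn_final = out$ghcn_final)
}

#' Steady firing rates of isolated neurons
#'
#' Convenience wrapper: simulates `burn_in + window` ms at a constant
#' injected current and returns each neuron's firing rate in the analysis
#' window.  A neuron is "pacemaking" if it fires persistently, i.e. emits
#' spikes in the final quarter of the window.
#'
#' @param g conductance vector or population data.frame.
#' @param I_ext injected current (pA).
#' @param burn_in,window burn-in discarded and measurement window (ms).
#' @inheritParams simulate_isolated
#' @return data.frame with `rate` (Hz) and logical `pacemaking`.
#' @export
isolated_rates <- function(g, I_ext = 0, burn_in = 500, window = 2000,
                           kinetics = load_gate_kinetics(),
                           membrane = gp_membrane_params(),
                           calcium = gp_calcium_params()) {
  res <- simulate_isolated(g, protocol = data.frame(duration = burn_in + window,
                                                    I_ext = I_ext),
                           kinetics = kinetics, membrane = membrane,
                           calcium = calcium)
  t0 <- burn_in
  t1 <- burn_in + window
  stats <- vapply(res$spikes, function(s) {
    st <- s$times[s$times >= t0 & s$times < t1]
    c(rate = 1000 * length(st) / window,
      pace = length(st[st >= t1 - window / 4]) > 0)
  }, numeric(2))
  data.frame(rate = stats[1, ], pacemaking = stats[2, ] > 0)
}
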