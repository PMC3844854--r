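## Network construction and whole-network simulation.
##
## 100 GP neurons (default), each inhibiting `gp_fanout` = 20 randomly
## chosen others (no self-connections); 50 STN units, each exciting
## `stn_fanout` = 2 randomly chosen GP neurons.  Under Parkinsonian
## conditions the STN active-phase rate and both synaptic conductance means
## are increased.  All randomness flows from the config's master seed via
## named sub-seed streams.

#' Network configuration
#'
#' Collects the full specification of one network simulation.  Scaling
#' presets (`n_gp` = 200/`n_stn` = 100 and 300/150) keep the per-neuron
#' fan-outs constant, lowering the coupling proportion.
#'
#' @param n_gp,n_stn population sizes.
#' @param gp_fanout inhibitory synapses made by each GP neuron
#'   (< `n_gp`).
#' @param stn_fanout GP targets of each STN unit.
#' @param condition `"healthy"` or `"parkinsonian"`.
#' @param protocol optional [swa_protocol()]; defaults to the preset for
#'   the condition.
#' @param duration simulated time (ms).
#' @param analysis_window_start start of the analysis window (ms); defaults
#'   to the latter half of the run.
#' @param downregulation a [downregulation_params()].
#' @param g_gg,g_sg optional overrides of the mean unitary conductances
#'   (nS) for GP-GP and STN-GP synapses.
#' @param seed master seed (integer).
#' @return Object of class `network_config`.
#' @export
#' @examples
#' cfg <- network_config(condition = "parkinsonian", seed = 1)
#' cfg$synapses$gp_gp$g_mean  # 1.0
network_config <- function(n_gp = 100, n_stn = 50,
                           gp_fanout = 20, stn_fanout = 2,
                           condition = c("healthy", "parkinsonian"),
                           protocol = NULL,
                           duration = 13000,
                           analysis_window_start = duration / 2,
                           downregulation = downregulation_params(),
                           g_gg = NULL, g_sg = NULL,
                           seed = 1) {
  condition <- match.arg(condition)
  if (gp_fanout >= n_gp)
    stop("gp_fanout must be smaller than n_gp (no self-connections)")
  stopifnot(n_gp >= 1, n_stn >= 0, stn_fanout <= n_gp, duration > 0)
  if (is.null(protocol)) protocol <- swa_protocol(condition)
  cfg <- structure(list(
    n_gp = n_gp, n_stn = n_stn, gp_fanout = gp_fanout,
    stn_fanout = stn_fanout, condition = condition, protocol = protocol,
    duration = duration, analysis_window_start = analysis_window_start,
    downregulation = downregulation,
    synapses = list(gp_gp = synapse_params("gp_gp", condition, g_mean = g_gg),
                    stn_gp = synapse_params("stn_gp", condition, g_mean = g_sg)),
    seed = as.integer(seed)), class = "network_config")
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> %d GP + %d STN, condition '%s', %g ms, seed %d\n",
    x$n_gp, x$n_stn, x$condition, x$duration, x$seed))
  cat(sprintf("  fan-outs: GP %d, STN %d | g_GG %.2g nS, g_SG %.2g nS | active rate %g Hz | downregulation %s\n",
              x$gp_fanout, x$stn_fanout, x$synapses$gp_gp$g_mean,
              x$synapses$stn_gp$g_mean, x$protocol$active_rate,
              if (x$downregulation$enabled) "on" else "off"))
  invisible(x)
}

#' Resolved condition-dependent parameters
#'
#' The Parkinsonian condition makes three changes relative to healthy:
#' STN active-phase rate 30 -> 60 Hz, mean STN-GP conductance 0.1 -> 0.2 nS,
#' mean GP-GP conductance 0.5 -> 1.0 nS.
#'
#' @param cfg a [network_config()] (or a condition name).
#' @return Named numeric: `active_rate` (Hz), `g_sg` (nS), `g_gg` (nS).
#' @export
#' @examples
#' apply_condition("parkinsonian")  # 60, 0.2, 1.0
apply_condition <- function(cfg) {
  if (is.character(cfg)) cfg <- network_config(condition = cfg)
  c(active_rate = cfg$protocol$active_rate,
    g_sg = cfg$synapses$stn_gp$g_mean,
    g_gg = cfg$synapses$gp_gp$g_mean)
}

# master seed -> named sub-seed streams
derive_seeds <- function(master, streams = c("heterogeneity", "connectivity",
                                             "synaptic_noise", "stn")) {
  set.seed(master)
  stats::setNames(sample.int(.Machine$integer.max - 1, length(streams)),
                  streams)
}

#' Build random network connectivity
#'
#' GP-to-GP: each source neuron selects `gp_fanout` distinct targets
#' uniformly at random, never itself.  STN-to-GP: each STN unit selects
#' `stn_fanout` distinct GP targets.  Per-edge unitary conductances are
#' drawn from the corresponding synapse preset.
#'
#' @param cfg a [network_config()].
#' @param seed optional integer seed for the connectivity and conductance
#'   draws (defaults are derived from `cfg$seed`).
#' @return Object of class `connectivity_graph`: data.frames `gp_edges` and
#'   `stn_edges` with columns `pre`, `post`, `g_syn`.
#' @export
build_connectivity <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gp_tgt <- lapply(seq_len(cfg$n_gp), function(i)
    sample(setdiff(seq_len(cfg$n_gp), i), cfg$gp_fanout))
  gp_edges <- data.frame(
    pre = rep(seq_len(cfg$n_gp), each = cfg$gp_fanout),
    post = unlist(gp_tgt))
  gp_edges$g_syn <- sample_unitary_conductances(nrow(gp_edges),
                                                cfg$synapses$gp_gp)
  if (cfg$n_stn > 0) {
    stn_tgt <- lapply(seq_len(cfg$n_stn), function(u)
      sample(seq_len(cfg$n_gp), cfg$stn_fanout))
    stn_edges <- data.frame(
      pre = rep(seq_len(cfg$n_stn), each = cfg$stn_fanout),
      post = unlist(stn_tgt))
    stn_edges$g_syn <- sample_unitary_conductances(nrow(stn_edges),
                                                   cfg$synapses$stn_gp)
  } else {
    stn_edges <- data.frame(pre = integer(0), post = integer(0),
                            g_syn = numeric(0))
  }
  structure(list(gp_edges = gp_edges, stn_edges = stn_edges,
                 n_gp = cfg$n_gp, n_stn = cfg$n_stn),
            class = "connectivity_graph")
}

# edge data.frame -> CSR (0-based) over n sources
.edges_to_csr <- function(edges, n_src) {
  o <- order(edges$pre)
  edges <- edges[o, , drop = FALSE]
  counts <- tabulate(edges$pre, nbins = n_src)
  list(ptr = as.integer(c(0, cumsum(counts))),
       tgt = as.integer(edges$post - 1L),
       w = as.numeric(edges$g_syn))
}

#' Simulate the GP network
#'
#' Draws the heterogeneous GP population, wires the network, generates the
#' STN spike trains, and integrates the coupled system with the adaptive
#' Runge--Kutta--Fehlberg solver (tolerances 1e-5, maximum step 1 ms).  STN
#' spikes are injected as events; HCN downregulation (if enabled) is applied
#' at 1 ms control intervals.  Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [network_config()].
#' @param kinetics gate kinetics ([load_gate_kinetics()]).
#' @param membrane,calcium parameter objects.
#' @param record integer indices of GP neurons whose voltage traces to keep.
#' @param sample_dt trace sampling interval (ms).
#' @return Object of class `simulation_result`: `spikes` (list of
#'   [spike_train()]), `ghcn_final`, `ca_final`, `population`,
#'   `connectivity`, `stn_trains`, `config`, `sub_seeds`, `kinetics`.
#' @export
simulate_network <- function(cfg,
                             kinetics = load_gate_kinetics(),
                             membrane = gp_membrane_params(),
                             calcium = gp_calcium_params(),
                             record = integer(0), sample_dt = 1) {
  seeds <- derive_seeds(cfg$seed)
  pop <- sample_population(cfg$n_gp, seed = seeds[["heterogeneity"]])
  set.seed(seeds[["connectivity"]])
  graph <- build_connectivity(cfg)
  stn <- if (cfg$n_stn > 0)
    generate_stn_train(cfg$protocol, cfg$duration, n_units = cfg$n_stn,
                       seed = seeds[["stn"]])
  else list()

  gp_csr <- .edges_to_csr(graph$gp_edges, cfg$n_gp)
  stn_csr <- .edges_to_csr(graph$stn_edges, max(cfg$n_stn, 1))
  ev_times <- unlist(lapply(stn, function(s) s$times))
  if (is.null(ev_times)) ev_times <- numeric(0)
  ev <- data.frame(
    time = ev_times,
    unit = rep(seq_along(stn) - 1L,
               vapply(stn, function(s) length(s$times), integer(1))))
  ev <- ev[order(ev$time), , drop = FALSE]

  dr <- cfg$downregulation
  out <- cpp_simulate_network(
    .g_matrix(pop),
    c(membrane$C, membrane$g_leak, membrane$E_leak),
    .channel_table$e_rev, .kinetics_matrix(kinetics),
    c(calcium$epsilon, calcium$k_ca),
    c(as.numeric(dr$enabled), dr$T_HCN, dr$k_HCN, dr$theta, dr$sigma),
    c(cfg$synapses$gp_gp$tau_o, cfg$synapses$gp_gp$tau_c,
      cfg$synapses$gp_gp$e_rev),
    c(cfg$synapses$stn_gp$tau_o, cfg$synapses$stn_gp$tau_c,
      cfg$synapses$stn_gp$e_rev),
    gp_ptr = gp_csr$ptr, gp_tgt = gp_csr$tgt, gp_w = gp_csr$w,
    ev_time = as.numeric(ev$time), ev_unit = as.integer(ev$unit),
    ext_ptr = stn_csr$ptr, ext_tgt = stn_csr$tgt, ext_w = stn_csr$w,
    ext_kind = rep(0L, length(stn_csr$w)),
    prot_end = cfg$duration, prot_amp = 0,
    duration = cfg$duration, v0 = membrane$E_leak, ca0 = 0,
    hmax = 1, control_dt = dr$update_interval,
    trace_idx = as.integer(record - 1L), sample_dt = sample_dt,
    record_downreg = length(record) > 0)

  spikes <- lapply(seq_len(cfg$n_gp), function(i)
    spike_train(out$spikes[[i]], c(0, cfg$duration), id = i))
  res <- list(spikes = spikes,
              ghcn_final = out$ghcn_final,
              ca_final = out$ca_final,
              population = pop,
              connectivity = graph,
              stn_trains = stn,
              config = cfg,
              sub_seeds = seeds,
              kinetics = kinetics)
  if (!is.null(out$trace_t))
    res$traces <- data.frame(t = out$trace_t, out$trace_v)
  if (!is.null(out$downreg_t))
    res$downreg <- data.frame(t = out$downreg_t, out$downreg_g)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  rates <- vapply(x$spikes, function(s)
    1000 * length(s$times) / diff(s$interval), numeric(1))
  cat(sprintf(
    "<simulation_result> %d GP neurons, %g ms, condition '%s'\n  mean rate %.1f Hz (range %.1f-%.1f)\n",
    length(x$spikes), x$config$duration, x$config$condition,
    mean(rates), min(rates), max(rates)))
  invisible(x)
}

#' Run a battery of independent network trials
#'
#' Each trial uses fresh connectivity, STN spike trains and parameter noise
#' derived from an independent sub-seed of the master seed.
#'
#' @param cfg a [network_config()]; its `seed` acts as the master seed.
#' @param n_trials number of trials (>= 1).
#' @param ... passed on to [simulate_network()].
#' @return List of `simulation_result` objects (class `trial_battery`).
#' @export
run_trial_battery <- function(cfg, n_trials = 12, ...) {
  stopifnot(n_trials >= 1)
  set.seed(cfg$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1, n_trials)
  res <- lapply(trial_seeds, function(s) {
    cfg_i <- cfg
    cfg_i$seed <- s
    simulate_network(cfg_i, ...)
  })
  class(res) <- "trial_battery"
  attr(res, "master_seed") <- cfg$seed
  res
}
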