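## Double-exponential conductance synapses.
##
## Each synapse carries an opening variable o and a closing variable c; a
## presynaptic spike step-increases both by 1, after which they decay
## exponentially with time constants tau_o < tau_c.  The synaptic current is
## I = (c - o) * g_syn * (e_rev - V_post), a difference of exponentials that
## rises over ~tau_o and decays over ~tau_c.

#' Synapse parameter presets
#'
#' GABAergic GP-to-GP synapses use `tau_o` = 5 ms, `tau_c` = 40 ms, reversal
#' -80 mV, and a mean unitary conductance of 0.5 nS (healthy), doubled to
#' 1.0 nS under Parkinsonian conditions (3.0 nS in the high-inhibition
#' beta-band variant).  Glutamatergic STN-to-GP synapses use `tau_o` = 0.2
#' ms, `tau_c` = 60 ms, reversal 0 mV (standard AMPA value), mean 0.1 nS
#' (healthy) or 0.2 nS (Parkinsonian).  Unitary conductances are drawn per
#' synapse from a Gaussian with a relative s.d. of 0.3, truncated at 0.
#'
#' @param kind `"gp_gp"` or `"stn_gp"`.
#' @param condition `"healthy"`, `"parkinsonian"`, or `"beta_high_inhibition"`
#'   (the latter only affects `gp_gp`).
#' @param g_mean optional override of the mean unitary conductance (nS).
#' @return Object of class `synapse_params` with fields `tau_o`, `tau_c`,
#'   `e_rev`, `g_mean`, `g_sd_fraction`.
#' @export
#' @examples
#' synapse_params("gp_gp", "parkinsonian")$g_mean  # 1.0
synapse_params <- function(kind = c("gp_gp", "stn_gp"),
                           condition = c("healthy", "parkinsonian",
                                         "beta_high_inhibition"),
                           g_mean = NULL) {
  kind <- match.arg(kind)
  condition <- match.arg(condition)
  p <- if (kind == "gp_gp") {
    list(tau_o = 5, tau_c = 40, e_rev = -80,
         g_mean = switch(condition, healthy = 0.5, parkinsonian = 1.0,
                         beta_high_inhibition = 3.0))
  } else {
    list(tau_o = 0.2, tau_c = 60, e_rev = 0,
         g_mean = switch(condition, healthy = 0.1, parkinsonian = 0.2,
                         beta_high_inhibition = 0.2))
  }
  if (!is.null(g_mean)) p$g_mean <- g_mean
  stopifnot(p$tau_o > 0, p$tau_o < p$tau_c, p$g_mean >= 0)
  structure(c(p, list(kind = kind, g_sd_fraction = 0.3)),
            class = "synapse_params")
}

#' Synapse state derivatives
#'
#' Between spikes both variables decay to zero:
#' `do/dt = -o/tau_o`, `dc/dt = -c/tau_c`.
#'
#' @param state list/vector with elements `o` and `c` (>= 0).
#' @param p a [synapse_params()].
#' @return Named numeric `c(do, dc)` in 1/ms.
#' @export
synapse_rhs <- function(state, p) {
  stopifnot(state$o >= 0, state$c >= 0)
  c(do = -state$o / p$tau_o, dc = -state$c / p$tau_c)
}

#' Presynaptic spike update
#'
#' Both synapse variables are step-increased by 1 at the spike time;
#' simultaneous spikes sum.
#'
#' @param state list with `o`, `c`.
#' @param n number of simultaneous presynaptic spikes.
#' @return Updated state.
#' @export
on_presynaptic_spike <- function(state, n = 1) {
  state$o <- state$o + n
  state$c <- state$c + n
  state
}

#' Synaptic current
#'
#' `I = (c - o) * g_syn * (e_rev - V_post)` in pA.  The total synaptic
#' current of a neuron is the sum over its afferent synapses.
#'
#' @param state list with `o`, `c`.
#' @param g_syn unitary maximal conductance (nS), >= 0.
#' @param e_rev synaptic reversal potential (mV).
#' @param v_post postsynaptic membrane potential (mV).
#' @return Current in pA.
#' @export
synaptic_current <- function(state, g_syn, e_rev, v_post) {
  stopifnot(g_syn >= 0)
  (state$c - state$o) * g_syn * (e_rev - v_post)
}

#' Closed-form single-spike conductance time course
#'
#' After a single spike at `t = 0` from rest, `o(t) = exp(-t/tau_o)` and
#' `c(t) = exp(-t/tau_c)`, so the conductance factor is
#' `c(t) - o(t) >= 0` (because `tau_o < tau_c`), peaking at
#' `t* = ln(tau_c/tau_o) / (1/tau_o - 1/tau_c)` independent of `g_syn`.
#'
#' @param p a [synapse_params()].
#' @param t times (ms) at which to evaluate the factor (optional).
#' @return If `t` is `NULL`, the peak time `t*` (ms); otherwise the factor
#'   `c(t) - o(t)` at the requested times.
#' @export
#' @examples
#' synapse_peak_time(synapse_params("gp_gp"))  # ~11.88 ms
synapse_peak_time <- function(p, t = NULL) {
  if (is.null(t))
    return(log(p$tau_c / p$tau_o) / (1 / p$tau_o - 1 / p$tau_c))
  exp(-t / p$tau_c) - exp(-t / p$tau_o)
}

#' Sample unitary synaptic conductances
#'
#' Gaussian draws with mean `g_mean` and s.d. `g_sd_fraction * g_mean`,
#' truncated at zero.
#'
#' @param n number of synapses.
#' @param p a [synapse_params()].
#' @return Numeric vector of conductances (nS).
#' @export
sample_unitary_conductances <- function(n, p) {
  pmax(0, stats::rnorm(n, p$g_mean, p$g_sd_fraction * p$g_mean))
}

#' Peak IPSP amplitude of a unitary GP-to-GP synapse
#'
#' Holds a mean-parameter GP neuron near a target potential with a constant
#' hyperpolarizing current (computed from the steady-state current balance),
#' delivers one presynaptic spike, and returns the peak deflection of the
#' membrane potential below the holding trajectory.
#'
#' @param g_gg unitary conductance of the inhibitory synapse (nS).
#' @param v_hold holding potential (mV).
#' @param kinetics,membrane,calcium model parameter objects.
#' @return Peak IPSP amplitude in mV (>= 0).
#' @export
#' @examples
#' \donttest{
#' calibrate_unitary_ipsp(0.5)  # ~0.5 mV
#' }
calibrate_unitary_ipsp <- function(g_gg,
                                   v_hold = -65,
                                   kinetics = load_gate_kinetics(),
                                   membrane = gp_membrane_params(),
                                   calcium = gp_calcium_params()) {
  stopifnot(g_gg >= 0)
  channels <- default_channels(kinetics)
  st <- neuron_state(v_hold, channels = channels)
  i_hold <- -membrane$C *
    membrane_rhs(st, membrane, channels, I_syn = 0, I_ext = 0)
  settle <- 2000
  dur <- settle + 500
  run_one <- function(with_spike) {
    ev_time <- if (with_spike) settle else numeric(0)
    out <- cpp_simulate_network(
      matrix(.g_matrix(mean_conductances()), nrow = 1),
      c(membrane$C, membrane$g_leak, membrane$E_leak),
      .channel_table$e_rev, .kinetics_matrix(kinetics),
      c(calcium$epsilon, calcium$k_ca),
      c(0, 0.2, 0.6, 0.5, 0.1),
      c(5, 40, -80), c(0.2, 60, 0),
      gp_ptr = c(0L, 0L), gp_tgt = integer(0), gp_w = numeric(0),
      ev_time = ev_time, ev_unit = rep(0L, length(ev_time)),
      ext_ptr = c(0L, 1L), ext_tgt = 0L, ext_w = g_gg, ext_kind = 1L,
      prot_end = dur, prot_amp = i_hold,
      duration = dur, v0 = v_hold, ca0 = 0,
      hmax = 1, control_dt = 1,
      trace_idx = 0L, sample_dt = 0.25, record_downreg = FALSE)
    data.frame(t = out$trace_t, v = out$trace_v[, 1])
  }
  base <- run_one(FALSE)
  resp <- run_one(TRUE)
  vb <- base$v[length(base$v)]
  if (abs(vb - v_hold) > 2.5 || length(detect_spikes(base$t, base$v)$times))
    stop("holding current failed to stabilize the neuron near ", v_hold, " mV")
  win <- resp$t >= settle
  max(0, max(base$v[win] - resp$v[win]))
}
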