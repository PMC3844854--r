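# shared fixtures: calibrated kinetics, mean-parameter conductances, and a
# few small canned protocols

kin <- load_gate_kinetics()
chans <- default_channels(kin)
memb <- gp_membrane_params()
cap <- gp_calcium_params()

# mean-parameter neuron state at a given voltage
state_at <- function(v, ca = 0) neuron_state(v, ca, channels = chans)

# steady firing rate of a single conductance set over a window
quick_rate <- function(g, I_ext = 0, burn = 500, window = 1500) {
  res <- simulate_isolated(g, protocol = data.frame(duration = burn + window,
                                                    I_ext = I_ext),
                           kinetics = kin)
  ts <- res$spikes[[1]]$times
  1000 * sum(ts >= burn) / window
}

# homogeneous Poisson spike train on [0, T)
poisson_train <- function(rate_hz, T_ms, id = NA) {
  n <- stats::rpois(1, rate_hz * T_ms / 1000)
  spike_train(sort(stats::runif(n, 0, T_ms)), c(0, T_ms), id = id)
}
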