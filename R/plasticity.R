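## Activity-dependent downregulation of HCN maximal conductance.
##
## When intracellular calcium exceeds a threshold, both HCN conductances are
## decremented between integration control steps by a sigmoidal function of
## calcium; the conductance never goes below zero and never recovers.

#' HCN downregulation parameters
#'
#' The update applied every `update_interval` ms, when `Ca > T_HCN`:
#' `g' = max(0, g - k_HCN * dt / (1 + exp((theta - Ca) / sigma)))`.
#' `k_HCN` is the maximal conductance decrement per millisecond; the default
#' corresponds to 6e-4 uS/ms (0.6 nS/ms), which fully depletes an HCN
#' conductance of 177 nS in a few hundred milliseconds of strong drive --
#' a rapid reduction in response to sustained fast firing.
#'
#' @param T_HCN calcium threshold above which downregulation occurs.
#' @param k_HCN maximal decrement rate (nS/ms).
#' @param theta calcium level of half-maximal decrement.
#' @param sigma sigmoid slope.
#' @param update_interval interval between discrete adjustments (ms).
#' @param enabled logical flag.
#' @return Object of class `downregulation_params`.
#' @export
downregulation_params <- function(T_HCN = 0.2, k_HCN = 0.6, theta = 0.5,
                                  sigma = 0.1, update_interval = 1,
                                  enabled = TRUE) {
  stopifnot(T_HCN > 0, k_HCN > 0, theta > 0, sigma > 0, update_interval > 0)
  structure(list(T_HCN = T_HCN, k_HCN = k_HCN, theta = theta, sigma = sigma,
                 update_interval = update_interval, enabled = enabled),
            class = "downregulation_params")
}

#' Apply one downregulation step
#'
#' Returns the updated HCN maximal conductance.  If calcium is at or below
#' the threshold, or the mechanism is disabled, the conductance is
#' unchanged; otherwise it is decremented by the sigmoidal amount, clamped
#' at zero.  The rule is applied identically and independently to the fast
#' and slow HCN conductances of each neuron.
#'
#' @param g_hcn current maximal conductance (nS), >= 0 (vectorized).
#' @param ca calcium level, >= 0 (vectorized).
#' @param p a [downregulation_params()].
#' @return Updated conductance(s), nS.
#' @export
#' @examples
#' p <- downregulation_params()
#' apply_downregulation(177, ca = 0.1, p)  # unchanged (below threshold)
#' 177 - apply_downregulation(177, ca = 0.5, p)  # k_HCN * dt / 2
apply_downregulation <- function(g_hcn, ca, p) {
  stopifnot(all(g_hcn >= 0), all(ca >= 0))
  if (!p$enabled) return(g_hcn)
  dec <- ifelse(ca > p$T_HCN,
                p$k_HCN * p$update_interval /
                  (1 + exp((p$theta - ca) / p$sigma)),
                0)
  pmax(0, g_hcn - dec)
}

#' Intrinsic pacemaking after network-driven downregulation
#'
#' Takes a simulated network result, freezes each neuron's (possibly
#' downregulated) HCN conductances, severs all synapses, simulates every
#' neuron in isolation, and returns the population statistics of the
#' intrinsic rates.
#'
#' @param result a `simulation_result` from [simulate_network()].
#' @param burn_in,window burn-in and measurement window for the isolated
#'   re-simulation (ms).
#' @return List with `rates` (per-neuron intrinsic rate, Hz), `mean_rate`,
#'   `quiet_fraction` (neurons firing < 1 spike/s in the window), and the
#'   per-neuron frozen conductance table.
#' @export
measure_post_downregulation_pacemaking <- function(result, burn_in = 500,
                                                   window = 2000) {
  g <- result$population
  g$hcnf <- result$ghcn_final[, 1]
  g$hcns <- result$ghcn_final[, 2]
  rr <- isolated_rates(g, I_ext = 0, burn_in = burn_in, window = window,
                       kinetics = result$kinetics)
  list(rates = rr$rate, mean_rate = mean(rr$rate),
       quiet_fraction = mean(!rr$pacemaking), population = g)
}
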