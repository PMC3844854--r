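## Voltage-gated channel architecture of the model GP neuron.
##
## Ten channels, each with an activation gate (m) and, for some, inactivation
## (h) and slow-inactivation (s) gates.  Gate exponents (mu, rho, phi) and
## maximal conductances are fixed model constants; gate kinetics (Boltzmann
## steady states with sigmoidal voltage-dependent time constants) are
## calibration data shipped as a text file and replaceable by the user.

# canonical channel order used throughout (and by the compiled engine)
.channel_names <- c("naf", "nap", "kv2", "kv3", "kv4f", "kv4s",
                    "kcnq", "hva", "hcnf", "hcns")

.channel_table <- data.frame(
  name  = .channel_names,
  g_max = c(5900, 17.7, 590, 590, 590, 590, 1.77, 1.77, 177, 177),
  e_rev = c(55, 55, -80, -80, -80, -80, -80, 120, -30, -30),
  mu    = c(3L, 3L, 4L, 4L, 4L, 4L, 4L, 1L, 1L, 1L),
  rho   = c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
  phi   = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
  stringsAsFactors = FALSE
)

# canonical gate order (must match the compiled engine)
.gate_channels <- c("naf", "naf", "naf", "nap", "nap", "nap",
                    "kv2", "kv2", "kv3", "kv3", "kv4f", "kv4f",
                    "kv4s", "kv4s", "kcnq", "hva", "hcnf", "hcns")
.gate_roles <- c("m", "h", "s", "m", "h", "s", "m", "h", "m", "h",
                 "m", "h", "m", "h", "m", "m", "m", "m")

#' Passive membrane parameters of the model GP neuron
#'
#' Total membrane capacitance (pF), leak conductance (nS) and leak reversal
#' potential (mV) of the single-compartment GP neuron.
#'
#' @param C capacitance in pF.
#' @param g_leak leak conductance in nS.
#' @param E_leak leak reversal potential in mV.
#' @return A named list of class `membrane_params`.
#' @export
#' @examples
#' gp_membrane_params()
gp_membrane_params <- function(C = 141.6, g_leak = 4.012, E_leak = -60.0) {
  stopifnot(C > 0, g_leak >= 0)
  structure(list(C = C, g_leak = g_leak, E_leak = E_leak),
            class = "membrane_params")
}

#' Intracellular calcium dynamics parameters
#'
#' Calcium in the model is a dimensionless activity variable driven by the
#' HVA current and cleared by a first-order pump:
#' `d[Ca]/dt = epsilon * (I_hva - k_ca * [Ca])`.
#'
#' @param epsilon buffering scale.
#' @param k_ca pump rate.
#' @return A named list of class `calcium_params`.
#' @export
gp_calcium_params <- function(epsilon = 1e-4, k_ca = 15.0) {
  stopifnot(epsilon > 0, k_ca > 0)
  structure(list(epsilon = epsilon, k_ca = k_ca), class = "calcium_params")
}

#' Load gate kinetics from a delimited text file
#'
#' One record per gate: channel, gate role (m/h/s), Boltzmann half-activation
#' voltage `v_half` (mV) and slope `slope` (mV; negative slope =
#' inactivation), and a sigmoidal voltage-dependent time constant
#' `tau(V) = tau_min + (tau_max - tau_min) / (1 + exp((V - v_tau)/sigma_tau))`
#' (ms).  The shipped default file is the package's calibrated set; a user
#' holding alternative kinetics can drop in their own file.
#'
#' @param path path to the kinetics CSV; defaults to the calibrated set
#'   shipped with the package.
#' @return A data.frame with one row per gate in canonical order.
#' @export
load_gate_kinetics <- function(path = system.file("extdata",
                                                  "gate_kinetics.csv",
                                                  package = "pallidalnet")) {
  kin <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("channel", "gate", "v_half", "slope", "tau_min", "tau_max",
              "v_tau", "sigma_tau")
  if (!all(needed %in% names(kin)))
    stop("kinetics file must have columns: ", paste(needed, collapse = ", "))
  key <- paste(kin$channel, kin$gate)
  want <- paste(.gate_channels, .gate_roles)
  idx <- match(want, key)
  if (anyNA(idx))
    stop("kinetics file is missing gates: ",
         paste(want[is.na(idx)], collapse = ", "))
  kin <- kin[idx, , drop = FALSE]
  rownames(kin) <- NULL
  bad <- kin$tau_min <= 0 | kin$tau_max <= 0
  if (any(bad))
    stop("non-positive time constants for gates: ",
         paste(want[bad], collapse = ", "))
  kin
}

# kinetics data.frame -> 18 x 6 numeric matrix for the engine
.kinetics_matrix <- function(kin) {
  as.matrix(kin[, c("v_half", "slope", "tau_min", "tau_max",
                    "v_tau", "sigma_tau")])
}

#' Channel specifications of the model GP neuron
#'
#' Returns the full set of channel specifications: name, maximal conductance
#' (nS, Table values), reversal potential (mV, by ion), integer gate
#' exponents and per-gate kinetics.
#'
#' @param kinetics gate kinetics data.frame as returned by
#'   [load_gate_kinetics()].
#' @param g_max optional named numeric vector overriding maximal
#'   conductances (e.g. `c(hcnf = 0, hcns = 0)` for an HCN blockade).
#' @return A named list of `channel_spec` objects.
#' @export
#' @examples
#' ch <- default_channels()
#' ch$nap$g_max
default_channels <- function(kinetics = load_gate_kinetics(), g_max = NULL) {
  specs <- lapply(seq_len(nrow(.channel_table)), function(i) {
    row <- .channel_table[i, ]
    gidx <- which(.gate_channels == row$name)
    kin <- kinetics[gidx, , drop = FALSE]
    rownames(kin) <- kin$gate
    g <- row$g_max
    if (!is.null(g_max) && row$name %in% names(g_max))
      g <- unname(g_max[[row$name]])
    stopifnot(g >= 0)
    structure(list(name = row$name, g_max = g, e_rev = row$e_rev,
                   mu = row$mu, rho = row$rho, phi = row$phi,
                   kinetics = kin),
              class = "channel_spec")
  })
  names(specs) <- .channel_table$name
  specs
}

#' Gate steady state and time constant
#'
#' `gate_steady_state` evaluates the Boltzmann steady state
#' `x_inf(V) = 1/(1 + exp((v_half - V)/slope))`; `gate_time_constant`
#' evaluates the sigmoidal voltage-dependent time constant.
#'
#' @param kin one row of a gate kinetics data.frame (or a list with the same
#'   fields).
#' @param v membrane potential in mV (vectorized).
#' @return Numeric vector.
#' @export
gate_steady_state <- function(kin, v) {
  1 / (1 + exp((kin$v_half - v) / kin$slope))
}

#' @rdname gate_steady_state
#' @export
gate_time_constant <- function(kin, v) {
  tau <- kin$tau_min + (kin$tau_max - kin$tau_min) /
    (1 + exp((v - kin$v_tau) / kin$sigma_tau))
  if (any(tau <= 0)) stop("non-positive gate time constant")
  tau
}

#' First-order gate relaxation derivative
#'
#' `dx/dt = (x_inf(V) - x) / tau(V)` in 1/ms.  The derivative drives the
#' gate value toward its voltage-dependent steady state, so any integration
#' respecting `tau > 0` keeps `x` in `[0, 1]`.
#'
#' @inheritParams gate_steady_state
#' @param x current gate value in `[0, 1]`.
#' @return Numeric vector, 1/ms.
#' @export
gate_derivative <- function(kin, x, v) {
  if (any(x < 0 | x > 1)) stop("gate value outside [0, 1]")
  (gate_steady_state(kin, v) - x) / gate_time_constant(kin, v)
}

#' Ionic current through one channel
#'
#' `I = m^mu * h^rho * s^phi * g_max * (E_rev - V)` in pA.  Gates with
#' exponent zero contribute a factor of one.
#'
#' @param spec a `channel_spec` (see [default_channels()]).
#' @param gates named list/vector with elements `m`, and `h`/`s` where the
#'   channel has those gates; values in `[0, 1]`.
#' @param v membrane potential in mV.
#' @return Current in pA (positive = depolarizing).
#' @export
#' @examples
#' ch <- default_channels()
#' channel_current(ch$kv3, c(m = 0.5, h = 1), v = -60)
channel_current <- function(spec, gates, v) {
  if (!inherits(spec, "channel_spec")) stop("unknown channel specification")
  gates <- as.list(gates)
  prod <- 1
  if (spec$mu > 0) {
    if (is.null(gates$m)) stop("channel ", spec$name, " requires gate m")
    if (gates$m < 0 || gates$m > 1) stop("gate value outside [0, 1]")
    prod <- prod * gates$m^spec$mu
  }
  if (spec$rho > 0) {
    if (is.null(gates$h)) stop("channel ", spec$name, " requires gate h")
    if (gates$h < 0 || gates$h > 1) stop("gate value outside [0, 1]")
    prod <- prod * gates$h^spec$rho
  }
  if (spec$phi > 0) {
    if (is.null(gates$s)) stop("channel ", spec$name, " requires gate s")
    if (gates$s < 0 || gates$s > 1) stop("gate value outside [0, 1]")
    prod <- prod * gates$s^spec$phi
  }
  prod * spec$g_max * (spec$e_rev - v)
}

#' Membrane potential derivative of the GP neuron
#'
#' `dV/dt = [g_leak (E_leak - V) + sum of channel currents + I_syn + I_ext]/C`
#' in mV/ms (pF, nS, mV unit system).  This is the reference (R)
#' implementation of the right-hand side; the compiled engine used by the
#' simulators evaluates the identical expression.
#'
#' @param state list with `V` (mV) and `gates` (named list per channel of
#'   named gate values).
#' @param params [gp_membrane_params()].
#' @param channels list of `channel_spec`s ([default_channels()]).
#' @param I_syn,I_ext synaptic and injected currents in pA.
#' @return dV/dt in mV/ms.
#' @export
membrane_rhs <- function(state, params, channels, I_syn = 0, I_ext = 0) {
  ich <- sum(vapply(channels, function(sp)
    channel_current(sp, state$gates[[sp$name]], state$V), numeric(1)))
  (params$g_leak * (params$E_leak - state$V) + ich + I_syn + I_ext) / params$C
}

#' Intracellular calcium derivative
#'
#' `d[Ca]/dt = epsilon * (I_hva - k_ca * [Ca])`.  Calcium is a dimensionless
#' activity variable; its fixed point under constant HVA current is
#' `I_hva / k_ca`.
#'
#' @param ca current calcium level (>= 0).
#' @param cap [gp_calcium_params()].
#' @param I_hva instantaneous HVA channel current (pA).
#' @return d\[Ca\]/dt.
#' @export
calcium_rhs <- function(ca, cap, I_hva) {
  stopifnot(all(ca >= 0))
  cap$epsilon * (I_hva - cap$k_ca * ca)
}

# neuron state helper: gates at steady state for a voltage
.steady_gates <- function(channels, v) {
  lapply(channels, function(sp) {
    g <- list()
    if (sp$mu > 0) g$m <- gate_steady_state(sp$kinetics["m", ], v)
    if (sp$rho > 0) g$h <- gate_steady_state(sp$kinetics["h", ], v)
    if (sp$phi > 0) g$s <- gate_steady_state(sp$kinetics["s", ], v)
    g
  })
}

#' Initial neuron state
#'
#' Membrane potential at `v`, every gate at its steady state for `v`,
#' calcium at `ca`.
#'
#' @param v initial membrane potential (mV).
#' @param ca initial calcium level.
#' @param channels channel specification list.
#' @return A list of class `neuron_state` with fields `V`, `gates`, `Ca`,
#'   `g_hcn_fast`, `g_hcn_slow`.
#' @export
neuron_state <- function(v = -60, ca = 0, channels = default_channels()) {
  structure(list(V = v, gates = .steady_gates(channels, v), Ca = ca,
                 g_hcn_fast = channels$hcnf$g_max,
                 g_hcn_slow = channels$hcns$g_max),
            class = "neuron_state")
}
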