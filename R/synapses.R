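#' Peak normalizer of a double-exponential conductance waveform
#'
#' The difference of two exponentials
#' \eqn{w(t) = e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}} peaks at
#' \eqn{t_p = \frac{\tau_{rise}\tau_{decay}}{\tau_{decay}-\tau_{rise}}
#' \ln(\tau_{decay}/\tau_{rise})}. The normalizer \eqn{k = 1/w(t_p)} scales
#' the waveform so a unit impulse produces a conductance transient whose peak
#' equals the configured peak conductance.
#'
#' @param tau_rise Rise time constant, ms (0 < `tau_rise` < `tau_decay`).
#' @param tau_decay Decay time constant, ms.
#' @return The dimensionless normalizer `k` (>= 1).
#' @examples
#' peak_normalizer(0.99, 1)  # ~270.5: nearly-equal time constants
#' peak_normalizer(1, 5)     # ~1.87
#' @export
peak_normalizer <- function(tau_rise, tau_decay) {
  if (any(tau_rise <= 0) || any(tau_rise >= tau_decay))
    stop("requires 0 < tau_rise < tau_decay (alpha-function limit not supported)")
  t_p <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  1 / (exp(-t_p / tau_decay) - exp(-t_p / tau_rise))
}

#' Double-exponential synapse parameters
#'
#' Conductance-based synapse whose waveform is the normalized difference of a
#' slow and a fast exponential trace: \eqn{g(t) = g_{peak}\,k\,(b - a)} with
#' \eqn{da/dt = -a/\tau_{rise}}, \eqn{db/dt = -b/\tau_{decay}} between spikes.
#' `k` is computed with [peak_normalizer()] so `g_peak` is the per-spike peak
#' conductance.
#'
#' @param g_peak Peak conductance, nS.
#' @param e_rev Reversal potential, mV.
#' @param tau_rise,tau_decay Trace time constants, ms (rise < decay).
#' @param delay Axonal delay, ms.
#' @return An object of class `"double_exp_params"`.
#' @export
double_exp_params <- function(g_peak = 2, e_rev = -75,
                              tau_rise = 0.99, tau_decay = 1, delay = 3) {
  k <- peak_normalizer(tau_rise, tau_decay)
  structure(list(g_peak = g_peak, e_rev = e_rev, tau_rise = tau_rise,
                 tau_decay = tau_decay, k = k, delay = delay),
            class = "double_exp_params")
}

#' Single-exponential synapse parameters
#'
#' @param g_peak Peak conductance, nS.
#' @param e_rev Reversal potential, mV.
#' @param tau Decay time constant, ms (> 0).
#' @param delay Axonal delay, ms.
#' @return An object of class `"single_exp_params"`.
#' @export
single_exp_params <- function(g_peak = 0, e_rev = 0, tau = 1, delay = 1) {
  if (tau <= 0) stop("`tau` must be positive")
  structure(list(g_peak = g_peak, e_rev = e_rev, tau = tau, delay = delay),
            class = "single_exp_params")
}

#' Fresh synapse trace state
#'
#' @param params A `double_exp_params` or `single_exp_params` object.
#' @param n Number of postsynaptic units.
#' @return For double-exponential synapses a list with traces `a` (fast) and
#'   `b` (slow); for single-exponential a list with trace `a`.
#' @export
synapse_state <- function(params, n = 1L) {
  if (inherits(params, "double_exp_params"))
    structure(list(a = numeric(n), b = numeric(n)), class = "double_exp_state")
  else
    structure(list(a = numeric(n)), class = "single_exp_state")
}

#' Decay synapse traces over one step
#'
#' Traces obey linear homogeneous ODEs between spikes, so they are propagated
#' exactly: each trace is multiplied by `exp(-dt/tau)`. Composing two half
#' steps therefore equals one full step to machine precision, independent of
#' the membrane solver in use.
#'
#' @param state A state from [synapse_state()].
#' @param params The matching parameter object.
#' @param dt Step size, ms (> 0).
#' @return The decayed state.
#' @export
synapse_decay <- function(state, params, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  if (inherits(state, "double_exp_state")) {
    state$a <- state$a * exp(-dt / params$tau_rise)
    state$b <- state$b * exp(-dt / params$tau_decay)
  } else {
    state$a <- state$a * exp(-dt / params$tau)
  }
  state
}

#' Deliver spikes to a synapse
#'
#' Each arriving spike increments the trace(s) by `increment` (default 1, the
#' unit-increment convention under which `g_peak` is the per-spike peak
#' conductance). Simultaneous spikes superpose additively.
#'
#' @param state A state from [synapse_state()].
#' @param count Number of spikes arriving at each postsynaptic unit
#'   (scalar or vector).
#' @param increment Trace increment per spike.
#' @return The updated state.
#' @export
apply_spike <- function(state, count = 1, increment = 1) {
  state$a <- state$a + count * increment
  if (inherits(state, "double_exp_state"))
    state$b <- state$b + count * increment
  state
}

#' Instantaneous synaptic current
#'
#' `g_peak * k * (b - a) * (e_rev - v)` for double-exponential synapses and
#' `g_peak * a * (e_rev - v)` for single-exponential ones. With conductance in
#' nS and voltage in mV the result is in pA.
#'
#' @param state A state from [synapse_state()].
#' @param params The matching parameter object.
#' @param v Postsynaptic membrane potential, mV.
#' @return Current in pA (positive = depolarizing).
#' @export
synaptic_current <- function(state, params, v) {
  synaptic_conductance(state, params) * (params$e_rev - v)
}

#' Instantaneous synaptic conductance
#'
#' @inheritParams synaptic_current
#' @return Conductance in nS.
#' @export
synaptic_conductance <- function(state, params) {
  if (inherits(state, "double_exp_state"))
    params$g_peak * params$k * (state$b - state$a)
  else
    params$g_peak * state$a
}

#' Delta-synapse weight
#'
#' In the LIF network a synapse is an instantaneous membrane-potential jump
#' `g` (mV; sign encodes excitation or inhibition) delivered `d` ms after the
#' presynaptic spike.
#'
#' @param g Voltage jump, mV.
#' @param d Axonal delay, ms.
#' @return An object of class `"delta_weight"`.
#' @export
delta_weight <- function(g, d) {
  structure(list(g = g, d = d), class = "delta_weight")
}
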