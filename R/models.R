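#' Leaky integrate-and-fire membrane parameters
#'
#' Parameters of the leaky integrate-and-fire (LIF) neuron
#' \deqn{dv/dt = -v/\tau + \sum_j g\,\delta(t - t'_j - d),}
#' with threshold-and-reset: whenever \eqn{v > \theta}, the membrane is reset
#' to \eqn{v_r} and the neuron is refractory for `t_ref` milliseconds.
#'
#' All fields may be scalars or per-neuron vectors (recycled against the state).
#'
#' @param tau Membrane time constant, ms. Must be positive.
#' @param theta Spike threshold, mV. Must exceed `v_reset`.
#' @param v_reset Reset potential, mV.
#' @param t_ref Absolute refractory period, ms (>= 0).
#' @return An object of class `"lif_params"` (a named list).
#' @examples
#' p <- lif_params(tau = 10, theta = 1, v_reset = 0, t_ref = 5.01)
#' @export
lif_params <- function(tau = 10, theta = 1, v_reset = 0, t_ref = 5.01) {
  if (any(tau <= 0)) stop("`tau` must be positive")
  if (any(theta <= v_reset)) stop("`theta` must exceed `v_reset`")
  if (any(t_ref < 0)) stop("`t_ref` must be non-negative")
  structure(list(tau = tau, theta = theta, v_reset = v_reset, t_ref = t_ref),
            class = "lif_params")
}

#' Leaky integrate-and-fire membrane state
#'
#' @param n Number of neurons.
#' @param v Initial membrane potential(s), mV (recycled to length `n`).
#' @return A list with fields `v`, `last_spike`, `refractory_until`
#'   (class `"lif_state"`). Fresh neurons have never spiked
#'   (`last_spike = -Inf`) and are not refractory.
#' @export
lif_state <- function(n = 1L, v = 0) {
  structure(list(v = rep_len(v, n),
                 last_spike = rep(-Inf, n),
                 refractory_until = rep(-Inf, n)),
            class = "lif_state")
}

#' Advance LIF membranes by one fixed time step
#'
#' Exact exponential propagation of the leak over one step of length `dt`,
#' followed by delivery of the accumulated delta-synapse jump and the
#' threshold/reset/refractory bookkeeping. The step ends at time `t`; delta
#' inputs land at the end of the step (after the decay), spikes are stamped
#' with time `t`, and a neuron that spiked at `t'` becomes eligible again at
#' the first step boundary at or after `t' + t_ref` (refractory expiry is
#' continuous-time, not snapped to the grid).
#'
#' Two refractory semantics are supported. In `"clamp"` mode (default) the
#' membrane is held at `v_reset` while refractory and incoming jumps are
#' discarded. In `"integrate"` mode the membrane keeps integrating inputs but
#' the threshold is disabled until expiry.
#'
#' @param state A [lif_state()] (all fields vectors of equal length).
#' @param params A [lif_params()].
#' @param dt Step size, ms (> 0).
#' @param input_jump Summed delta-synapse weights delivered at this boundary,
#'   mV (scalar or per-neuron vector).
#' @param t Time of the boundary reached by this step, ms.
#' @param refractory_mode `"clamp"` or `"integrate"`.
#' @return A list with the updated `state` and a logical vector `spiked`.
#' @examples
#' st <- lif_state(1, v = 0.5)
#' lif_step(st, lif_params(), dt = 0.1, input_jump = 0, t = 0.1)
#' @export
lif_step <- function(state, params, dt, input_jump = 0, t = 0,
                     refractory_mode = c("clamp", "integrate")) {
  refractory_mode <- match.arg(refractory_mode)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  n <- length(state$v)
  refrac <- t < state$refractory_until
  v <- state$v * exp(-dt / params$tau) + input_jump
  if (refractory_mode == "clamp") {
    v[refrac] <- rep_len(params$v_reset, n)[refrac]
  } else {
    # integrate mode: membrane evolves normally, threshold disabled below
  }
  spiked <- !refrac & (v > params$theta)
  if (any(spiked)) {
    v[spiked] <- rep_len(params$v_reset, n)[spiked]
    state$last_spike[spiked] <- t
    state$refractory_until[spiked] <- t + rep_len(params$t_ref, n)[spiked]
  }
  state$v <- v
  list(state = state, spiked = spiked)
}

#' Hodgkin-Huxley membrane parameters
#'
#' Classical single-compartment Hodgkin-Huxley parameters in the modern
#' shifted-voltage convention (rest near -65 mV). Conductances are densities
#' (mS/cm^2), potentials are mV, capacitance is uF/cm^2 and the injected
#' current `i_inj` is a density (uA/cm^2). `area` (cm^2) converts absolute
#' synaptic conductances in nS into densities; the default 1e-4 cm^2
#' corresponds to a 100 pF cell at c = 1 uF/cm^2.
#'
#' @param g_na,g_k,g_l Maximal sodium, potassium, leak conductances, mS/cm^2.
#' @param e_na,e_k,e_l Reversal potentials, mV.
#' @param c Membrane capacitance, uF/cm^2 (> 0).
#' @param i_inj Injected current density, uA/cm^2.
#' @param area Membrane area, cm^2 (> 0).
#' @return An object of class `"hh_params"`.
#' @export
hh_params <- function(g_na = 120, g_k = 36, g_l = 0.3,
                      e_na = 50, e_k = -77, e_l = -54.4,
                      c = 1, i_inj = 0, area = 1e-4) {
  if (c <= 0) stop("`c` must be positive")
  if (area <= 0) stop("`area` must be positive")
  if (any(c(g_na, g_k, g_l) < 0)) stop("conductances must be non-negative")
  structure(list(g_na = g_na, g_k = g_k, g_l = g_l,
                 e_na = e_na, e_k = e_k, e_l = e_l,
                 c = c, i_inj = i_inj, area = area),
            class = "hh_params")
}

#' Hodgkin-Huxley state at a given voltage
#'
#' Builds a state with gating variables at their voltage-dependent steady
#' state, the usual way conductance-based simulations are initialized.
#'
#' @param v Membrane potential(s), mV.
#' @return A list with fields `v`, `m`, `h`, `n` (class `"hh_state"`).
#' @export
hh_state <- function(v = -65) {
  ss <- gating_steady_state(v)
  structure(list(v = v, m = ss$m_inf, h = ss$h_inf, n = ss$n_inf),
            class = "hh_state")
}

# Quotient-form rate with a removable singularity at denom = 0; the analytic
# limit is substituted when |denom| < 1e-7.
.rate_quotient <- function(num, denom, limit) {
  out <- num / denom
  sing <- abs(denom) < 1e-7
  if (any(sing)) out[sing] <- limit
  out
}

#' Classical Hodgkin-Huxley rate functions
#'
#' The six voltage-dependent opening/closing rates of the gating variables
#' (m: sodium activation, h: sodium inactivation, n: potassium activation) in
#' the shifted-voltage convention with rest near -65 mV:
#' \deqn{\alpha_m = 0.1(v+40)/(1 - e^{-(v+40)/10}),\quad \beta_m = 4e^{-(v+65)/18}}
#' \deqn{\alpha_h = 0.07e^{-(v+65)/20},\quad \beta_h = 1/(1 + e^{-(v+35)/10})}
#' \deqn{\alpha_n = 0.01(v+55)/(1 - e^{-(v+55)/10}),\quad \beta_n = 0.125e^{-(v+65)/80}}
#' The removable singularities of the quotient forms (at v = -40 and v = -55)
#' are evaluated by their analytic limits (1.0 and 0.1).
#'
#' @param v Membrane potential, mV (vectorized; must be finite).
#' @return A list of six numeric vectors `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, in 1/ms.
#' @examples
#' hh_rates(-40)$alpha_m  # exactly 1 (removable singularity)
#' @export
hh_rates <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("`v` must be finite")
  list(
    alpha_m = .rate_quotient(0.1 * (v + 40), 1 - exp(-(v + 40) / 10), 1.0),
    beta_m  = 4 * exp(-(v + 65) / 18),
    alpha_h = 0.07 * exp(-(v + 65) / 20),
    beta_h  = 1 / (1 + exp(-(v + 35) / 10)),
    alpha_n = .rate_quotient(0.01 * (v + 55), 1 - exp(-(v + 55) / 10), 0.1),
    beta_n  = 0.125 * exp(-(v + 65) / 80)
  )
}

#' Steady-state gating values
#'
#' \eqn{x_\infty(v) = \alpha_x(v) / (\alpha_x(v) + \beta_x(v))} for each gating
#' variable. Used to initialize states and by the exponential-Euler solver.
#'
#' @param v Membrane potential, mV (vectorized; must be finite).
#' @return A list with `m_inf`, `h_inf`, `n_inf`, each in (0, 1).
#' @export
gating_steady_state <- function(v) {
  r <- hh_rates(v)
  list(m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
       h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
       n_inf = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' Time derivatives of the Hodgkin-Huxley state
#'
#' Right-hand side of the conductance-based point-neuron model
#' \deqn{c\,dv/dt = g_{Na} m^3 h (E_{Na}-v) + g_K n^4 (E_K-v) + g_L(E_L-v)
#'   + I + g_{syn,i}(E_i - v) + g_{syn,e}(E_e - v)}
#' plus first-order kinetics for m, h, n. Synaptic conductances are passed as
#' instantaneous absolute values in nS and divided by the membrane area to
#' obtain densities.
#'
#' @param state An [hh_state()] (fields may be vectors over neurons).
#' @param params An [hh_params()].
#' @param syn Optional list with instantaneous synaptic terms:
#'   `g_inh` (nS), `e_inh` (mV), `g_exc` (nS), `e_exc` (mV). Missing entries
#'   default to zero conductance.
#' @param rates Optional precomputed [hh_rates()] at `state$v` (an
#'   optimization hook for table-backed rates); computed if `NULL`.
#' @return A list `dv`, `dm`, `dh`, `dn` of time derivatives (mV/ms, 1/ms).
#' @export
hh_derivatives <- function(state, params, syn = NULL, rates = NULL) {
  v <- state$v; m <- state$m; h <- state$h; n <- state$n
  if (is.null(rates)) rates <- hh_rates(v)
  i_ion <- params$g_na * m^3 * h * (params$e_na - v) +
    params$g_k * n^4 * (params$e_k - v) +
    params$g_l * (params$e_l - v)
  i_syn <- 0
  if (!is.null(syn)) {
    nS_to_density <- 1e-6 / params$area   # nS -> mS, then per cm^2
    if (!is.null(syn$g_inh))
      i_syn <- i_syn + syn$g_inh * nS_to_density * (syn$e_inh - v)
    if (!is.null(syn$g_exc))
      i_syn <- i_syn + syn$g_exc * nS_to_density * (syn$e_exc - v)
  }
  list(dv = (i_ion + params$i_inj + i_syn) / params$c,
       dm = rates$alpha_m * (1 - m) - rates$beta_m * m,
       dh = rates$alpha_h * (1 - h) - rates$beta_h * h,
       dn = rates$alpha_n * (1 - n) - rates$beta_n * n)
}
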