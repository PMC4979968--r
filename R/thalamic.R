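#' Thalamic neuron parameters
#'
#' Parameter set for one thalamic nucleus of integrate-and-fire-or-burst
#' (IFB) neurons: a conductance-based leaky integrate-and-fire cell augmented
#' with a slow de-inactivation variable `h` gating a T-type calcium current.
#' Defaults reproduce the three nuclei of the thalamo-cortical module: the
#' specific relay nucleus (SP), the non-specific/intralaminar nucleus (NSP)
#' and the inhibitory reticular nucleus (TRN). The nuclei share all constants
#' except the T-channel switch threshold `V_h` (-66 mV for SP/NSP, -64 mV for
#' TRN) and the inactivation time constant `tau_h_minus` (20 ms SP/NSP,
#' 40 ms TRN).
#'
#' @param nucleus One of `"SP"`, `"NSP"`, `"TRN"`.
#' @param n Number of neurons in the nucleus.
#' @param E_T Calcium driving reversal potential (mV). The T-current drives
#'   the membrane toward this strongly depolarised value whenever the cell is
#'   above the switch threshold with de-inactivated channels.
#' @return A list of class `thalamic_params` with fields `C` (membrane
#'   capacitance, uF/cm^2), `g_L`/`V_L` (leak conductance mS/cm^2 and reversal
#'   mV), `g_T` (T-channel conductance), `V_h` (activation/inactivation switch
#'   threshold, mV), `E_T`, `V_0` (spike threshold), `V_reset`, `V_E`/`V_I`
#'   (synaptic reversals), `tau_h_minus`/`tau_h_plus` (h decay/recovery, ms),
#'   `k_E`/`k_I` (synaptic gains) and `n`.
#' @export
thalamic_params <- function(nucleus = c("SP", "NSP", "TRN"), n = 100L,
                            E_T = 120) {
  nucleus <- match.arg(nucleus)
  p <- list(
    nucleus = nucleus,
    n = as.integer(n),
    C = 2,
    g_L = 0.035,
    V_L = -65,
    g_T = 0.07,
    V_h = if (nucleus == "TRN") -64 else -66,
    E_T = E_T,
    V_0 = -35,
    V_reset = -50,
    V_E = 0,
    V_I = -85,
    tau_h_minus = if (nucleus == "TRN") 40 else 20,
    tau_h_plus = 100,
    k_E = 1,
    k_I = 0.1
  )
  stopifnot(p$g_L >= 0, p$g_T >= 0, p$V_reset < p$V_0,
            p$tau_h_minus > 0, p$tau_h_plus > 0,
            p$V_I < p$V_L, p$V_L < p$V_E)
  class(p) <- "thalamic_params"
  p
}

#' Initial state of a thalamic population
#'
#' @param params A [thalamic_params()] object.
#' @param V0 Initial membrane potential (mV), recycled over neurons.
#' @param h0 Initial T-channel de-inactivation level in `[0, 1]`.
#' @return List of class `thalamic_state` with vectors `V`, `h`, `g_E`,
#'   `g_I` and logical `spike_flags`.
#' @export
thalamic_state <- function(params, V0 = params$V_L, h0 = 0) {
  n <- params$n
  st <- list(V = rep_len(V0, n), h = rep_len(h0, n),
             g_E = numeric(n), g_I = numeric(n),
             spike_flags = logical(n))
  class(st) <- "thalamic_state"
  st
}

#' T-type calcium current
#'
#' `I_T = g_T * m_inf(V) * h * (V - E_T)` with a Heaviside activation
#' `m_inf(V) = 1` for `V > V_h`, else 0. With `E_T` far above rest the term
#' is negative (inward) whenever active, so subtracting it in the membrane
#' equation depolarises the cell: this is the depolarising ramp of a
#' low-threshold calcium spike.
#'
#' @param V Membrane potential(s), mV.
#' @param h De-inactivation level(s) in `[0, 1]`.
#' @param params A [thalamic_params()] object.
#' @return Current density (same sign convention as the leak term), vectorised.
#' @export
t_current <- function(V, h, params) {
  if (any(!is.finite(V)) || any(!is.finite(h)))
    stop("t_current: non-finite membrane potential or h")
  if (any(h < 0 | h > 1)) stop("t_current: h outside [0, 1]")
  params$g_T * as.numeric(V > params$V_h) * h * (V - params$E_T)
}

#' Advance the T-channel de-inactivation variable one step
#'
#' Forward-Euler step of the two-branch linear relaxation: above the switch
#' threshold `V_h` the channel inactivates, `dh/dt = -h / tau_h_minus`; below
#' it the channel de-inactivates, `dh/dt = (1 - h) / tau_h_plus`. The result
#' is clamped to `[0, 1]`.
#'
#' @param h Current level(s) in `[0, 1]`.
#' @param V Membrane potential(s) governing the branch choice.
#' @param dt Step size, ms (> 0).
#' @param params A [thalamic_params()] object.
#' @return Updated `h`, clamped to `[0, 1]`.
#' @export
update_h <- function(h, V, dt, params) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("update_h: dt must be a positive scalar")
  stopifnot(all(h >= 0), all(h <= 1))
  dh <- ifelse(V > params$V_h, -h / params$tau_h_minus,
               (1 - h) / params$tau_h_plus)
  pmin(pmax(h + dt * dh, 0), 1)
}

#' Advance a synaptic conductance one step
#'
#' Euler step of `dg/dt = -g / tau_s + gain * sum_j W_ij s_j`: exponential
#' decay plus an instantaneous increment from the weighted presynaptic spikes
#' arriving this step (already delayed by the caller).
#'
#' @param g Conductance(s), mS, non-negative.
#' @param tau_s Decay time constant, ms (> 0).
#' @param gain Synaptic gain multiplying the weighted spike sum.
#' @param weighted_spike_sum `sum_j W_ij s_j` for each target neuron.
#' @param dt Step size, ms.
#' @return Updated conductance(s), non-negative.
#' @export
decay_conductance <- function(g, tau_s, gain, weighted_spike_sum, dt = 1) {
  stopifnot(all(g >= 0), tau_s > 0, dt > 0)
  pmax(g * (1 - dt / tau_s) + gain * weighted_spike_sum, 0)
}

#' One integration step of a thalamic population
#'
#' Advances the IFB membrane equation
#' `C dV/dt = -g_L (V - V_L) - g_E (V - V_E) - g_I (V - V_I) - I_T`
#' by forward Euler: leak, excitatory and inhibitory conductance inputs
#' pulling toward their reversals, and the T-type calcium current. Neurons
#' reaching the spike threshold `V_0` emit a spike and reset to `V_reset`;
#' `h` relaxes per [update_h()] using the potential at step start. The
#' synaptic conductances themselves are advanced by the caller (they are
#' per-projection quantities; this function consumes their summed value in
#' `state$g_E` / `state$g_I`).
#'
#' @param state A [thalamic_state()].
#' @param params A [thalamic_params()].
#' @param dt Step size, ms (1 ms in the standard protocol).
#' @return The updated state; `state$spike_flags` marks neurons that fired.
#' @export
step_thalamic <- function(state, params, dt = 1) {
  V <- state$V
  if (any(!is.finite(V)) || any(!is.finite(state$h)))
    stop("step_thalamic: non-finite state")
  I_T <- t_current(V, state$h, params)
  I_L <- params$g_L * (V - params$V_L)
  I_syn <- state$g_E * (V - params$V_E) + state$g_I * (V - params$V_I)
  V_new <- V + dt / params$C * (-I_L - I_syn - I_T)
  spikes <- V_new >= params$V_0
  V_new[spikes] <- params$V_reset
  state$h <- update_h(state$h, V, dt, params)
  state$V <- V_new
  state$spike_flags <- spikes
  state
}
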