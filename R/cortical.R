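#' Cortical neuron parameters
#'
#' Per-neuron parameter arrays for the quadratic integrate-and-fire
#' (Izhikevich) cortical sheet: 800 regular-spiking excitatory cells and 200
#' fast-spiking inhibitory interneurons by default. Heterogeneity enters
#' through a per-neuron uniform(0,1) draw `r`: excitatory cells have
#' `c = -65 + 15 r^2` and `d = 8 - 6 r^2`; inhibitory cells have
#' `a = 0.02 + 0.08 r` and `b = 0.25 - 0.05 r`. The constant intrinsic drive
#' (`I = 6.7` excitatory, `2.7` inhibitory) puts every cell above rheobase so
#' the isolated sheet is spontaneously active.
#'
#' @param n_exc,n_inh Population sizes.
#' @param I_E,I_I Constant intrinsic drive for excitatory and inhibitory cells.
#' @param r Optional per-neuron uniform(0,1) heterogeneity vector of length
#'   `n_exc + n_inh`; drawn from the current RNG state when `NULL`.
#' @return List of class `cortical_params` with per-neuron vectors `a`, `b`,
#'   `c`, `d`, `I_intrinsic`, the draw `r`, logical `is_exc`, and
#'   `spike_cutoff` (30 mV).
#' @export
cortical_params <- function(n_exc = 800L, n_inh = 200L,
                            I_E = 6.7, I_I = 2.7, r = NULL) {
  n <- n_exc + n_inh
  if (is.null(r)) r <- stats::runif(n)
  stopifnot(length(r) == n, all(r >= 0), all(r <= 1))
  is_exc <- c(rep(TRUE, n_exc), rep(FALSE, n_inh))
  re <- r[is_exc]; ri <- r[!is_exc]
  p <- list(
    n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
    a = c(rep(0.02, n_exc), 0.02 + 0.08 * ri),
    b = c(rep(0.2, n_exc), 0.25 - 0.05 * ri),
    c = c(-65 + 15 * re^2, rep(-65, n_inh)),
    d = c(8 - 6 * re^2, rep(2, n_inh)),
    I_intrinsic = c(rep(I_E, n_exc), rep(I_I, n_inh)),
    r = r,
    is_exc = is_exc,
    spike_cutoff = 30
  )
  class(p) <- "cortical_params"
  p
}

#' Initial state of the cortical population
#'
#' Standard initialisation of the quadratic model: `v = -65` mV,
#' `u = b * v`.
#'
#' @param params A [cortical_params()] object.
#' @param v0 Initial membrane potential (mV).
#' @return List of class `cortical_state` with vectors `v`, `u`,
#'   `I_syn_decaying` (decaying thalamic afferent current), `I_pulse`
#'   (instantaneous cortico-cortical input accumulated for this step) and
#'   logical `spike_flags`.
#' @export
cortical_state <- function(params, v0 = -65) {
  n <- params$n_exc + params$n_inh
  st <- list(v = rep_len(v0, n), u = params$b * rep_len(v0, n),
             I_syn_decaying = numeric(n), I_pulse = numeric(n),
             spike_flags = logical(n))
  class(st) <- "cortical_state"
  st
}

#' One integration step of the cortical population
#'
#' Advances `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and `du/dt = a (b v - u)`
#' with total input `I = I_intrinsic + I_syn_decaying + I_pulse + I_extra`.
#' The membrane potential takes two 0.5*dt half-steps per full step (the
#' standard treatment of the quadratic model's stiffness); the recovery
#' variable takes one full step. Cells reaching 30 mV spike and reset
#' (`v <- c`, `u <- u + d`). `I_pulse` is cleared after use: instantaneous
#' cortico-cortical pulses must be re-accumulated by the caller each step.
#'
#' @param state A [cortical_state()].
#' @param params A [cortical_params()].
#' @param dt Step size, ms.
#' @param I_extra Additional per-neuron current (e.g. the post-lesion GABA
#'   ramp), recycled.
#' @return Updated state with `spike_flags` marking cells that fired.
#' @export
step_cortical <- function(state, params, dt = 1, I_extra = 0) {
  v <- state$v; u <- state$u
  if (any(!is.finite(v)) || any(!is.finite(u)))
    stop("step_cortical: non-finite state")
  I <- params$I_intrinsic + state$I_syn_decaying + state$I_pulse + I_extra
  half <- dt / 2
  v <- v + half * (0.04 * v^2 + 5 * v + 140 - u + I)
  v <- v + half * (0.04 * v^2 + 5 * v + 140 - u + I)
  u <- u + dt * params$a * (params$b * v - u)
  spikes <- v >= params$spike_cutoff
  v[spikes] <- params$c[spikes]
  u[spikes] <- u[spikes] + params$d[spikes]
  state$v <- v
  state$u <- u
  state$I_pulse <- numeric(length(v))
  state$spike_flags <- spikes
  state
}
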