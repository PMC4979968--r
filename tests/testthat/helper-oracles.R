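# Reference (oracle) integrators, independent of the package's steppers.

# Fine-step reference for a single IFB thalamic neuron under prescribed
# conductance traces gE(t), gI(t) (functions of time in ms).
ref_thalamic <- function(params, duration, dt = 0.01, gE = function(t) 0,
                         gI = function(t) 0, V0 = params$V_L, h0 = 0) {
  n <- round(duration / dt)
  V <- V0; h <- h0; spikes <- numeric(0)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    IT <- if (V > params$V_h) params$g_T * h * (V - params$E_T) else 0
    IL <- params$g_L * (V - params$V_L)
    Isyn <- gE(t) * (V - params$V_E) + gI(t) * (V - params$V_I)
    Vn <- V + dt / params$C * (-IL - Isyn - IT)
    dh <- if (V > params$V_h) -h / params$tau_h_minus else
      (1 - h) / params$tau_h_plus
    h <- min(max(h + dt * dh, 0), 1)
    if (Vn >= params$V_0) { spikes <- c(spikes, t); Vn <- params$V_reset }
    V <- Vn
  }
  list(V = V, h = h, spikes = spikes)
}

# Fine-step reference for a single Izhikevich cell at constant drive.
ref_izhikevich <- function(I, duration, dt = 0.01, a = 0.02, b = 0.2,
                           c = -65, d = 8, v0 = -65) {
  n <- round(duration / dt)
  v <- v0; u <- b * v0; count <- 0L
  for (i in seq_len(n)) {
    v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * a * (b * v - u)
    if (v >= 30) { v <- c; u <- u + d; count <- count + 1L }
  }
  list(count = count, v = v, u = u)
}

# Short protocol for fast lesion-experiment tests (10 s, lesion at 5 s:
# the shortest windows the 1 Hz wavelet's support still fits into).
quick_config <- function(...) {
  sim_config(duration = 10000, lesion_time = 5000, ...)
}
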