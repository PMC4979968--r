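#' Simulation protocol configuration
#'
#' The standard protocol integrates the network for 20 s of model time at
#' 1 ms steps and deafferents a contiguous 30% block of the cortical sheet
#' at t = 10 s. Optionally a slow-onset constant inhibitory current mimics
#' the post-ischaemic rise in extrasynaptic GABA.
#'
#' @param duration Total simulated time, ms.
#' @param dt Integration step, ms.
#' @param lesion_time Lesion onset, ms (must be < `duration`).
#' @param lesion_fraction Fraction of each cortical subpopulation
#'   deafferented, in `[0, 1)`. 0 disables the lesion.
#' @param lesion_anchor Start index (0-based) of the lesioned excitatory
#'   block; the inhibitory block is the aligned `anchor/4` position.
#' @param gaba_enabled Apply the post-lesion inhibitory current.
#' @param gaba_amplitude Plateau magnitude of that current (model current
#'   units, applied negatively). A calibration parameter: the default is set
#'   by [calibrate_gaba()] so the with-GABA cortical spectrum diverges below
#'   the lesion-only spectrum from roughly 23 Hz upward.
#' @param gaba_ramp Linear onset duration, ms.
#' @param n_runs Cohort size for [run_cohort()].
#' @param peak_bounds Pre-lesion dominant-peak acceptance bounds (Hz) for the
#'   cohort omission rule (the healthy control group's min/max peak
#'   frequencies).
#' @param i_jitter_sd Length-2 vector: s.d. of the per-step Gaussian jitter
#'   added to the intrinsic cortical drive of excitatory and inhibitory
#'   cells. Set to 0 to make the cortical drive purely deterministic.
#' @param I_E,I_I Constant intrinsic drive of excitatory and inhibitory
#'   cortical cells. The excitatory default is the calibration result of the
#'   healthy-state procedure (choose the drive so the intact network's
#'   cortical power spectrum peaks at the healthy dominant-alpha frequency;
#'   see the methods vignette and [calibrate_cortex()]).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(duration = 20000, dt = 1, lesion_time = 10000,
                       lesion_fraction = 0.30, lesion_anchor = 0L,
                       gaba_enabled = FALSE, gaba_amplitude = 1.5,
                       gaba_ramp = 1000, n_runs = 40L,
                       peak_bounds = c(8.3, 11.9),
                       i_jitter_sd = c(2, 2), I_E = 4.4, I_I = 2.7) {
  stopifnot(lesion_fraction >= 0, lesion_fraction < 1,
            lesion_time < duration, dt > 0, gaba_ramp > 0,
            length(i_jitter_sd) == 2, all(i_jitter_sd >= 0))
  structure(list(duration = duration, dt = dt, lesion_time = lesion_time,
                 lesion_fraction = lesion_fraction,
                 lesion_anchor = as.integer(lesion_anchor),
                 gaba_enabled = gaba_enabled,
                 gaba_amplitude = gaba_amplitude, gaba_ramp = gaba_ramp,
                 n_runs = as.integer(n_runs), peak_bounds = peak_bounds,
                 i_jitter_sd = i_jitter_sd, I_E = I_E, I_I = I_I),
            class = "sim_config")
}

#' Lesion mask over the cortical population
#'
#' Contiguous aligned blocks: `floor(fraction * 800)` excitatory cells
#' starting at `anchor` and `floor(fraction * 200)` inhibitory cells starting
#' at the aligned position `anchor / 4`.
#'
#' @param fraction Lesion fraction in `[0, 1)`.
#' @param anchor 0-based start index within the excitatory population.
#' @param n_exc,n_inh Cortical subpopulation sizes.
#' @return Logical vector over the `n_exc + n_inh` cortical cells
#'   (excitatory first).
#' @export
lesion_mask <- function(fraction, anchor = 0L, n_exc = 800L, n_inh = 200L) {
  stopifnot(fraction >= 0, fraction < 1)
  mask <- logical(n_exc + n_inh)
  ne <- floor(fraction * n_exc)
  ni <- floor(fraction * n_inh)
  ai <- anchor %/% 4L
  if (anchor + ne > n_exc || ai + ni > n_inh)
    stop("lesion block exceeds the cortical population")
  if (ne > 0) mask[(anchor + 1L):(anchor + ne)] <- TRUE
  if (ni > 0) mask[n_exc + (ai + 1L):(ai + ni)] <- TRUE
  mask
}

#' Apply a structural lesion to a topology
#'
#' Deafferents a contiguous block of cortical neurons: every afferent and
#' efferent edge of a lesioned cell is removed from the realized projections.
#' Peripheral Poisson drives onto the thalamus are untouched. The implicit
#' cortico-cortical coupling is handled by the simulator through the mask.
#'
#' @param topology A [build_network()] result.
#' @param fraction Lesion fraction in `[0, 1)`.
#' @param anchor 0-based start index of the excitatory block.
#' @return New topology with pruned edges and `lesion_mask` set.
#' @export
apply_lesion <- function(topology, fraction, anchor = 0L) {
  mask <- lesion_mask(fraction, anchor,
                      topology$sizes[["E"]], topology$sizes[["I"]])
  n_exc <- topology$sizes[["E"]]
  topology$projections <- lapply(topology$projections, function(sp) {
    if (is.null(sp$edges)) return(sp)
    src_les <- switch(sp$source,
      E = mask[sp$edges$src], I = mask[n_exc + sp$edges$src],
      CRX = mask[sp$edges$src], rep(FALSE, nrow(sp$edges)))
    tgt_les <- switch(sp$target,
      E = mask[sp$edges$tgt], I = mask[n_exc + sp$edges$tgt],
      CRX = mask[sp$edges$tgt], rep(FALSE, nrow(sp$edges)))
    sp$edges <- sp$edges[!(src_les | tgt_les), , drop = FALSE]
    rownames(sp$edges) <- NULL
    sp
  })
  topology$lesion_mask <- mask
  topology
}

#' Post-lesion inhibitory (GABA) current
#'
#' Zero before the lesion; ramps linearly from 0 to `-gaba_amplitude` over
#' `gaba_ramp` ms after lesion onset; constant thereafter. Applied by the
#' simulator to all non-lesioned cortical neurons when `gaba_enabled`.
#'
#' @param t Time(s) since simulation start, ms.
#' @param config A [sim_config()].
#' @return Current value(s) (non-positive).
#' @export
gaba_current <- function(t, config) {
  stopifnot(all(t >= 0))
  if (!config$gaba_enabled) return(rep(0, length(t)))
  el <- pmax(t - config$lesion_time, 0)
  -config$gaba_amplitude * pmin(el / config$gaba_ramp, 1)
}

# Assemble the per-run random inputs (topology, heterogeneity, Poisson
# drives) from one seed, so R and C++ steppers consume identical data.
prepare_run <- function(config, topology = NULL, seed = 1L) {
  n_steps <- as.integer(round(config$duration / config$dt))
  set.seed(seed)
  if (is.null(topology)) topology <- build_network(seed = NULL)
  crx <- cortical_params(I_E = config$I_E, I_I = config$I_I)
  drive_sp <- poisson_drive(0.5, topology$sizes[["SP"]], n_steps)
  drive_nsp <- poisson_drive(0.35, topology$sizes[["NSP"]], n_steps)
  mask <- if (config$lesion_fraction > 0)
    lesion_mask(config$lesion_fraction, config$lesion_anchor,
                topology$sizes[["E"]], topology$sizes[["I"]])
  else logical(topology$sizes[["CRX"]])
  gaba <- gaba_current((seq_len(n_steps) - 1) * config$dt, config)
  list(topology = topology, crx = crx, drive_sp = drive_sp,
       drive_nsp = drive_nsp, mask = mask, gaba = gaba, n_steps = n_steps)
}

# Edge projections in the flat form the C++ engine expects.
edge_projections <- function(topology) {
  keep <- Filter(function(sp) !is.null(sp$edges), topology$projections)
  lapply(keep, function(sp) {
    list(source = sp$source, target = sp$target, polarity = sp$polarity,
         src = as.integer(sp$edges$src), tgt = as.integer(sp$edges$tgt),
         weight = sp$edges$weight, tau_s = sp$tau_s, delay = sp$delay,
         n_source = as.integer(topology$sizes[[sp$source]]),
         n_target = as.integer(topology$sizes[[sp$target]]))
  })
}

#' Run one 20 s lesion simulation
#'
#' Integrates the full thalamo-cortical network: three IFB thalamic nuclei
#' driven by Poisson peripheral input, the Izhikevich cortical sheet, all 13
#' projections with their delays, the lesion at `lesion_time` and (optionally)
#' the slow-onset GABA current. Fully deterministic given `seed`: the
#' topology, cortical heterogeneity and Poisson drive are all drawn from it.
#'
#' Lesioned neurons keep their intrinsic drive but are synaptically isolated;
#' their post-lesion spikes are not recorded and they are excluded from the
#' cortical LFP for the whole run (so the averaging set is constant in time).
#'
#' @param config A [sim_config()].
#' @param topology Optional pre-built healthy [build_network()] topology; by
#'   default a fresh topology is drawn from `seed` (each run of a cohort has
#'   its own random connectivity).
#' @param seed Integer seed.
#' @return List of class `simulation_result`: `spikes` (data.frame
#'   `population`, `neuron`, `time_ms`), `lfp` (4 x n_steps matrix, rows SP,
#'   NSP, TRN, CRX: per-step mean membrane potential of non-lesioned
#'   neurons), `lesion_mask`, `config`, `seed`.
#' @export
run_simulation <- function(config = sim_config(), topology = NULL, seed = 1L) {
  inp <- prepare_run(config, topology, seed)
  lesion_step <- if (config$lesion_fraction > 0)
    as.integer(round(config$lesion_time / config$dt)) else -1L
  sp <- thalamic_params("SP"); nsp <- thalamic_params("NSP")
  trn <- thalamic_params("TRN")
  out <- .run_network_cpp(inp$n_steps, config$dt,
                          unclass(sp), unclass(nsp), unclass(trn),
                          unclass(inp$crx),
                          edge_projections(inp$topology),
                          inp$drive_sp, inp$drive_nsp,
                          lesion_step, inp$mask, inp$gaba,
                          inp$topology$w_cc,
                          rep(sp$V_L, 3), rep(0, 3),
                          config$i_jitter_sd)
  lfp <- out$lfp
  rownames(lfp) <- c("SP", "NSP", "TRN", "CRX")
  pops <- c("SP", "NSP", "TRN", "CRX")
  spikes <- data.frame(population = pops[out$spike_pop + 1L],
                       neuron = out$spike_neuron,
                       time_ms = out$spike_time * config$dt)
  structure(list(spikes = spikes, lfp = lfp, lesion_mask = inp$mask,
                 config = config, seed = seed),
            class = "simulation_result")
}

#' Pure-R reference integration of the network
#'
#' Step-for-step mirror of the compiled engine, written in plain R for
#' cross-validation: with identical seed and config the two must produce
#' identical rasters and LFPs. Orders of magnitude slower; use short
#' durations.
#'
#' @inheritParams run_simulation
#' @return Same structure as [run_simulation()].
#' @export
run_simulation_r <- function(config = sim_config(), topology = NULL,
                             seed = 1L) {
  inp <- prepare_run(config, topology, seed)
  n_steps <- inp$n_steps; dt <- config$dt
  lesion_step <- if (config$lesion_fraction > 0)
    as.integer(round(config$lesion_time / config$dt)) else -1L
  tp <- list(SP = thalamic_params("SP"), NSP = thalamic_params("NSP"),
             TRN = thalamic_params("TRN"))
  crx <- inp$crx
  n_crx <- crx$n_exc + crx$n_inh
  projs <- edge_projections(inp$topology)
  # per-projection synaptic state and ring buffers
  for (q in seq_along(projs)) {
    pr <- projs[[q]]
    d <- if (is.na(pr$delay) || pr$delay < 1) {
      if (pr$source %in% c("INPUT_SP", "INPUT_NSP")) 0L else 1L
    } else as.integer(pr$delay)
    pr$eff_delay <- d
    pr$buf <- matrix(0, nrow = d + 1L, ncol = pr$n_target)
    pr$g <- numeric(pr$n_target)
    pr$w_abs <- abs(pr$weight)
    pr$active <- rep(TRUE, length(pr$src))
    pr$src_off <- if (pr$source == "I") crx$n_exc else 0L
    pr$tgt_off <- if (pr$target == "I") crx$n_exc else 0L
    projs[[q]] <- pr
  }
  Vt <- lapply(tp, function(p) rep(p$V_L, p$n))
  ht <- lapply(tp, function(p) rep(0, p$n))
  v <- rep(-65, n_crx); u <- crx$b * v
  pulse <- numeric(n_crx)
  les <- inp$mask; keep <- !les
  lfp <- matrix(0, 4, n_steps, dimnames = list(c("SP", "NSP", "TRN", "CRX")))
  rec <- list(pop = integer(0), neuron = integer(0), time = integer(0))
  thal_spk <- list(SP = logical(100), NSP = logical(100), TRN = logical(100))
  crx_spk <- logical(n_crx)

  for (t in 0:(n_steps - 1)) {
    lesioned <- lesion_step >= 0 && t >= lesion_step
    if (lesion_step >= 0 && t == lesion_step) {
      for (q in seq_along(projs)) {
        pr <- projs[[q]]
        src_crx <- pr$source %in% c("E", "I", "CRX")
        tgt_crx <- pr$target %in% c("E", "I", "CRX")
        if (!src_crx && !tgt_crx) next
        bad <- rep(FALSE, length(pr$src))
        if (src_crx) bad <- bad | les[pr$src + pr$src_off]
        if (tgt_crx) bad <- bad | les[pr$tgt + pr$tgt_off]
        projs[[q]]$active <- pr$active & !bad
      }
    }
    # exogenous Poisson arrivals (zero delay: land in the current slot)
    for (q in seq_along(projs)) {
      pr <- projs[[q]]
      if (!pr$source %in% c("INPUT_SP", "INPUT_NSP")) next
      D <- if (pr$source == "INPUT_SP") inp$drive_sp else inp$drive_nsp
      slot <- t %% nrow(pr$buf) + 1L
      firing <- which(D[, t + 1L] == 1L)
      sel <- pr$active & pr$src %in% firing
      if (any(sel)) {
        add <- tapply(pr$w_abs[sel], pr$tgt[sel], sum)
        idx <- as.integer(names(add))
        projs[[q]]$buf[slot, idx] <- pr$buf[slot, idx] + as.numeric(add)
      }
    }
    # synaptic state update
    gE <- list(SP = numeric(100), NSP = numeric(100), TRN = numeric(100))
    gI <- list(SP = numeric(100), NSP = numeric(100), TRN = numeric(100))
    crx_syn <- numeric(n_crx)
    for (q in seq_along(projs)) {
      pr <- projs[[q]]
      slot <- t %% nrow(pr$buf) + 1L
      arr <- pr$buf[slot, ]
      projs[[q]]$buf[slot, ] <- 0
      if (pr$target %in% c("SP", "NSP", "TRN")) {
        tpp <- tp[[pr$target]]
        gain <- if (pr$polarity == "exc") tpp$k_E else tpp$k_I
        g <- pmax(pr$g * (1 - dt / pr$tau_s) + gain * arr, 0)
        projs[[q]]$g <- g
        if (pr$polarity == "exc") gE[[pr$target]] <- gE[[pr$target]] + g
        else gI[[pr$target]] <- gI[[pr$target]] + g
      } else {
        g <- pmax(pr$g * (1 - dt / pr$tau_s) + arr, 0)
        projs[[q]]$g <- g
        sgn <- if (pr$polarity == "exc") 1 else -1
        idx <- seq_len(pr$n_target) + pr$tgt_off
        crx_syn[idx] <- crx_syn[idx] + sgn * g
      }
    }
    # thalamic update
    for (k in c("SP", "NSP", "TRN")) {
      p <- tp[[k]]
      Vi <- Vt[[k]]; hi <- ht[[k]]
      IT <- ifelse(Vi > p$V_h, p$g_T * hi * (Vi - p$E_T), 0)
      IL <- p$g_L * (Vi - p$V_L)
      Isyn <- gE[[k]] * (Vi - p$V_E) + gI[[k]] * (Vi - p$V_I)
      Vn <- Vi + dt / p$C * (-IL - Isyn - IT)
      spk <- Vn >= p$V_0
      Vn[spk] <- p$V_reset
      hn <- pmin(pmax(hi + dt * ifelse(Vi > p$V_h, -hi / p$tau_h_minus,
                                       (1 - hi) / p$tau_h_plus), 0), 1)
      Vt[[k]] <- Vn; ht[[k]] <- hn; thal_spk[[k]] <- spk
      ki <- match(k, c("SP", "NSP", "TRN"))
      lfp[ki, t + 1L] <- mean(Vn)
      if (any(spk)) {
        rec$pop <- c(rec$pop, rep(ki - 1L, sum(spk)))
        rec$neuron <- c(rec$neuron, which(spk))
        rec$time <- c(rec$time, rep(t, sum(spk)))
      }
    }
    # cortical update
    I <- crx$I_intrinsic + crx_syn + pulse
    if (any(config$i_jitter_sd > 0))
      I <- I + stats::rnorm(n_crx) *
        rep(config$i_jitter_sd, c(crx$n_exc, crx$n_inh))
    if (lesioned) I[keep] <- I[keep] + inp$gaba[t + 1L]
    v <- v + 0.5 * dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    v <- v + 0.5 * dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * crx$a * (crx$b * v - u)
    spk <- v >= crx$spike_cutoff
    v[spk] <- crx$c[spk]; u[spk] <- u[spk] + crx$d[spk]
    crx_spk <- spk
    rec_spk <- spk & !(lesioned & les)
    if (any(rec_spk)) {
      rec$pop <- c(rec$pop, rep(3L, sum(rec_spk)))
      rec$neuron <- c(rec$neuron, which(rec_spk))
      rec$time <- c(rec$time, rep(t, sum(rec_spk)))
    }
    lfp[4L, t + 1L] <- mean(v[keep])
    # next-step cortico-cortical pulses (dense weight matrix, zero diagonal);
    # accumulated column by column, in the same order as the compiled engine,
    # so the two paths stay bitwise-comparable
    senders <- if (lesioned) spk & !les else spk
    pulse <- numeric(n_crx)
    for (j in which(senders)) pulse <- pulse + inp$topology$w_cc[, j]
    if (lesioned) pulse[les] <- 0
    # schedule this step's network spikes
    for (q in seq_along(projs)) {
      pr <- projs[[q]]
      if (pr$source %in% c("INPUT_SP", "INPUT_NSP")) next
      spikes_src <- switch(pr$source,
        SP = thal_spk$SP, NSP = thal_spk$NSP, TRN = thal_spk$TRN,
        E = crx_spk[seq_len(crx$n_exc)],
        I = crx_spk[crx$n_exc + seq_len(crx$n_inh)],
        CRX = crx_spk)
      firing <- which(spikes_src)
      if (!length(firing)) next
      slot <- (t + pr$eff_delay) %% nrow(pr$buf) + 1L
      sel <- pr$active & pr$src %in% firing
      if (any(sel)) {
        add <- tapply(pr$w_abs[sel], pr$tgt[sel], sum)
        idx <- as.integer(names(add))
        projs[[q]]$buf[slot, idx] <- pr$buf[slot, idx] + as.numeric(add)
      }
    }
  }
  pops <- c("SP", "NSP", "TRN", "CRX")
  spikes <- data.frame(population = pops[rec$pop + 1L], neuron = rec$neuron,
                       time_ms = rec$time * dt)
  structure(list(spikes = spikes, lfp = lfp, lesion_mask = les,
                 config = config, seed = seed),
            class = "simulation_result")
}

#' Inter-spike-interval summary of a raster
#'
#' Consecutive spike-time differences per neuron within a window. ISIs below
#' 20 ms are counted as intra-burst intervals; the pooled share of such ISIs
#' is the `burst_fraction`, and a neuron is classified as bursting when more
#' than half of its own ISIs fall below 20 ms.
#'
#' @param spikes Raster data.frame with columns `population`, `neuron`,
#'   `time_ms` (as in [run_simulation()]).
#' @param window `c(t0, t1)` ms, inclusive.
#' @param population Population to summarise (e.g. `"NSP"`).
#' @param burst_isi Intra-burst ISI threshold, ms.
#' @return List of class `isi_summary`: `isis` (list per neuron),
#'   `burst_fraction` (pooled; `NA` if no ISIs), `classification`
#'   (`"tonic"`/`"burst"` per neuron with >= 1 ISI), `n_isis`.
#' @export
isi_statistics <- function(spikes, window, population = "NSP",
                           burst_isi = 20) {
  s <- spikes[spikes$population == population &
                spikes$time_ms >= window[1] & spikes$time_ms <= window[2], ]
  isis <- lapply(split(s$time_ms, s$neuron), function(tt) diff(sort(tt)))
  isis <- isis[lengths(isis) > 0]
  all_isis <- unlist(isis, use.names = FALSE)
  cls <- vapply(isis, function(x) {
    if (mean(x < burst_isi) > 0.5) "burst" else "tonic"
  }, character(1))
  structure(list(
    isis = isis,
    burst_fraction = if (length(all_isis)) mean(all_isis < burst_isi)
                     else NA_real_,
    classification = cls,
    n_isis = length(all_isis)), class = "isi_summary")
}

# Spectral + burst summaries of one run, shared by cohort and sweep.
summarise_run <- function(res, bank = NULL) {
  cfg <- res$config
  if (is.null(bank)) bank <- morlet_bank(1, 80, fs = 1000 / cfg$dt)
  pre_idx <- seq_len(round(cfg$lesion_time / cfg$dt))
  post_idx <- (round(cfg$lesion_time / cfg$dt) + 1L):ncol(res$lfp)
  spec <- function(x) power_spectrum(x, bank)
  crx_pre <- spec(res$lfp["CRX", pre_idx])
  crx_post <- spec(res$lfp["CRX", post_idx])
  nsp_post <- spec(res$lfp["NSP", post_idx])
  trn_post <- spec(res$lfp["TRN", post_idx])
  bf <- function(pop, w) isi_statistics(res$spikes, w, pop)$burst_fraction
  pre_w <- c(0, cfg$lesion_time)
  post_w <- c(cfg$lesion_time, cfg$duration)
  list(
    pre_peak = dominant_peak(crx_pre, c(6, 13)),
    post_peak = dominant_peak(crx_post, c(6, 13)),
    nsp_post_peak = dominant_peak(nsp_post, c(1, 13)),
    trn_post_peak = dominant_peak(trn_post, c(1, 13)),
    crx_pre_spectrum = crx_pre, crx_post_spectrum = crx_post,
    nsp_post_spectrum = nsp_post,
    burst_pre = c(SP = bf("SP", pre_w), NSP = bf("NSP", pre_w),
                  TRN = bf("TRN", pre_w)),
    burst_post = c(SP = bf("SP", post_w), NSP = bf("NSP", post_w),
                   TRN = bf("TRN", post_w)),
    nsp_mean_v_pre = mean(res$lfp["NSP", pre_idx]),
    nsp_mean_v_post = mean(res$lfp["NSP", post_idx]))
}

#' Run a seeded cohort of lesion simulations
#'
#' Runs `config$n_runs` simulations with seeds `base_seed + 1 .. + n_runs`,
#' summarises each (dominant pre/post cortical peaks in 6-13 Hz, thalamic
#' low-frequency peaks, burst fractions) and applies the noise constraint:
#' runs whose pre-lesion cortical dominant peak falls outside
#' `config$peak_bounds` (the healthy control group's 8.3-11.9 Hz peak range)
#' are omitted from group statistics.
#'
#' @param config A [sim_config()].
#' @param base_seed Base integer seed.
#' @param keep_first Keep the full [run_simulation()] result of the first
#'   retained run (for raster/ISI figures).
#' @param progress Print one line per run.
#' @return List of class `cohort_result`: `runs` (data.frame with per-run
#'   summaries and `retained` flag), `summaries` (full per-run summary
#'   lists), `omitted` (seeds of omitted runs), `first_result`, `config`.
#' @export
run_cohort <- function(config = sim_config(), base_seed = 1L,
                       keep_first = FALSE, progress = FALSE) {
  stopifnot(config$n_runs >= 1)
  bank <- morlet_bank(1, 80, fs = 1000 / config$dt)
  summaries <- vector("list", config$n_runs)
  first_result <- NULL
  for (i in seq_len(config$n_runs)) {
    res <- run_simulation(config, seed = base_seed + i)
    summaries[[i]] <- summarise_run(res, bank)
    if (progress)
      message(sprintf("run %d/%d: pre %.2f Hz post %.2f Hz", i, config$n_runs,
                      summaries[[i]]$pre_peak, summaries[[i]]$post_peak))
    if (keep_first && is.null(first_result) &&
        summaries[[i]]$pre_peak >= config$peak_bounds[1] &&
        summaries[[i]]$pre_peak <= config$peak_bounds[2])
      first_result <- res
  }
  runs <- data.frame(
    seed = base_seed + seq_len(config$n_runs),
    pre_peak = vapply(summaries, `[[`, 0, "pre_peak"),
    post_peak = vapply(summaries, `[[`, 0, "post_peak"),
    nsp_post_peak = vapply(summaries, `[[`, 0, "nsp_post_peak"),
    trn_post_peak = vapply(summaries, `[[`, 0, "trn_post_peak"),
    burst_pre_nsp = vapply(summaries, function(s) s$burst_pre[["NSP"]], 0),
    burst_post_nsp = vapply(summaries, function(s) s$burst_post[["NSP"]], 0),
    burst_pre_trn = vapply(summaries, function(s) s$burst_pre[["TRN"]], 0),
    burst_post_trn = vapply(summaries, function(s) s$burst_post[["TRN"]], 0),
    nsp_mean_v_pre = vapply(summaries, `[[`, 0, "nsp_mean_v_pre"),
    nsp_mean_v_post = vapply(summaries, `[[`, 0, "nsp_mean_v_post"))
  runs$retained <- runs$pre_peak >= config$peak_bounds[1] &
    runs$pre_peak <= config$peak_bounds[2]
  structure(list(runs = runs, summaries = summaries,
                 omitted = runs$seed[!runs$retained],
                 first_result = first_result, config = config),
            class = "cohort_result")
}

#' Lesion-size sweep
#'
#' For each lesion fraction, runs `reps` simulations and reports the mean and
#' s.e.m. of the post-lesion cortical dominant peak (6-13 Hz). Increasing
#' lesion size slows the dominant rhythm.
#'
#' @param sizes Ascending lesion fractions.
#' @param reps Simulations per size.
#' @param config Base [sim_config()] (its `lesion_fraction` is overridden).
#' @param base_seed Base seed; size `k`, rep `i` uses
#'   `base_seed + 1000 * k + i`.
#' @return data.frame: `size`, `mean_post_peak`, `sem_post_peak`,
#'   `mean_pre_peak`.
#' @export
lesion_sweep <- function(sizes = seq(0, 0.5, by = 0.1), reps = 10L,
                         config = sim_config(), base_seed = 1L) {
  stopifnot(!is.unsorted(sizes))
  bank <- morlet_bank(1, 80, fs = 1000 / config$dt)
  rows <- lapply(seq_along(sizes), function(k) {
    cfg <- config
    cfg$lesion_fraction <- sizes[k]
    peaks <- vapply(seq_len(reps), function(i) {
      res <- run_simulation(cfg, seed = base_seed + 1000L * k + i)
      s <- summarise_run(res, bank)
      c(s$pre_peak, s$post_peak)
    }, numeric(2))
    data.frame(size = sizes[k],
               mean_post_peak = mean(peaks[2, ]),
               sem_post_peak = stats::sd(peaks[2, ]) / sqrt(reps),
               mean_pre_peak = mean(peaks[1, ]))
  })
  do.call(rbind, rows)
}

#' Calibrate the cortical intrinsic drive against the healthy alpha peak
#'
#' Reproduces the healthy-state calibration: for each candidate excitatory
#' drive, runs lesion-free simulations and reports the mean dominant peak of
#' the cortical power spectrum in 6-13 Hz. The default `sim_config()$I_E` is
#' the value whose peak matches the healthy (control-group) dominant alpha
#' frequency. The quadratic model's firing period shortens with drive, so
#' the sheet rhythm moves monotonically with `I_E` over this range.
#'
#' @param I_E_grid Candidate excitatory drive values.
#' @param reps Lesion-free runs per candidate.
#' @param config Base [sim_config()] (lesion disabled internally).
#' @param base_seed Base seed.
#' @return data.frame: `I_E`, `mean_peak_hz`, `sd_peak_hz`.
#' @export
calibrate_cortex <- function(I_E_grid = seq(5.2, 6.7, by = 0.3), reps = 3L,
                             config = sim_config(), base_seed = 1L) {
  bank <- morlet_bank(1, 80, fs = 1000 / config$dt)
  rows <- lapply(I_E_grid, function(ie) {
    cfg <- config
    cfg$I_E <- ie
    cfg$lesion_fraction <- 0
    peaks <- vapply(seq_len(reps), function(i) {
      res <- run_simulation(cfg, seed = base_seed + i)
      dominant_peak(power_spectrum(res$lfp["CRX", ], bank), c(6, 13))
    }, 0)
    data.frame(I_E = ie, mean_peak_hz = mean(peaks),
               sd_peak_hz = stats::sd(peaks))
  })
  do.call(rbind, rows)
}

#' Calibrate the GABA current amplitude
#'
#' Sweeps candidate amplitudes and, for each, compares the average post-lesion
#' cortical spectrum with and without the inhibitory ramp, reporting the
#' lowest frequency from which the with-GABA spectrum stays below the
#' lesion-only spectrum. Used once to fix the default `gaba_amplitude` so
#' this divergence frequency lands near 23 Hz.
#'
#' @param amplitudes Candidate plateau magnitudes.
#' @param reps Runs per amplitude.
#' @param config Base [sim_config()].
#' @param base_seed Base seed.
#' @return data.frame: `amplitude`, `divergence_hz` (NA when the spectra
#'   never stay separated).
#' @export
calibrate_gaba <- function(amplitudes = c(0.5, 1, 1.5, 2, 3), reps = 3L,
                           config = sim_config(), base_seed = 1L) {
  bank <- morlet_bank(1, 80, fs = 1000 / config$dt)
  post_idx <- (round(config$lesion_time / config$dt) + 1L):
    round(config$duration / config$dt)
  mean_post_spec <- function(cfg) {
    specs <- vapply(seq_len(reps), function(i) {
      res <- run_simulation(cfg, seed = base_seed + i)
      power_spectrum(res$lfp["CRX", post_idx], bank)$power
    }, numeric(length(bank$freqs)))
    rowMeans(specs)
  }
  cfg0 <- config; cfg0$gaba_enabled <- FALSE
  base_spec <- mean_post_spec(cfg0)
  rows <- lapply(amplitudes, function(a) {
    cfg <- config; cfg$gaba_enabled <- TRUE; cfg$gaba_amplitude <- a
    g <- mean_post_spec(cfg)
    below <- g < base_spec
    run <- rev(cumprod(rev(below)))  # suffix of all-below frequencies
    div <- if (any(run == 1)) bank$freqs[which(run == 1)[1]] else NA_real_
    data.frame(amplitude = a, divergence_hz = div)
  })
  do.call(rbind, rows)
}
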