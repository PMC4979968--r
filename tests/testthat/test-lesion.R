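test_that("lesion isolates the expected contiguous blocks", {
  topo <- build_network(seed = 9)
  les <- apply_lesion(topo, 0.30)
  expect_equal(sum(les$lesion_mask[1:800]), 240)     # 30% of excitatory
  expect_equal(sum(les$lesion_mask[801:1000]), 60)   # 30% of inhibitory
  expect_true(all(which(les$lesion_mask[1:800]) == 1:240))
  # every afferent and efferent edge of a lesioned cell is gone
  for (nm in c("E->TRN", "E->SP", "E->NSP")) {
    expect_false(any(les$projections[[nm]]$edges$src <= 240), info = nm)
  }
  expect_false(any(les$projections[["SP->E"]]$edges$tgt <= 240))
  expect_false(any(les$projections[["NSP->E"]]$edges$tgt <= 240))
  # intrathalamic wiring and peripheral drives untouched
  for (nm in c("Input-SP->SP", "Input-NSP->NSP", "SP->TRN", "TRN->SP",
               "TRN->NSP", "NSP->TRN")) {
    expect_identical(les$projections[[nm]]$edges, topo$projections[[nm]]$edges,
                     info = nm)
  }
})

test_that("zero lesion is the identity and surviving edges are untouched", {
  topo <- build_network(seed = 10)
  expect_identical(apply_lesion(topo, 0)$projections, topo$projections)
  les <- apply_lesion(topo, 0.30)
  # set-difference oracle: surviving edges are exactly the pre-lesion edges
  # not incident on the lesioned block
  for (nm in c("E->NSP", "SP->E", "NSP->E")) {
    pre <- topo$projections[[nm]]$edges
    post <- les$projections[[nm]]$edges
    mask <- les$lesion_mask
    incident <- switch(nm,
      "E->NSP" = mask[pre$src],
      "SP->E" = mask[pre$tgt],
      "NSP->E" = mask[pre$tgt])
    kept <- pre[!incident, ]
    rownames(kept) <- NULL
    expect_identical(post, kept, info = nm)
  }
  expect_error(apply_lesion(topo, 0.5, anchor = 500L), "exceeds")
})

test_that("GABA current ramps linearly after the lesion and plateaus", {
  cfg <- sim_config(gaba_enabled = TRUE, gaba_amplitude = 2, gaba_ramp = 1000)
  expect_equal(gaba_current(c(0, 5000, 9999), cfg), c(0, 0, 0))
  expect_equal(gaba_current(10500, cfg), -1)          # ramp midpoint
  expect_equal(gaba_current(c(11000, 15000), cfg), c(-2, -2))
  off <- sim_config(gaba_enabled = FALSE)
  expect_equal(gaba_current(c(0, 15000), off), c(0, 0))
})

test_that("ISI statistics match hand computation", {
  spikes <- data.frame(population = "NSP", neuron = 1L,
                       time_ms = c(100, 105, 400))
  s <- isi_statistics(spikes, c(0, 1000), "NSP")
  expect_equal(unname(s$isis[["1"]]), c(5, 295))
  expect_equal(s$burst_fraction, 0.5)
  # empty window reports missing, regular slow train has no burst ISIs
  expect_true(is.na(isi_statistics(spikes, c(500, 1000), "NSP")$burst_fraction))
  reg <- data.frame(population = "TRN", neuron = 2L,
                    time_ms = seq(0, 900, by = 100))
  expect_equal(isi_statistics(reg, c(0, 1000), "TRN")$burst_fraction, 0)
  expect_equal(unname(isi_statistics(reg, c(0, 1000), "TRN")$classification),
               "tonic")
})

test_that("simulations are reproducible and lesioned cells leave the record", {
  cfg <- quick_config()
  r1 <- run_simulation(cfg, seed = 21)
  r2 <- run_simulation(cfg, seed = 21)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$lfp, r2$lfp)
  r3 <- run_simulation(cfg, seed = 22)
  expect_false(identical(r1$spikes, r3$spikes))
  # no spikes attributed to lesioned cortical neurons after the lesion
  post <- r1$spikes[r1$spikes$population == "CRX" &
                      r1$spikes$time_ms >= cfg$lesion_time, ]
  expect_false(any(r1$lesion_mask[post$neuron]))
  expect_equal(ncol(r1$lfp), 10000)
})

test_that("the compiled engine matches the pure-R reference step for step", {
  cfg <- sim_config(duration = 600, lesion_time = 300)
  rc <- run_simulation(cfg, seed = 31)
  rr <- run_simulation_r(cfg, seed = 31)
  expect_equal(rr$lfp, rc$lfp, tolerance = 1e-10)
  expect_equal(rr$spikes, rc$spikes)
})

test_that("the cohort omission rule drops out-of-band runs", {
  cfg <- quick_config(n_runs = 4L)
  ch <- run_cohort(cfg, base_seed = 77)
  expect_equal(nrow(ch$runs), 4)
  expect_identical(ch$runs$retained,
                   ch$runs$pre_peak >= 8.3 & ch$runs$pre_peak <= 11.9)
  expect_identical(ch$omitted, ch$runs$seed[!ch$runs$retained])
  # artificial bounds that exclude everything
  cfg2 <- quick_config(n_runs = 2L, peak_bounds = c(100, 101))
  ch2 <- run_cohort(cfg2, base_seed = 77)
  expect_equal(sum(ch2$runs$retained), 0)
  expect_equal(length(ch2$omitted), 2)
})
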