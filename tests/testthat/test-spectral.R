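test_that("wavelet bank is well-formed under both cycle rules", {
  b <- morlet_bank(1, 35, n_freqs = 50, fs = 500)
  expect_length(b$freqs, 50)
  expect_true(all(diff(b$freqs) > 0))
  expect_true(all(diff(b$cycles) >= 0))
  expect_equal(b$freqs[c(1, 50)], c(1, 35))
  # proportional rule: every wavelet spans the same time-window
  expect_equal(diff(range(b$support)), 0)
  # max-value normalization
  for (i in c(1, 25, 50)) expect_equal(max(Mod(b$wavelets[[i]])), 1)
  blin <- morlet_bank(1, 35, fs = 500, cycles = c(3, 10))
  expect_equal(blin$cycles[c(1, 50)], c(3, 10))
  expect_true(all(diff(blin$support) < 0))  # high f -> shorter wavelets
})

test_that("wavelet power localizes oscillations and respects scaling laws", {
  fs <- 500
  b <- morlet_bank(1, 35, fs = fs)
  tt <- seq(0, 30, by = 1 / fs)[-1]
  x <- sin(2 * pi * 10 * tt)
  sp <- power_spectrum(x, b)
  expect_equal(dominant_peak(sp, c(1, 35)),
               b$freqs[which.min(abs(b$freqs - 10))])
  # zero signal, zero power; amplitude scales power quadratically
  expect_true(all(power_spectrum(numeric(6000), b)$power == 0))
  sp2 <- power_spectrum(2 * x, b)
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-8)
  expect_true(all(sp$power >= 0))
  expect_error(tf_power(rnorm(100), b), "shorter")
})

test_that("band powers of white noise agree with a periodogram oracle", {
  set.seed(14)
  fs <- 500
  x <- rnorm(fs * 60)
  b <- morlet_bank(1, 35, fs = fs)
  mse <- band_mse(power_spectrum(x, b), band_set())
  # oracle: mean periodogram power per band
  pg <- spec.pgram(ts(x, frequency = fs), plot = FALSE)
  oracle <- vapply(seq_len(nrow(band_set())), function(i)
    mean(pg$spec[pg$freq >= band_set()$lo[i] & pg$freq <= band_set()$hi[i]]), 0)
  # white noise: flat bands, same rank ordering as the oracle (all ~equal,
  # so compare relative spread instead of exact ranks)
  expect_lt(diff(range(mse)) / mean(mse), 0.25)
  expect_lt(diff(range(oracle)) / mean(oracle), 0.25)
})

test_that("stationary band power is invariant to doubling the duration", {
  set.seed(15)
  fs <- 500
  b <- morlet_bank(1, 35, fs = fs)
  x <- rnorm(fs * 120)
  m1 <- band_mse(power_spectrum(x[1:(fs * 60)], b))
  m2 <- band_mse(power_spectrum(x, b))
  expect_equal(unname(m2 / m1), rep(1, 4), tolerance = 0.15)
})

test_that("band summaries honour the printed band edges and their gaps", {
  bands <- band_set()
  expect_equal(bands$band, c("delta", "theta", "alpha", "beta"))
  expect_true(all(bands$lo[-1] > bands$hi[-nrow(bands)]))  # disjoint, ordered
  bm <- band_set(model = TRUE)
  expect_equal(bm$band[5], "gamma")
  flat <- structure(list(freqs = seq(1, 35, by = 0.1),
                         power = rep(1, 341)), class = "power_spectrum")
  expect_equal(unname(band_mse(flat)), rep(1, 4))
  # line at 10 Hz: alpha only
  line <- structure(list(freqs = c(1, 6, 10, 20, 31),
                         power = c(0, 0, 5, 0, 0)), class = "power_spectrum")
  expect_equal(unname(band_mse(line)), c(0, 0, 5, 0))
  # 4.1 Hz falls in the printed gap between delta (<= 4.0) and theta (>= 4.2):
  # its power reaches no band, and theta (left with no grid point) reports NA
  gap <- structure(list(freqs = c(1, 4.1, 9, 20, 31),
                        power = c(0, 7, 0, 0, 0)), class = "power_spectrum")
  expect_equal(unname(band_mse(gap)), c(0, NA, 0, 0))
  expect_warning(band_mse(structure(list(freqs = c(2, 9), power = c(1, 1)),
                                    class = "power_spectrum")), "cover")
})

test_that("dominant peak picks the maximum and breaks ties downward", {
  sp <- structure(list(freqs = c(6, 8, 9.7, 10, 12),
                       power = c(1, 2, 9, 3, 1)), class = "power_spectrum")
  expect_equal(dominant_peak(sp, c(6, 13)), 9.7)
  tie <- structure(list(freqs = c(6, 8, 10, 12),
                        power = c(1, 5, 5, 1)), class = "power_spectrum")
  expect_equal(dominant_peak(tie, c(6, 13)), 8)
  expect_error(dominant_peak(sp, c(100, 120)), "outside")
})

test_that("peak recovery holds across the 6-12 Hz range", {
  fs <- 500
  b <- morlet_bank(1, 35, fs = fs)
  tt <- seq(1 / fs, 40, by = 1 / fs)
  set.seed(16)
  for (f in 6:12) {
    x <- sin(2 * pi * f * tt) + rnorm(length(tt), sd = 0.3)
    pk <- dominant_peak(power_spectrum(x, b), c(4, 14))
    bin <- which(b$freqs == pk)
    truth <- which.min(abs(b$freqs - f))
    expect_lte(abs(bin - truth), 1)
  }
})

test_that("LFP is the mean over non-lesioned neurons", {
  tr <- matrix(-65, 4, 10)
  expect_equal(compute_lfp(tr), rep(-65, 10))
  tr2 <- rbind(rep(-60, 5), rep(-70, 5))
  expect_equal(compute_lfp(tr2), rep(-65, 5))
  tr3 <- rbind(rep(0, 5), rep(10, 5), rep(99, 5), rep(99, 5))
  expect_equal(compute_lfp(tr3, c(FALSE, FALSE, TRUE, TRUE)), rep(5, 5))
})
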