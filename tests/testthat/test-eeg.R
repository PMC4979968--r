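# Small synthetic recording used across the pipeline tests.
toy_recording <- function(n_sec = 10, fs = 500, seed = 1, amp = 5) {
  set.seed(seed)
  d <- matrix(rnorm(17 * n_sec * fs, sd = amp), 17,
              dimnames = list(eeg_electrodes(), NULL))
  eeg_recording(d, fs = fs)
}

test_that("bandpass attenuates stopband and preserves passband", {
  fs <- 500
  tt <- seq(1 / fs, 20, by = 1 / fs)
  mk <- function(f) {
    d <- matrix(rep(sin(2 * pi * f * tt), 17), 17, byrow = TRUE,
                dimnames = list(eeg_electrodes(), NULL))
    eeg_recording(d, fs = fs)
  }
  # oracle: the filter's transfer function evaluated on the unit circle,
  # squared because zero-phase application runs the filter twice
  flt <- signal::butter(2, c(0.5, 35) / (fs / 2), type = "pass")
  gain <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(flt$b) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * z))^2
  }
  rms <- function(x) sqrt(mean(x^2))
  mid <- 2000:8000
  out60 <- bandpass(mk(60))
  expect_lt(rms(out60$data[1, mid]) / rms(mk(60)$data[1, mid]), 0.2)
  expect_equal(rms(out60$data[1, mid]) / rms(mk(60)$data[1, mid]),
               gain(60), tolerance = 0.05)
  out10 <- bandpass(mk(10))
  expect_gt(rms(out10$data[1, mid]) / rms(mk(10)$data[1, mid]), 0.95)
  zero <- eeg_recording(matrix(0, 17, 1000,
                               dimnames = list(eeg_electrodes(), NULL)))
  expect_true(all(bandpass(zero)$data == 0))
})

test_that("common-average reference zeroes the channel mean everywhere", {
  rec <- toy_recording()
  out <- rereference_car(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  # identical signals cancel; a zero-mean pair is unchanged
  same <- eeg_recording(matrix(1, 2, 10, dimnames = list(c("C3", "C4"), NULL)))
  expect_true(all(rereference_car(same)$data == 0))
  pair <- eeg_recording(rbind(C3 = rep(1, 10), C4 = rep(-1, 10)))
  expect_equal(rereference_car(pair)$data, pair$data)
})

test_that("epoch extraction takes the first clean windows and rejects artifacts", {
  rec <- toy_recording(n_sec = 120)
  eps <- extract_epochs(rec)
  expect_equal(sum(eps$accepted), 45)
  expect_equal(length(eps$accepted), floor(120 * 500 / 1024))  # 58 candidates
  expect_true(all(which(eps$accepted) == 1:45))
  expect_equal(dim(eps$epochs), c(45, 17, 1024))
  # a 100 uV spike in window 3 rejects window 3 only
  rec2 <- toy_recording(n_sec = 120)
  rec2$data[5, 2200] <- 100
  eps2 <- extract_epochs(rec2)
  expect_false(eps2$accepted[3])
  expect_true(all(eps2$accepted[c(1, 2, 4)]))
  expect_true(all(abs(eps2$epochs) <= 75))
  # an all-artifact recording yields an empty set with a warning
  bad <- eeg_recording(matrix(200, 17, 5000,
                              dimnames = list(eeg_electrodes(), NULL)))
  expect_warning(eps3 <- extract_epochs(bad), "artifact-free")
  expect_equal(dim(eps3$epochs)[1], 0)
})

test_that("the orchestrator rejects a permuted preprocessing order", {
  rec <- toy_recording()
  out_of_order <- bandpass(rereference_car(rec))
  expect_error(extract_epochs(out_of_order, strict = TRUE), "order")
  expect_no_error(suppressWarnings(
    extract_epochs(rereference_car(bandpass(rec)), strict = TRUE)))
})

test_that("electrode mirroring swaps lateral pairs and is an involution", {
  x <- stats::setNames(seq_len(17), eeg_electrodes())
  m <- mirror_electrodes(x, "left")
  expect_equal(m[["C3"]], x[["C4"]])
  expect_equal(m[["C4"]], x[["C3"]])
  expect_equal(m[["O1"]], x[["O2"]])
  expect_equal(m[c("Fz", "Cz", "Pz")], x[c("Fz", "Cz", "Pz")])
  expect_identical(mirror_electrodes(m, "left"), x)
  expect_identical(mirror_electrodes(x, "right"), x)
  expect_identical(mirror_electrodes(x, "none"), x)
  mat <- matrix(rnorm(17 * 4), 17, dimnames = list(eeg_electrodes(), NULL))
  expect_identical(mirror_electrodes(mirror_electrodes(mat, "left"), "left"),
                   mat)
})

test_that("rank-sum p-values match exact enumeration for small samples", {
  set.seed(31)
  for (i in 1:12) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, mean = runif(1, -1, 1))
    expect_equal(ranksum_exact(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("identical groups compare as indistinguishable", {
  recs <- lapply(1:3, function(i) {
    r <- toy_recording(n_sec = 95, seed = 40 + i, amp = 3)
    r$group <- "x"; r$subject_id <- paste0("s", i); r
  })
  subs <- lapply(recs, analyze_subject)
  cmp <- compare_groups(subs, subs)
  expect_true(all(cmp$band_tests$p_value == 1))
  expect_equal(cmp$peak_test$p_value, 1)
  expect_true(all(abs(cmp$electrode_diff) < 1e-12))
  expect_equal(rownames(cmp$electrode_diff), eeg_electrodes())
})

test_that("recordings round-trip through the delimited-text dialect", {
  rec <- toy_recording(n_sec = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_table(rec, path)
  back <- read_eeg_table(path, fs = rec$fs)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$data, rec$data, tolerance = 1e-6, ignore_attr = TRUE)
})
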