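test_that("wiring patterns obey their degree laws", {
  one <- build_projection(projection_spec("x", "SP", "TRN", "exc", 1,
                                          "one_to_one"), 100, 100)
  expect_equal(nrow(one), 100)
  expect_equal(one$src, one$tgt)
  e81 <- build_projection(projection_spec("x", "E", "SP", "exc", 1,
                                          "eight_to_one"), 800, 100)
  expect_equal(nrow(e81), 800)
  expect_true(all(table(e81$tgt) == 8))            # in-degree exactly 8
  expect_true(all(table(e81$src) == 1))
  expect_equal(e81$tgt[1:8], rep(1L, 8))           # contiguous block alignment
  e18 <- build_projection(projection_spec("x", "SP", "E", "exc", 1,
                                          "one_to_eight"), 100, 800)
  expect_true(all(table(e18$src) == 8))            # out-degree exactly 8
  expect_error(build_projection(projection_spec("x", "SP", "TRN", "exc", 1,
                                                "one_to_one"), 100, 99),
               "equal sizes")
  expect_error(build_projection(projection_spec("x", "E", "SP", "exc", 1,
                                                "eight_to_one"), 799, 100),
               "8 x target")
})

test_that("probabilistic wiring matches the binomial expectation", {
  spec <- projection_spec("x", "TRN", "NSP", "inh", 1, "one_to_many", p = 0.15)
  counts <- vapply(1:100, function(s)
    nrow(build_projection(spec, 100, 100, seed = s)), 0)
  # mean over 100 seeds within 3 s.d. of the mean: sd = sqrt(n p q) / 10
  expect_lt(abs(mean(counts) - 1500), 3 * sqrt(10000 * 0.15 * 0.85) / 10)
  # identical seeds reproduce; different seeds differ
  e1 <- build_projection(spec, 100, 100, seed = 7)
  e2 <- build_projection(spec, 100, 100, seed = 7)
  e3 <- build_projection(spec, 100, 100, seed = 8)
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
})

test_that("the default network realizes every connectivity-table row", {
  topo <- build_network(seed = 42)
  expect_equal(unname(topo$sizes[c("SP", "NSP", "TRN", "CRX")]),
               c(100L, 100L, 100L, 1000L))
  rows <- list(  # name, polarity, g_s, tau_s, delay
    c("Input-SP->SP", "exc", 0.005, 10, 0),
    c("Input-NSP->NSP", "exc", 0.005, 10, 0),
    c("SP->TRN", "exc", 0.018, 10, 3),
    c("TRN->SP", "inh", 0.35, 75, 3),
    c("TRN->NSP", "inh", 0.18, 75, 3),
    c("NSP->TRN", "exc", 0.015, 10, 3),
    c("E->TRN", "exc", 0.02, 7, 7),
    c("E->SP", "exc", 0.007, 7, 7),
    c("E->NSP", "exc", 0.02, 7, 7),
    c("SP->E", "exc", 0.002, 7, 7),
    c("NSP->E", "exc", 0.8, 7, 7))
  for (r in rows) {
    pr <- topo$projections[[r[1]]]
    expect_equal(pr$polarity, r[2], info = r[1])
    expect_equal(pr$g_s, as.numeric(r[3]), info = r[1])
    expect_equal(pr$tau_s, as.numeric(r[4]), info = r[1])
    expect_equal(pr$delay, as.numeric(r[5]), info = r[1])
    sgn <- if (r[2] == "inh") -1 else 1
    expect_true(all(sign(pr$edges$weight) == sgn), info = r[1])
  }
  # TRN->SP: one-to-one inhibitory, weight -0.35 on every edge
  trn_sp <- topo$projections[["TRN->SP"]]$edges
  expect_equal(nrow(trn_sp), 100)
  expect_true(all(trn_sp$weight == -0.35))
  # cortico-cortical pulse matrix: signs by source class, no self-edges
  expect_equal(dim(topo$w_cc), c(1000, 1000))
  expect_true(all(diag(topo$w_cc) == 0))
  self <- diag(1000) == 1  # true self-edge positions in the full matrix
  expect_true(all(topo$w_cc[, 1:800][!self[, 1:800]] >= 0))
  expect_true(all(topo$w_cc[, 1:800][!self[, 1:800]] <= 0.3))
  expect_true(all(topo$w_cc[, 801:1000][!self[, 801:1000]] <= 0))
  expect_true(all(topo$w_cc[, 801:1000][!self[, 801:1000]] >= -1))
  # fixed variant puts the printed value on every edge
  tf <- build_network(seed = 42, cc_weights = "fixed")
  expect_true(all(tf$w_cc[, 1:800][!self[, 1:800]] == 0.3))
  expect_true(all(tf$w_cc[, 801:1000][!self[, 801:1000]] == -1))
})

test_that("network builds are seed-deterministic", {
  t1 <- build_network(seed = 5)
  t2 <- build_network(seed = 5)
  t3 <- build_network(seed = 6)
  expect_identical(t1$projections, t2$projections)
  expect_identical(t1$w_cc, t2$w_cc)
  expect_false(identical(t1$projections[["TRN->NSP"]]$edges,
                         t3$projections[["TRN->NSP"]]$edges))
  expect_error(build_network(projections = default_projection_table()[-4]),
               "missing projection")
})

test_that("Poisson drives are Bernoulli per line per step", {
  expect_true(all(poisson_drive(0, 10, 100, seed = 1) == 0L))
  expect_true(all(poisson_drive(1, 10, 100, seed = 1) == 1L))
  d <- poisson_drive(0.5, 100, 1000, seed = 3)
  counts <- rowSums(d)
  expect_true(all(abs(counts - 500) < 3 * sqrt(1000 * 0.25)))
  expect_identical(d, poisson_drive(0.5, 100, 1000, seed = 3))
})

test_that("topology serializes to a readable edge table", {
  topo <- build_network(seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology(topo, path)
  tab <- read.delim(path)
  expect_setequal(unique(tab$projection),
                  vapply(default_projection_table(), `[[`, "", "name"))
  e_sp <- tab[tab$projection == "E->SP", ]
  expect_equal(nrow(e_sp), 800)
  expect_true(all(e_sp$weight == 0.007))
})
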