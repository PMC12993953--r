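test_that("stitch_enhancers joins peaks within the gap and conserves constituents", {
  # far-apart peaks: one domain each
  ps <- peak_set(rep("chr1", 3), c(0, 50000, 100000),
                 c(1000, 51000, 101000), score = c(1, 2, 3))
  d <- stitch_enhancers(ps, stitch_gap = 12500)
  expect_equal(nrow(d), 3)
  expect_equal(d$n_constituents, rep(1L, 3))

  # forced join across 4.9 kb
  ps2 <- peak_set(c("chr1", "chr1"), c(0, 5000), c(100, 5100),
                  score = c(2, 3))
  d2 <- stitch_enhancers(ps2, stitch_gap = 12500)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$start, 0); expect_equal(d2$end, 5100)
  expect_equal(d2$n_constituents, 2L)
  expect_equal(d2$total_signal, 5)
})

test_that("stitching matches the transitive-closure oracle and is idempotent", {
  set.seed(50)
  for (trial in 1:10) {
    df <- random_peak_df(100, max_pos = 20000)
    gap <- sample(c(50, 200, 1000), 1)
    got <- stitch_enhancers(as_ps(df), stitch_gap = gap)
    sorted <- df[order(df$chrom, df$start, df$end), ]
    want <- oracle_stitch(sorted, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_constituents, want$n)
    expect_equal(got$total_signal, want$total, tolerance = 1e-9)
    # constituent conservation
    expect_equal(sum(got$n_constituents), nrow(df))
  }
})

test_that("classify_super places the elbow cutoff correctly", {
  # one domain 100x all others is the only super
  ps <- peak_set(rep("chr1", 10), (0:9) * 100000, (0:9) * 100000 + 1000,
                 score = c(rep(1, 9) + runif(9, 0, 0.1), 100))
  d <- classify_super(stitch_enhancers(ps, 100))
  expect_equal(sum(d$is_super), 1)
  expect_true(d$is_super[which.max(d$total_signal)])

  # exactly linear scaled curve: tie resolved to the top-ranked point
  lin <- peak_set(rep("chr1", 8), (0:7) * 100000, (0:7) * 100000 + 1000,
                  score = 1:8)
  dl <- classify_super(stitch_enhancers(lin, 100))
  expect_equal(sum(dl$is_super), 1)
  expect_true(dl$is_super[which.max(dl$total_signal)])

  # fewer than 3 domains: all typical with a warning
  two <- peak_set(c("chr1", "chr1"), c(0, 100000), c(1000, 101000),
                  score = c(1, 50))
  expect_warning(dt <- classify_super(stitch_enhancers(two, 100)),
                 "fewer than 3")
  expect_false(any(dt$is_super))

  # the super set is an upper set in signal rank
  set.seed(51)
  ps3 <- peak_set(rep("chr1", 50), (0:49) * 100000, (0:49) * 100000 + 1000,
                  score = rlnorm(50, 1, 1.3))
  d3 <- classify_super(stitch_enhancers(ps3, 100))
  if (any(d3$is_super))
    expect_true(min(d3$total_signal[d3$is_super]) >=
                  max(d3$total_signal[!d3$is_super]))
})

test_that("fragmentation statistics detect the planted regime and stay silent on null", {
  land <- simulate_enhancer_landscape(seed = 52)
  doms <- lapply(land, function(p) classify_super(stitch_enhancers(p)))
  fs <- fragmentation_stats(doms, attr(land, "group_ages"))
  expect_gt(fs$trends[["n_super"]], 0)
  expect_lt(fs$trends[["mean_super_length"]], 0)

  # identical domain sets: all trends 0
  same <- fragmentation_stats(list(a = doms[[1]], b = doms[[1]]), c(25, 65))
  expect_true(all(same$trends == 0))

  expect_error(fragmentation_stats(doms[1], 25), "2 age groups")

  # null generator rarely produces strong trends
  strong <- 0L
  for (s in 1:20) {
    l0 <- simulate_enhancer_landscape(fragmentation_rate = 0,
                                      signal_noise_sd = 0.15, seed = 500 + s)
    d0 <- lapply(l0, function(p) classify_super(stitch_enhancers(p)))
    t0 <- fragmentation_stats(d0, attr(l0, "group_ages"))$trends
    if (abs(t0[["n_super"]]) > 0.8 && abs(t0[["mean_super_length"]]) > 0.8)
      strong <- strong + 1L
  }
  expect_lte(strong, 2L)
})

test_that("loess trajectory reproduces known inflections and ignores linear signal", {
  set.seed(53)
  ages <- seq(5, 75, length.out = 200)

  # logistic centered at 40: exactly one inflection within +/- 2 y
  sig <- plogis((ages - 40) / 5)
  tj <- loess_trajectory(ages, sig, span = 0.3)
  expect_equal(length(tj$inflection_ages), 1)
  expect_lt(abs(tj$inflection_ages - 40), 2)

  # linear signal: no curvature
  lin <- loess_trajectory(ages, 0.2 * ages + 3)
  expect_equal(length(lin$inflection_ages), 0)

  # constant signal: flat fit, no inflections
  cst <- loess_trajectory(ages, rep(2, 200))
  expect_equal(length(cst$inflection_ages), 0)

  # span = 1 with linear data reproduces the least-squares line
  y <- 1.5 * ages - 7
  tj1 <- loess_trajectory(ages, y, span = 1)
  ols <- lm(y ~ ages)
  pred <- predict(ols, data.frame(ages = tj1$age_grid))
  expect_equal(tj1$fitted, unname(pred), tolerance = 1e-6)

  expect_error(loess_trajectory(ages[1:5], sig[1:5]), "10 samples")
  expect_error(loess_trajectory(ages, sig, span = 0), "span")
})
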