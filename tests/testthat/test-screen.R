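test_that("spearman_screen reproduces hand and oracle rank correlations", {
  ages <- c(10, 20, 30, 40, 50)
  x <- rbind(age_copy = ages,
             toy = c(2, 1, 4, 3, 5),
             flat = rep(7, 5))
  tab <- spearman_screen(x, ages)
  expect_equal(tab$rho[1], 1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4 => 0.8
  expect_equal(tab$rho[2], 0.8)
  expect_true(is.na(tab$rho[3]))
  expect_false(candidate_filter(tab)$is_candidate[3])

  expect_error(spearman_screen(x[, 1:3], ages[1:3]), "4 samples")
  expect_error(spearman_screen(x, rep(5, 5)), "ages")
})

test_that("spearman_screen agrees with cor.test on tied small instances", {
  set.seed(11)
  for (trial in 1:100) {
    n <- sample(5:8, 1)
    ages <- sample(1:5, n, replace = TRUE)
    if (length(unique(ages)) < 2) next
    x <- matrix(sample(1:4, 3 * n, replace = TRUE), 3, n)
    x <- x[apply(x, 1, sd) > 0, , drop = FALSE]
    if (!nrow(x)) next
    tab <- spearman_screen(x, ages)
    for (g in seq_len(nrow(x))) {
      want <- suppressWarnings(cor.test(x[g, ], ages, method = "spearman"))
      expect_equal(tab$rho[g], unname(want$estimate), tolerance = 1e-12)
    }
  }
})

test_that("exact permutation p-values match the t-approximation in rank order", {
  set.seed(12)
  ages <- c(3, 9, 15, 27, 41, 60)
  x <- matrix(rnorm(30), 5, 6)
  exact <- spearman_screen(x, ages, exact = TRUE)
  approx <- spearman_screen(x, ages)
  expect_equal(order(exact$p), order(approx$p))
  expect_true(all(exact$p >= 0 & exact$p <= 1))
  expect_error(spearman_screen(matrix(rnorm(18), 2, 9), 1:9, exact = TRUE),
               "n <= 8")
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (trial in 1:100) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("candidate_filter applies inclusive joint thresholds", {
  tab <- data.frame(rho = c(0.5, 0.49, -0.6, -0.5),
                    p = c(0.05, 0.001, 0.2, 0.04))
  out <- candidate_filter(tab, r_min = 0.5, p_max = 0.05)
  expect_equal(out$is_candidate, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$direction, c("positive", "none", "none", "negative"))
})

test_that("screening recovers planted monotone peaks", {
  sim <- simulate_chipseq(n_peaks = 2000, n_samples = 60,
                          fraction_linear = 0.1, fraction_nonlinear = 0,
                          exact = TRUE, seed = 21)
  tab <- candidate_filter(spearman_screen(sim$signal))
  planted <- sim$truth$peak_table$label != "null"
  sens <- sum(tab$is_candidate & planted) / sum(planted)
  fdr <- sum(tab$is_candidate & !planted) / max(1, sum(tab$is_candidate))
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
  # planted correlations sit near the calibrated 0.7
  expect_lt(abs(mean(abs(tab$rho[planted])) - 0.7), 0.1)
  # directions match the planted signs
  lab <- sim$truth$peak_table$label
  hit <- tab$is_candidate & planted
  expect_true(all(tab$direction[hit & lab == "linear+"] == "positive"))
  expect_true(all(tab$direction[hit & lab == "linear-"] == "negative"))
})

test_that("pc1_age_correlation finds rank-1 age structure and respects nulls", {
  ages <- seq(20, 70, length.out = 12)
  x <- rbind(ages * 2 + 5, matrix(1, 4, 12))
  res <- pc1_age_correlation(x, ages)
  expect_equal(abs(res$r), 1, tolerance = 1e-9)

  # duplicated samples get identical scores
  xd <- cbind(x, x[, 1])
  resd <- pc1_age_correlation(xd, c(ages, ages[1]))
  expect_equal(resd$scores[1], resd$scores[13])

  # pure noise: |r| small, p > 0.05 in at least 90% of runs
  set.seed(14)
  high_p <- 0L
  for (trial in 1:100) {
    xn <- matrix(rnorm(20 * 50), 20, 50)
    rn <- pc1_age_correlation(xn, runif(50, 5, 75))
    if (rn$p > 0.05) high_p <- high_p + 1L
  }
  expect_gte(high_p, 90)
})

test_that("fisher_enrichment matches the hypergeometric enumeration oracle", {
  expect_equal(fisher_enrichment(2, 2, 2, 2)$p, 1)
  expect_equal(fisher_enrichment(3, 1, 1, 3)$p, 34 / 70, tolerance = 1e-9)
  expect_lt(fisher_enrichment(50, 0, 0, 50)$p, 1e-20)
  expect_error(fisher_enrichment(0, 0, 3, 4), "margin")

  set.seed(15)
  for (trial in 1:100) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- fisher_enrichment(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got$p, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                        tab[2, 1], tab[2, 2]),
                 tolerance = 1e-7)
    # transposition symmetry
    tp <- fisher_enrichment(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
    expect_equal(got$p, tp$p, tolerance = 1e-9)
  }
})
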