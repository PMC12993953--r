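# latent log2 matrices with planted batch structure come straight from the
# generator's exact mode (truth$latent = baseline + age effect + batch + noise)
latent_with_batch <- function(seed, n_peaks = 200, n_samples = 60,
                              fraction_linear = 0, batch_shift = 2,
                              batch_scale = 2, batch_labels = NULL) {
  sim <- simulate_chipseq(n_peaks = n_peaks, n_samples = n_samples,
                          fraction_linear = fraction_linear,
                          fraction_nonlinear = 0, n_batches = 2,
                          batch_shift = batch_shift, batch_scale = batch_scale,
                          batch_labels = batch_labels,
                          exact = TRUE, seed = seed)
  list(x = sim$truth$latent, samples = sim$samples, truth = sim$truth)
}

test_that("single batch is returned unchanged with a warning", {
  set.seed(1)
  m <- matrix(rnorm(50), 10, 5)
  expect_warning(res <- fit_adjust(m, batch = rep("a", 5),
                                   covariates = NULL), "single batch")
  expect_equal(res$corrected, m)
})

test_that("confounded covariates raise an error naming the aliased column", {
  set.seed(2)
  m <- matrix(rnorm(120), 10, 12)
  batch <- rep(c("a", "b"), each = 6)
  covs <- data.frame(age = ifelse(batch == "a", 30, 60))  # perfectly aliased
  expect_error(fit_adjust(m, batch = batch, covariates = covs),
               "rank-deficient|aliased")
})

test_that("planted location/scale batch effects are removed", {
  d <- latent_with_batch(seed = 31)
  batch <- d$samples$batch
  res <- fit_adjust(d$x, batch = batch,
                    covariates = data.frame(age = d$samples$age,
                                            sex = d$samples$sex))
  z <- res$corrected
  i1 <- batch == "batch1"; i2 <- batch == "batch2"

  mean_diff_before <- abs(rowMeans(d$x[, i2]) - rowMeans(d$x[, i1]))
  mean_diff_after <- abs(rowMeans(z[, i2]) - rowMeans(z[, i1]))
  expect_lt(mean(mean_diff_after), 0.15)        # ~2 planted, near 0 after
  expect_lt(mean(mean_diff_after), mean(mean_diff_before) / 5)

  var_ratio_after <- apply(z[, i2], 1, var) / apply(z[, i1], 1, var)
  expect_lt(abs(median(var_ratio_after) - 1), 0.35)  # planted ratio was 4

  # per-feature grand means preserved within tolerance
  expect_lt(max(abs(rowMeans(z) - rowMeans(d$x))), 0.05)

  # EB model bookkeeping: positive shrunk variances, one pair per batch/feature
  expect_true(all(res$model$delta_star > 0))
  expect_equal(dim(res$model$gamma_star), c(2, 200))
})

test_that("no planted effect: batch mean differences shrink toward zero", {
  d <- latent_with_batch(seed = 32, batch_shift = 0, batch_scale = 1)
  batch <- d$samples$batch
  res <- fit_adjust(d$x, batch = batch,
                    covariates = data.frame(age = d$samples$age))
  i1 <- batch == "batch1"; i2 <- batch == "batch2"
  before <- mean(abs(rowMeans(d$x[, i2]) - rowMeans(d$x[, i1])))
  after <- mean(abs(rowMeans(res$corrected[, i2]) - rowMeans(res$corrected[, i1])))
  expect_lt(after, before)
  expect_lt(after, 0.1)
})

test_that("correction approximately matches the reference ComBat implementation", {
  skip_if_not_installed("sva")
  d <- latent_with_batch(seed = 33, fraction_linear = 0.2)
  mod <- stats::model.matrix(~ age + sex, data = d$samples)
  ref <- suppressMessages(
    sva::ComBat(dat = d$x, batch = d$samples$batch, mod = mod))
  res <- fit_adjust(d$x, batch = d$samples$batch,
                    covariates = data.frame(age = d$samples$age,
                                            sex = d$samples$sex))
  expect_lt(max(abs(res$corrected - ref)), 0.02)
})

test_that("age signal survives correction (covariate preservation)", {
  # batches correlated with age make the uncorrected slope biased
  wins <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    ages <- runif(60, 5, 75)
    batch_labels <- ifelse(xor(ages > 40, runif(60) < 0.25), "b2", "b1")
    sim <- simulate_chipseq(n_peaks = 60, ages = ages, fraction_linear = 0.5,
                            fraction_nonlinear = 0, batch_shift = 2,
                            batch_scale = 1.5, batch_labels = batch_labels,
                            exact = TRUE, seed = 100 + r)
    x <- sim$truth$latent
    truth_beta <- sim$truth$peak_table$beta / diff(range(c(5, 75)))  # per-year slope
    u <- sim$samples$age
    slope_of <- function(m) apply(m, 1, function(v) coef(lm(v ~ u))[2])
    res <- fit_adjust(x, batch = sim$samples$batch,
                      covariates = data.frame(age = u))
    err_raw <- mean(abs(slope_of(x) - truth_beta))
    err_cor <- mean(abs(slope_of(res$corrected) - truth_beta))
    if (err_cor < err_raw) wins <- wins + 1L
  }
  expect_gte(wins, 0.9 * n_rep)
})

test_that("batch_diagnostics reports F reduction and handles degenerate features", {
  d <- latent_with_batch(seed = 34)
  res <- fit_adjust(d$x, batch = d$samples$batch,
                    covariates = data.frame(age = d$samples$age))
  dg <- batch_diagnostics(d$x, res$corrected, d$samples$batch)
  expect_lt(dg$mean_f_after, dg$mean_f_before)
  expect_lt(dg$pc_batch_r2_after, dg$pc_batch_r2_before)

  # identical matrices give identical diagnostics
  dg0 <- batch_diagnostics(d$x, d$x, d$samples$batch)
  expect_equal(dg0$mean_f_before, dg0$mean_f_after)

  # constant feature is NA and excluded from the mean
  xc <- rbind(d$x, 3)
  dgc <- batch_diagnostics(xc, xc, d$samples$batch)
  expect_true(is.na(dgc$f_before[nrow(xc)]))
  expect_false(is.na(dgc$mean_f_before))
})

test_that("re-correcting corrected data changes little (approximate idempotence)", {
  d <- latent_with_batch(seed = 35)
  res1 <- fit_adjust(d$x, batch = d$samples$batch,
                     covariates = data.frame(age = d$samples$age))
  res2 <- fit_adjust(res1$corrected, batch = d$samples$batch,
                     covariates = data.frame(age = d$samples$age))
  delta1 <- mean(abs(res1$corrected - d$x))
  delta2 <- mean(abs(res2$corrected - res1$corrected))
  expect_lt(delta2, delta1 / 10)
  expect_lt(delta2, 0.02)
})
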