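test_that("make_age_groups partitions the range and merges empty bins", {
  g <- make_age_groups(1:11, 11)
  expect_equal(as.integer(table(g)), rep(1L, 11))

  ages <- c(rep(10, 5), rep(70, 5))  # 9 interior bins empty
  expect_message(g2 <- make_age_groups(ages, 11), "empty")
  expect_equal(nlevels(droplevels(g2)), 2)
  expect_equal(length(g2), 10)
  expect_error(make_age_groups(rep(5, 4), 3), "equal")
})

test_that("fit_elastic_net honors the penalized least-squares objective", {
  set.seed(20)
  n <- 10
  x <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("f", 1:3), NULL))
  y <- rnorm(n, 30, 10)

  # full shrinkage: no features, intercept = mean(y)
  big <- fit_elastic_net(x, y, alpha = 1, lambda = 1e6)
  expect_equal(length(big$features), 0)
  expect_equal(big$intercept, mean(y))

  # ridge limit matches the closed form (X'X + n*lambda*I)^{-1} X'y
  lam <- 0.7
  ridge <- fit_elastic_net(x, y, alpha = 0, lambda = lam)
  want <- oracle_ridge(t(x), y, lam)
  got_w <- setNames(numeric(3), paste0("f", 1:3))
  got_w[ridge$features] <- ridge$coefficients
  expect_equal(unname(got_w), want$w, tolerance = 1e-6)
  expect_equal(ridge$intercept, want$intercept, tolerance = 1e-6)

  # realizable fit: y linear in one feature
  y2 <- 5 + 3 * x[1, ]
  lasso <- fit_elastic_net(x, y2, alpha = 1, lambda = 1e-6)
  pred <- lasso$intercept + crossprod(x[lasso$features, , drop = FALSE],
                                      lasso$coefficients)
  expect_gt(cor(as.numeric(pred), y2), 0.999)

  expect_error(fit_elastic_net(x, y, alpha = 2, lambda = 1), "alpha")
  expect_error(fit_elastic_net(x, y, alpha = 0.5, lambda = -1), "lambda")
})

test_that("sparsity is monotone non-increasing along the lambda path", {
  set.seed(21)
  x <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(30, 50, 15)
  lams <- exp(seq(log(0.01), log(5), length.out = 12))
  nz <- vapply(lams, function(l)
    length(fit_elastic_net(x, y, alpha = 0.5, lambda = l)$features),
    numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("histone_clock recovers a noise-free linear signal and its CV bookkeeping holds", {
  set.seed(22)
  ages <- runif(30, 5, 75)
  x <- rbind(ages / 10 + 1, matrix(rnorm(10 * 30, 5, 1), 10, 30))
  rownames(x) <- paste0("p", 1:11)
  fit <- histone_clock(x, ages, n_groups = 2, alpha = c(0.5, 1), nlambda = 40)
  expect_s3_class(fit, "histone_clock")
  expect_gte(fit$cv$r, 0.99)
  # every sample predicted exactly once across folds
  expect_equal(length(fit$cv$predictions), 30)
  expect_true(all(is.finite(fit$cv$predictions)))
  # methods
  expect_length(coef(fit), length(fit$features) + 1)
  expect_equal(residuals(fit), ages - fit$fitted.values)
  expect_output(print(fit), "LOGO-CV")
  expect_output(print(summary(fit)), "hyperparameters")
})

test_that("pure-noise features show no optimistic cross-validation bias", {
  # with age-stratified hold-out groups, uninformative features drive the
  # pooled out-of-fold predictions toward each training set's mean age, so
  # the null CV correlation is at or below zero -- never spuriously high
  set.seed(23)
  rs <- replicate(10, {
    ages <- runif(60, 5, 75)
    x <- matrix(rnorm(50 * 60), 50, 60)
    fit <- histone_clock(x, ages, n_groups = 4, alpha = 0.5, nlambda = 20)
    r <- suppressWarnings(cor(fit$cv$predictions, ages))
    if (is.na(r)) 0 else r
  })
  expect_lt(mean(rs), 0.1)
})

test_that("predict_age is deterministic, matches hand arithmetic, and checks features", {
  model <- structure(list(
    features = c("a", "b"), coefficients = c(2, -1), intercept = 40,
    standardization = list(mean = c(10, 5), sd = c(2, 1))),
    class = "histone_clock")
  x <- matrix(c(12, 4, 10, 5), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  # s1: 40 + 2*(12-10)/2 - 1*(4-5)/1 = 43; s2: 40 + 0 - 0 = 40
  expect_equal(unname(predict(model, x)), c(43, 40))
  expect_equal(predict(model, x), predict(model, x))
  expect_error(predict(model, x[1, , drop = FALSE]), "missing.*b")

  # permuting sample order permutes predictions identically
  expect_equal(unname(predict(model, x[, 2:1])), c(40, 43))
})

test_that("no training information leaks from held-out groups", {
  set.seed(24)
  sim <- simulate_chipseq(n_peaks = 100, n_samples = 40, fraction_linear = 0.2,
                          fraction_nonlinear = 0, exact = TRUE, seed = 24)
  x <- sim$signal$values
  ages <- sim$samples$age
  groups <- make_age_groups(ages, 4)
  hold <- levels(groups)[1]
  train_idx <- which(groups != hold)
  # standardization for the fold must equal what a model fitted without
  # those samples would use
  std_fold <- standardize_features(x, fit_columns = train_idx)
  std_alone <- standardize_features(x[, train_idx])
  expect_equal(std_fold$mean, std_alone$mean)
  expect_equal(std_fold$sd, std_alone$sd)
})

test_that("selected features overlap the planted informative set", {
  sim <- simulate_chipseq(n_peaks = 400, n_samples = 80, fraction_linear = 0.1,
                          fraction_nonlinear = 0, exact = TRUE, seed = 25)
  z <- standardize_features(sim$signal$values)$standardized
  fit <- histone_clock(z, sim$samples$age, n_groups = 6,
                       alpha = c(0.5, 1), nlambda = 50)
  planted <- sim$truth$peak_table$peak[sim$truth$peak_table$label != "null"]
  jac <- length(intersect(fit$features, planted)) /
    length(union(fit$features, planted))
  expect_gte(jac, 0.3)
})

test_that("accuracy_metrics computes RMSE, MAE and Pearson r", {
  expect_equal(accuracy_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, mae = 0, r = 1))
  m <- accuracy_metrics(c(10, 20, 30), c(12, 18, 33))
  expect_equal(m$mae, 7 / 3)
  expect_equal(m$rmse, sqrt(17 / 3))
  expect_equal(accuracy_metrics(1:5, 5:1)$r, -1)
  expect_true(is.na(accuracy_metrics(1:4, rep(2, 4))$r))
  expect_error(accuracy_metrics(1:3, 1:4), "mismatch")
})

test_that("age_gap computes per-sample gaps and paired scaled-gap tests", {
  sim <- simulate_paired_treatment(n_pairs = 10, rejuvenation_factor = 0.8,
                                   seed = 26)
  # train a clock on independent healthy samples from the same regime
  healthy <- simulate_chipseq(n_peaks = 500, n_samples = 60,
                              age_range = c(20, 70), fraction_linear = 0.2,
                              fraction_nonlinear = 0, noise_sd = 0.3,
                              n_batches = 1, exact = TRUE, seed = 27)
  fit <- histone_clock(log2_transform_for_test(healthy$signal),
                       healthy$samples$age, n_groups = 5,
                       alpha = 0.5, nlambda = 40)
  res <- age_gap(fit, log2_transform_for_test(sim$signal), sim$samples)
  expect_equal(length(res$scaled_gap), 10)
  expect_lt(res$mean_scaled_gap, -0.05)   # planted rejuvenation detected
  expect_lt(res$p, 0.05)

  # identical pre/post predictions: scaled gaps 0, t flagged NA
  model0 <- structure(list(features = character(), coefficients = numeric(),
                           intercept = 45,
                           standardization = list(mean = numeric(),
                                                  sd = numeric())),
                      class = "histone_clock")
  res0 <- age_gap(model0, sim$signal, sim$samples)
  expect_true(all(res0$scaled_gap == 0))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$t))

  # unpaired pair id errors
  bad <- sim$samples
  bad$pair_id[1] <- "pairXX"
  expect_error(age_gap(fit, sim$signal, bad), "exactly once")
})

test_that("clock JSON serialization round-trips predictions", {
  set.seed(28)
  ages <- runif(30, 10, 70)
  x <- rbind(ages + rnorm(30, 0, 2), matrix(rnorm(5 * 30), 5, 30))
  rownames(x) <- paste0("chr1:", 1:6 * 100, "-", 1:6 * 100 + 50)
  fit <- histone_clock(x, ages, n_groups = 3, alpha = 0.5, nlambda = 20)
  f <- withr::local_tempfile(fileext = ".json")
  write_clock(fit, f)
  back <- read_clock(f)
  expect_equal(predict(back, x), predict(fit, x))
})
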