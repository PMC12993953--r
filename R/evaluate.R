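#' Gaussian-noise robustness protocol
#'
#' Measures how a fixed, already-trained clock degrades as i.i.d.
#' Gaussian noise of increasing standard deviation is added to the
#' standardized feature values of the evaluation samples. The default
#' grid runs from 0 to 1.5 in increments of 0.3 (noise is in SD units of
#' the standardized features). At sigma = 0 no noise is drawn, so the
#' baseline RMSE is reproduced bit-exactly.
#'
#' @param model a fitted `histone_clock`.
#' @param x evaluation `signal_matrix` or matrix (features in rows, on
#'   the same scale the model was trained on — the model's stored
#'   standardization is applied internally).
#' @param y true ages of the evaluation samples.
#' @param sigma_grid non-negative noise SDs (default
#'   `seq(0, 1.5, by = 0.3)`).
#' @param n_reps repetitions per sigma (default 20).
#' @param seed RNG seed; the curve is bit-reproducible for a fixed seed.
#' @return An object of class `robustness_curve`: list with
#'   `sigma_grid`, `rmse_mean`, `rmse_sem`, `relative_rmse`
#'   (rmse(sigma)/rmse(0)), `rmse_reps` (n_reps x n_sigma matrix),
#'   `n_reps`, `seed`.
#' @export
noise_robustness <- function(model, x, y, sigma_grid = seq(0, 1.5, by = 0.3),
                             n_reps = 20, seed = 1) {
  if (any(sigma_grid < 0)) stop("noise SDs must be non-negative")
  if (n_reps < 1) stop("n_reps must be >= 1")
  mat <- signal_values(x)
  if (is.null(rownames(mat)) && inherits(x, "signal_matrix"))
    rownames(mat) <- peak_ids(x$peaks)
  idx <- match(model$features, rownames(mat))
  if (anyNA(idx))
    stop("model features missing from x: ",
         paste(model$features[is.na(idx)], collapse = ", "))
  z <- (mat[idx, , drop = FALSE] - model$standardization$mean) /
    model$standardization$sd
  w <- model$coefficients
  predict_z <- function(zz) model$intercept + as.numeric(crossprod(zz, w))

  set.seed(seed)
  rmse_reps <- matrix(NA_real_, n_reps, length(sigma_grid))
  for (si in seq_along(sigma_grid)) {
    s <- sigma_grid[si]
    for (r in seq_len(n_reps)) {
      zz <- if (s == 0) z
            else z + matrix(stats::rnorm(length(z), 0, s), nrow(z), ncol(z))
      rmse_reps[r, si] <- sqrt(mean((y - predict_z(zz))^2))
    }
  }
  rmse_mean <- colMeans(rmse_reps)
  rmse_sem <- apply(rmse_reps, 2, stats::sd) / sqrt(n_reps)
  structure(list(sigma_grid = sigma_grid, rmse_mean = rmse_mean,
                 rmse_sem = rmse_sem,
                 relative_rmse = rmse_mean / rmse_mean[sigma_grid == 0][1],
                 rmse_reps = rmse_reps, n_reps = n_reps, seed = seed),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("Noise-robustness curve\n")
  print(data.frame(sigma = x$sigma_grid, rmse = x$rmse_mean,
                   sem = x$rmse_sem, relative = x$relative_rmse))
  invisible(x)
}

#' Compare two robustness curves by per-sigma Mann-Whitney tests
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests on the
#' per-repetition RMSE distributions of two curves at each shared noise
#' level; exact enumeration for small untied samples, normal
#' approximation with tie correction otherwise.
#'
#' @param curve_a,curve_b `robustness_curve` objects on identical sigma
#'   grids with stored per-rep errors.
#' @return data frame with sigma, U statistic and two-sided p per level.
#' @export
compare_curves <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$sigma_grid, curve_b$sigma_grid)))
    stop("sigma grids differ")
  res <- lapply(seq_along(curve_a$sigma_grid), function(i) {
    a <- curve_a$rmse_reps[, i]; b <- curve_b$rmse_reps[, i]
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !any(duplicated(c(a, b)))
    wt <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
    data.frame(sigma = curve_a$sigma_grid[i], U = unname(wt$statistic),
               p = wt$p.value)
  })
  do.call(rbind, res)
}

#' Quantile rank of a clock's RMSE in a reference distribution
#'
#' Midrank convention: q = (#\{ref < rmse\} + 0.5 * #\{ref = rmse\}) /
#' #ref. A lower quantile means the clock outperforms more of the
#' reference predictors.
#'
#' @param clock_rmse the clock's RMSE.
#' @param reference_rmses numeric vector of reference RMSEs (e.g., the
#'   RMSE distribution of 100 benchmark predictions).
#' @return quantile in \[0, 1\].
#' @export
quantile_rank <- function(clock_rmse, reference_rmses) {
  if (!length(reference_rmses)) stop("reference list must be nonempty")
  (sum(reference_rmses < clock_rmse) +
     0.5 * sum(reference_rmses == clock_rmse)) / length(reference_rmses)
}

#' Sample-size saturation analysis
#'
#' Quantifies whether additional training samples still change the
#' model: per repetition, a fixed test set is held out, the remaining
#' samples are split into two disjoint halves, and for each training
#' size n one clock is trained on n samples from each half; the Pearson
#' correlation between the two clocks' predictions on the shared test
#' set measures model stability at that n. With `doubled = TRUE` every
#' sample is first duplicated (exact copies), approximating the curve at
#' larger effective sample sizes ("estimated" mode).
#'
#' @param x `signal_matrix` or matrix, features in rows.
#' @param y ages per sample.
#' @param n_grid strictly increasing training sizes; default 6 log-spaced
#'   sizes from 10 to the available half-size.
#' @param n_reps repetitions (default 5).
#' @param test_fraction held-out fraction (default 0.2).
#' @param doubled duplicate every sample first (estimated mode).
#' @param seed RNG seed.
#' @param n_groups,alpha,nlambda passed to [histone_clock] for each
#'   training run.
#' @return `saturation_curve`: list with `n_grid`, `r_mean`, `r_sd`,
#'   `r_reps`, `mode`, `n_reps`, `seed`.
#' @export
saturation_analysis <- function(x, y, n_grid = NULL, n_reps = 5,
                                test_fraction = 0.2, doubled = FALSE,
                                seed = 1, n_groups = 5, alpha = c(0.5),
                                nlambda = 30) {
  mat <- signal_values(x)
  if (is.null(rownames(mat)))
    rownames(mat) <- if (inherits(x, "signal_matrix")) peak_ids(x$peaks)
                     else paste0("f", seq_len(nrow(mat)))
  if (doubled) {
    mat <- cbind(mat, mat)
    colnames(mat) <- make.unique(colnames(mat) %||%
                                   as.character(seq_len(ncol(mat))))
    y <- c(y, y)
  }
  n <- ncol(mat)
  half <- floor((1 - test_fraction) * n / 2)
  if (is.null(n_grid))
    n_grid <- unique(round(exp(seq(log(10), log(half), length.out = 6))))
  if (any(diff(n_grid) <= 0)) stop("n_grid must be strictly increasing")
  if (max(n_grid) > half)
    stop(sprintf("n_grid exceeds available half-size (%d)", half))

  set.seed(seed)
  r_reps <- matrix(NA_real_, n_reps, length(n_grid))
  for (rep_i in seq_len(n_reps)) {
    test <- sample(n, max(1, round(test_fraction * n)))
    rest <- sample(setdiff(seq_len(n), test))
    a_idx <- rest[seq_len(half)]
    b_idx <- rest[half + seq_len(half)]
    for (ni in seq_along(n_grid)) {
      nn <- n_grid[ni]
      ia <- a_idx[seq_len(nn)]; ib <- b_idx[seq_len(nn)]
      pa <- train_and_predict(mat, y, ia, test, n_groups, alpha, nlambda)
      pb <- train_and_predict(mat, y, ib, test, n_groups, alpha, nlambda)
      r_reps[rep_i, ni] <- if (stats::sd(pa) == 0 || stats::sd(pb) == 0)
        NA_real_ else stats::cor(pa, pb)
    }
  }
  structure(list(n_grid = n_grid, r_mean = colMeans(r_reps, na.rm = TRUE),
                 r_sd = apply(r_reps, 2, stats::sd, na.rm = TRUE),
                 r_reps = r_reps,
                 mode = if (doubled) "estimated" else "observed",
                 n_reps = n_reps, seed = seed),
            class = "saturation_curve")
}

train_and_predict <- function(mat, y, train_idx, test_idx,
                              n_groups, alpha, nlambda) {
  ng <- min(n_groups, length(unique(y[train_idx])))
  fit <- histone_clock(mat[, train_idx, drop = FALSE], y[train_idx],
                       n_groups = ng, alpha = alpha, nlambda = nlambda)
  predict(fit, mat[, test_idx, drop = FALSE])
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("Saturation curve (%s mode, %d reps)\n", x$mode, x$n_reps))
  print(data.frame(n = x$n_grid, r_mean = x$r_mean, r_sd = x$r_sd))
  invisible(x)
}
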