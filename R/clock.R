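#' Age-stratified groups for leave-one-group-out cross-validation
#'
#' Partitions the age range into `n_groups` bins. In `"width"` mode
#' (default) the bins are equal-width over \[min age, max age\], so each
#' group spans a similar age range; `"quantile"` mode uses equal-count
#' quantile bins instead. Bins left empty by clustered ages are dropped,
#' so the realized group count may be smaller than requested (a message
#' is emitted).
#'
#' @param ages numeric ages in years.
#' @param n_groups requested number of groups (default 11).
#' @param mode `"width"` or `"quantile"`.
#' @return factor of group labels, ordered by age.
#' @export
make_age_groups <- function(ages, n_groups = 11, mode = c("width", "quantile")) {
  mode <- match.arg(mode)
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (length(unique(ages)) < 2) stop("ages must not all be equal")
  breaks <- if (mode == "width")
    seq(min(ages), max(ages), length.out = n_groups + 1)
  else
    unique(stats::quantile(ages, probs = seq(0, 1, length.out = n_groups + 1)))
  bin <- findInterval(ages, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  occupied <- sort(unique(bin))
  if (length(occupied) < n_groups)
    message(sprintf("%d of %d age bins are empty; %d groups realized",
                    n_groups - length(occupied), n_groups, length(occupied)))
  factor(match(bin, occupied), levels = seq_along(occupied),
         labels = paste0("g", seq_along(occupied)))
}

#' Fit an elastic net at fixed hyperparameters
#'
#' Minimizes (1/2n) * sum (y - yhat)^2 + lambda * (alpha * ||w||_1 +
#' (1 - alpha)/2 * ||w||_2^2) with an unpenalized intercept, on features
#' assumed already standardized. Zero-coefficient features are dropped
#' from the returned model.
#'
#' @param x numeric matrix, features in rows, samples in columns
#'   (standardized), or a `signal_matrix`.
#' @param y numeric response (ages in years).
#' @param alpha L1 mixing fraction in \[0, 1\].
#' @param lambda penalty >= 0.
#' @return list with `features`, `coefficients` (nonzero only),
#'   `intercept`, `alpha`, `lambda`.
#' @export
fit_elastic_net <- function(x, y, alpha, lambda) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  mat <- signal_values(x)
  if (length(y) != ncol(mat)) stop("length(y) must equal ncol(x)")
  # the solver scales the quadratic penalty term by the population SD of
  # y; reparameterize (alpha, lambda) so the stated objective holds
  sy <- sqrt(mean((y - mean(y))^2))
  a_l1 <- lambda * alpha
  b_l2 <- lambda * (1 - alpha) * sy
  lam_g <- a_l1 + b_l2
  alpha_g <- if (lam_g > 0) a_l1 / lam_g else alpha
  cf <- glmnet_coef_at(t(mat), y, alpha_g, lam_g)
  ids <- rownames(mat) %||% paste0("f", seq_len(nrow(mat)))
  w <- cf[-1]
  nz <- which(w != 0)
  list(features = ids[nz], coefficients = w[nz], intercept = cf[1],
       alpha = alpha, lambda = lambda)
}

# internal: solver-scale coefficients at one penalty (exact refit)
glmnet_coef_at <- function(tx, y, alpha, lambda) {
  fit <- glmnet::glmnet(tx, y, alpha = alpha, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = tx, y = y,
                         alpha = alpha, standardize = FALSE,
                         thresh = 1e-12, maxit = 1e6))
}

# internal: pooled LOGO-CV search over an alpha grid with per-alpha
# lambda paths derived from the full data
logo_cv_engine <- function(mat, y, groups, alpha_grid, nlambda) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  if (any(table(groups) == length(y)))
    stop("a single group contains all samples")
  ids <- rownames(mat) %||% paste0("f", seq_len(nrow(mat)))
  rownames(mat) <- ids

  full_std <- standardize_features(mat)
  paths <- lapply(alpha_grid, function(a) {
    glmnet::glmnet(t(signal_values(full_std$standardized)), y,
                   alpha = a, nlambda = nlambda, standardize = FALSE)$lambda
  })

  fold_idx <- split(seq_along(y), groups)
  n <- length(y)
  grid <- list()
  best <- list(rmse = Inf)
  cv_pred_store <- list()
  for (ai in seq_along(alpha_grid)) {
    a <- alpha_grid[ai]
    path <- paths[[ai]]
    preds <- matrix(NA_real_, n, length(path))
    for (fold in fold_idx) {
      train <- setdiff(seq_len(n), fold)
      std <- standardize_features(mat, fit_columns = train)
      zs <- signal_values(std$standardized)
      fit <- glmnet::glmnet(t(zs[, train, drop = FALSE]), y[train],
                            alpha = a, lambda = path, standardize = FALSE)
      # fold paths can stop early at saturation; interpolation to the
      # common grid is intended, so its note is silenced
      preds[fold, ] <- suppressWarnings(
        stats::predict(fit, t(zs[, fold, drop = FALSE]), s = path))
    }
    rmse_path <- sqrt(colMeans((preds - y)^2))
    grid[[ai]] <- data.frame(alpha = a, lambda = path, cv_rmse = rmse_path)
    # ties broken toward larger lambda (the sparser model)
    ok <- which(rmse_path <= min(rmse_path) + 1e-12)
    j <- ok[which.max(path[ok])]
    if (rmse_path[j] < best$rmse - 1e-12 ||
        (abs(rmse_path[j] - best$rmse) <= 1e-12 && path[j] > best$lambda)) {
      best <- list(alpha = a, lambda = path[j], rmse = rmse_path[j],
                   pred = preds[, j])
    }
  }
  list(best = best, grid = do.call(rbind, grid), groups = groups,
       full_std = full_std)
}

#' Fit a histone-modification epigenetic clock
#'
#' The central model of the package: a sparse elastic-net linear
#' predictor of chronological age from per-peak histone-modification
#' signal. Hyperparameters (the L1 mixing fraction alpha and penalty
#' lambda) are chosen by age-stratified leave-one-group-out
#' cross-validation (LOGO-CV): samples are partitioned into age strata,
#' each stratum is held out in turn, feature standardization is
#' re-estimated on the remaining samples only (no leakage), and the
#' (alpha, lambda) pair minimizing the pooled cross-validated RMSE is
#' selected, with ties broken toward the larger penalty (the sparser
#' model). The final model is refit on all samples at the chosen
#' hyperparameters.
#'
#' @param x a `signal_matrix` (typically stage `batch_corrected` or
#'   `log2bg`, restricted to candidate peaks) or a plain matrix with
#'   features in rows and samples in columns.
#' @param age numeric vector of chronological ages in years; taken from
#'   the sample sheet when `x` is a `signal_matrix`.
#' @param groups optional precomputed CV group factor; by default
#'   [make_age_groups] with `n_groups` age strata.
#' @param n_groups number of age strata for LOGO-CV (default 11).
#' @param alpha grid of L1 mixing fractions searched (default 0, 0.1,
#'   ..., 1).
#' @param nlambda number of penalties on each alpha's log-spaced path
#'   (default 100).
#' @param group_mode passed to [make_age_groups].
#' @return An object of class `histone_clock` with components
#'   `features`, `coefficients` (nonzero only), `intercept`, `alpha`,
#'   `lambda`, `standardization` (per-feature training mean/sd for the
#'   retained features), `cv` (group per sample, pooled out-of-fold
#'   predictions, RMSE/MAE/Pearson r, the search grid), `age`,
#'   `fitted.values`, and `provenance`.
#' @examples
#' sim <- simulate_chipseq(n_peaks = 150, n_samples = 40,
#'                         fraction_linear = 0.2, exact = TRUE, seed = 1)
#' z <- log2_background_subtract(sim$signal)
#' fit <- histone_clock(z, n_groups = 5, alpha = c(0.5), nlambda = 30)
#' fit
#' @export
histone_clock <- function(x, age = NULL, groups = NULL, n_groups = 11,
                          alpha = seq(0, 1, by = 0.1), nlambda = 100,
                          group_mode = "width") {
  mat <- signal_values(x)
  if (is.null(age)) {
    if (!inherits(x, "signal_matrix"))
      stop("age is required when x is not a signal_matrix")
    age <- x$samples$age
  }
  if (length(age) != ncol(mat)) stop("one age per sample is required")
  if (nrow(mat) < 1 || ncol(mat) < 3) stop("need >= 1 feature and >= 3 samples")
  if (is.null(rownames(mat)))
    rownames(mat) <- if (inherits(x, "signal_matrix")) peak_ids(x$peaks)
                     else paste0("f", seq_len(nrow(mat)))
  if (is.null(groups)) groups <- make_age_groups(age, n_groups, mode = group_mode)

  cv <- logo_cv_engine(mat, age, groups, alpha, nlambda)
  best <- cv$best
  zfull <- signal_values(cv$full_std$standardized)
  # refit on all samples at the winning hyperparameters (solver scale,
  # consistent with the CV search path)
  cf <- glmnet_coef_at(t(zfull), age, best$alpha, best$lambda)
  nz <- which(cf[-1] != 0)
  final <- list(features = rownames(mat)[nz], coefficients = cf[-1][nz],
                intercept = cf[1])

  keep <- match(final$features, rownames(mat))
  mu <- cv$full_std$mean[keep]
  sd_ <- cv$full_std$sd[keep]
  cv_metrics <- accuracy_metrics(age, best$pred)

  obj <- structure(list(
    features = final$features,
    coefficients = final$coefficients,
    intercept = final$intercept,
    alpha = best$alpha, lambda = best$lambda,
    standardization = list(mean = mu, sd = sd_),
    cv = list(groups = cv$groups, predictions = best$pred,
              rmse = cv_metrics$rmse, mae = cv_metrics$mae,
              r = cv_metrics$r, grid = cv$grid),
    age = age,
    provenance = if (inherits(x, "signal_matrix"))
      list(tissue = unique(x$samples$tissue), mark = unique(x$samples$mark),
           sample_ids = x$samples$sample_id)
    else list(sample_ids = colnames(mat)),
    call = match.call()),
    class = "histone_clock")
  obj$fitted.values <- predict(obj, mat)
  obj
}

#' Predict age from a fitted clock
#'
#' yhat = intercept + sum_f w_f * (x_f - mu_f) / sd_f, using the
#' training-set standardization stored in the model.
#'
#' @param object a `histone_clock`.
#' @param newdata `signal_matrix` or matrix with features in rows,
#'   matched to the model's features by identifier. All model features
#'   must be present.
#' @param ... unused.
#' @return numeric vector of predicted ages (years) per sample.
#' @export
predict.histone_clock <- function(object, newdata, ...) {
  mat <- signal_values(newdata)
  if (is.null(rownames(mat)) && inherits(newdata, "signal_matrix"))
    rownames(mat) <- peak_ids(newdata$peaks)
  if (!length(object$features))
    return(stats::setNames(rep(object$intercept, ncol(mat)), colnames(mat)))
  idx <- match(object$features, rownames(mat))
  if (anyNA(idx))
    stop("model features missing from newdata: ",
         paste(object$features[is.na(idx)], collapse = ", "))
  z <- (mat[idx, , drop = FALSE] - object$standardization$mean) /
    object$standardization$sd
  stats::setNames(object$intercept + as.numeric(crossprod(z, object$coefficients)),
                  colnames(mat))
}

#' Prediction accuracy metrics
#'
#' @param y observed ages; @param y_hat predicted ages.
#' @return list with `rmse`, `mae`, `r` (Pearson; NA if either vector is
#'   constant).
#' @export
accuracy_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  r <- if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) NA_real_
       else stats::cor(y, y_hat)
  list(rmse = sqrt(mean((y - y_hat)^2)), mae = mean(abs(y - y_hat)), r = r)
}

#' @export
print.histone_clock <- function(x, ...) {
  cat("Histone-modification epigenetic clock (elastic net)\n")
  cat(sprintf("  features: %d nonzero of model; alpha = %.2f, lambda = %.4g\n",
              length(x$features), x$alpha, x$lambda))
  if (!is.null(x$cv$rmse))
    cat(sprintf("  LOGO-CV: RMSE %.2f y, MAE %.2f y, Pearson r %.3f\n",
                x$cv$rmse, x$cv$mae, x$cv$r))
  invisible(x)
}

#' @export
summary.histone_clock <- function(object, ...) {
  train <- accuracy_metrics(object$age, object$fitted.values)
  structure(list(n_samples = length(object$age),
                 n_features = length(object$features),
                 alpha = object$alpha, lambda = object$lambda,
                 cv = object$cv[c("rmse", "mae", "r")],
                 train = train,
                 top = utils::head(object$features[
                   order(-abs(object$coefficients))], 10),
                 provenance = object$provenance),
            class = "summary.histone_clock")
}

#' @export
print.summary.histone_clock <- function(x, ...) {
  cat("Histone-modification epigenetic clock\n")
  cat(sprintf("  samples: %d; selected features: %d\n", x$n_samples, x$n_features))
  cat(sprintf("  hyperparameters: alpha = %.2f, lambda = %.4g\n", x$alpha, x$lambda))
  cat(sprintf("  LOGO-CV:  RMSE %.2f y  MAE %.2f y  Pearson r %.3f\n",
              x$cv$rmse, x$cv$mae, x$cv$r))
  cat(sprintf("  training: RMSE %.2f y  MAE %.2f y  Pearson r %.3f\n",
              x$train$rmse, x$train$mae, x$train$r))
  if (length(x$top))
    cat("  largest |coefficient| features:\n   ",
        paste(x$top, collapse = "\n    "), "\n")
  invisible(x)
}

#' @export
coef.histone_clock <- function(object, ...) {
  stats::setNames(c(object$intercept, object$coefficients),
                  c("(Intercept)", object$features))
}

#' @export
residuals.histone_clock <- function(object, ...) {
  object$age - object$fitted.values
}

#' Predicted versus chronological age plot
#'
#' Plots the pooled out-of-fold LOGO-CV predictions (default) or the
#' training fit against chronological age, with the identity line.
#'
#' @param x a `histone_clock`. @param which `"cv"` or `"train"`.
#' @param ... passed to `plot`.
#' @export
plot.histone_clock <- function(x, which = c("cv", "train"), ...) {
  which <- match.arg(which)
  pred <- if (which == "cv") x$cv$predictions else x$fitted.values
  graphics::plot(x$age, pred, xlab = "chronological age (y)",
                 ylab = sprintf("predicted age (%s)", which),
                 main = "Histone clock", ...)
  graphics::abline(0, 1, lty = 2, col = "red")
  invisible(x)
}

#' Age gap and paired scaled-gap statistics
#'
#' The age gap (age acceleration) of a sample is predicted minus
#' chronological age. For paired pre/post-treatment designs the scaled
#' age gap of a pair is (yhat_post - yhat_pre) / yhat_pre (relative
#' mode, the default) or yhat_post - yhat_pre (absolute mode), and the
#' scaled gaps are tested against zero with a one-sample two-sided
#' Student's t test.
#'
#' @param model a `histone_clock`.
#' @param x `signal_matrix` or matrix of the samples to predict.
#' @param meta sample metadata; defaults to the sheet of `x`. For paired
#'   mode it must contain `pair_id` and `condition` with values
#'   `pre_treatment` / `post_treatment`, each pair id appearing exactly
#'   once per condition.
#' @param paired compute the paired scaled-gap test (default TRUE when
#'   `meta` carries pair ids).
#' @param mode `"relative"` or `"absolute"` scaled gap.
#' @return list with `gap` (per sample), and in paired mode
#'   `scaled_gap` (per pair), `mean_scaled_gap`, `t`, `p` (NA with a
#'   flag when the gaps are constant).
#' @export
age_gap <- function(model, x, meta = NULL, paired = NULL, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (is.null(meta) && inherits(x, "signal_matrix")) meta <- x$samples
  pred <- predict(model, x)
  gap <- pred - meta$age
  if (is.null(paired)) paired <- !is.null(meta$pair_id) && !all(is.na(meta$pair_id))
  out <- list(gap = stats::setNames(gap, meta$sample_id), predicted = pred)
  if (!paired) return(out)
  if (is.null(meta$pair_id) || is.null(meta$condition))
    stop("paired mode requires pair_id and condition columns")
  pre <- meta$condition == "pre_treatment"
  post <- meta$condition == "post_treatment"
  pids <- sort(unique(meta$pair_id[pre | post]))
  pre_i <- match(pids, ifelse(pre, meta$pair_id, NA))
  post_i <- match(pids, ifelse(post, meta$pair_id, NA))
  if (anyNA(pre_i) || anyNA(post_i) ||
      sum(pre) != length(pids) || sum(post) != length(pids))
    stop("each pair_id must appear exactly once per condition")
  sg <- if (mode == "relative") (pred[post_i] - pred[pre_i]) / pred[pre_i]
        else pred[post_i] - pred[pre_i]
  out$scaled_gap <- stats::setNames(sg, pids)
  out$mean_scaled_gap <- mean(sg)
  if (length(sg) >= 2 && stats::sd(sg) > 0) {
    tt <- stats::t.test(sg, mu = 0)
    out$t <- unname(tt$statistic); out$p <- tt$p.value; out$degenerate <- FALSE
  } else {
    out$t <- NA_real_; out$p <- NA_real_; out$degenerate <- TRUE
  }
  out
}

#' Serialize a clock model to JSON
#'
#' Features are stored as "chrom:start-end" identifiers with their
#' coefficients, intercept, hyperparameters, and the per-feature
#' standardization arrays; [read_clock] restores the model.
#'
#' @param model a `histone_clock`. @param path output path.
#' @export
write_clock <- function(model, path) {
  payload <- list(features = model$features,
                  coefficients = model$coefficients,
                  intercept = model$intercept,
                  alpha = model$alpha, lambda = model$lambda,
                  standardization = model$standardization,
                  cv = model$cv[c("rmse", "mae", "r")],
                  provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a clock model written by [write_clock]
#' @param path JSON path.
#' @return a `histone_clock` (without CV predictions or training data).
#' @export
read_clock <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = as.character(p$features),
                 coefficients = as.numeric(p$coefficients),
                 intercept = as.numeric(p$intercept),
                 alpha = p$alpha, lambda = p$lambda,
                 standardization = list(mean = as.numeric(p$standardization$mean),
                                        sd = as.numeric(p$standardization$sd)),
                 cv = p$cv, age = NULL, provenance = p$provenance),
            class = "histone_clock")
}
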