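#' Empirical-Bayes batch correction preserving biological covariates
#'
#' Parametric location/scale adjustment in the empirical-Bayes framework:
#' per-feature linear models with batch indicators plus biological
#' covariates (age, sex) are fit; data are standardized by the feature
#' grand mean and pooled variance; per-(batch, feature) additive effects
#' are shrunk toward a per-batch normal prior and variance scale factors
#' toward an inverse-gamma prior, both estimated by method of moments and
#' iterated to convergence; the shrunk effects are removed and the
#' covariate structure and grand mean restored. Age and sex signal present
#' in the design is therefore preserved through the adjustment.
#'
#' @param x `signal_matrix` (typically stage `log2bg`) or plain matrix,
#'   features in rows.
#' @param batch factor or character vector of batch labels per sample
#'   (defaults to the `batch` column of the sample sheet when `x` is a
#'   `signal_matrix`).
#' @param covariates data frame of biological covariates to preserve
#'   (defaults to age and sex from the sample sheet). May be NULL.
#' @param conv convergence tolerance for the EB iteration (max absolute
#'   change in the shrunk parameters).
#' @param max_iter iteration cap.
#' @return list with `corrected` (same container as `x`, stage
#'   `batch_corrected`) and `model` (class `batch_model`: raw and shrunk
#'   additive effects `gamma_hat`/`gamma_star`, variance factors
#'   `delta_hat`/`delta_star`, per-batch prior parameters, feature grand
#'   means and pooled variances).
#' @export
fit_adjust <- function(x, batch = NULL, covariates = NULL,
                       conv = 1e-4, max_iter = 100) {
  mat <- signal_values(x)
  if (inherits(x, "signal_matrix")) {
    if (is.null(batch)) batch <- x$samples$batch
    if (is.null(covariates))
      covariates <- data.frame(age = x$samples$age,
                               sex = x$samples$sex %||% "unknown")
  }
  if (is.null(batch)) stop("batch labels are required")
  n <- ncol(mat)
  if (length(batch) != n) stop("one batch label per sample is required")
  batch <- as.character(batch)

  # batches with fewer than 2 samples cannot support a scale estimate;
  # fold them into one pseudo-batch
  tab <- table(batch)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("merging batch(es) with < 2 samples into pseudo-batch 'small': ",
            paste(small, collapse = ", "))
    batch[batch %in% small] <- "small"
  }
  batch <- factor(batch)
  batches <- levels(batch)
  n_batch <- length(batches)
  if (n_batch < 2) {
    warning("single batch; returning input unchanged")
    out <- if (inherits(x, "signal_matrix"))
      signal_matrix(mat, x$peaks, x$samples, stage = "batch_corrected") else mat
    return(list(corrected = out, model = NULL))
  }

  batch_design <- stats::model.matrix(~ -1 + batch)
  colnames(batch_design) <- batches
  design <- batch_design
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    cov_design <- stats::model.matrix(
      stats::as.formula(paste("~", paste(names(covariates), collapse = "+"))),
      data = covariates)
    cov_design <- cov_design[, -1, drop = FALSE]  # drop intercept; batch columns span it
    design <- cbind(batch_design, cov_design)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("design is rank-deficient (covariates confounded with batch); ",
         "aliased columns: ", paste(aliased, collapse = ", "))
  }

  n_per_batch <- as.integer(table(batch))
  # per-feature regression on batch + covariates
  B_hat <- solve(crossprod(design), t(design) %*% t(mat))  # p x G
  grand_mean <- crossprod(n_per_batch / n, B_hat[seq_len(n_batch), , drop = FALSE])
  resid <- mat - t(design %*% B_hat)
  var_pooled <- rowSums(resid^2) / n  # 1/n denominator, matching the EB framework
  if (any(var_pooled == 0))
    var_pooled[var_pooled == 0] <- .Machine$double.eps
  stand_mean <- matrix(grand_mean, nrow(mat), n, byrow = FALSE)
  if (ncol(design) > n_batch) {
    cov_part <- design[, -(seq_len(n_batch)), drop = FALSE] %*%
      B_hat[-(seq_len(n_batch)), , drop = FALSE]
    stand_mean <- stand_mean + t(cov_part)
  }
  s_data <- (mat - stand_mean) / sqrt(var_pooled)

  idx <- lapply(batches, function(b) which(batch == b))
  gamma_hat <- t(vapply(idx, function(j)
    rowMeans(s_data[, j, drop = FALSE]), numeric(nrow(mat))))
  delta_hat <- t(vapply(idx, function(j)
    apply(s_data[, j, drop = FALSE], 1, stats::var), numeric(nrow(mat))))
  rownames(gamma_hat) <- rownames(delta_hat) <- batches

  # method-of-moments hyperpriors per batch
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  a_prior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(n_batch)) {
    sd_b <- s_data[, idx[[i]], drop = FALSE]
    nb <- length(idx[[i]])
    g_old <- gamma_hat[i, ]; d_old <- delta_hat[i, ]
    for (it in seq_len(max_iter)) {
      g_new <- (t2[i] * nb * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (t2[i] * nb + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (nb / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  adjusted <- s_data
  for (i in seq_len(n_batch)) {
    adjusted[, idx[[i]]] <- (s_data[, idx[[i]], drop = FALSE] -
                               gamma_star[i, ]) / sqrt(delta_star[i, ])
  }
  corrected <- adjusted * sqrt(var_pooled) + stand_mean

  model <- structure(list(
    batches = batches, design = design,
    gamma_hat = gamma_hat, gamma_star = gamma_star,
    delta_hat = delta_hat, delta_star = delta_star,
    prior = list(gamma_bar = gamma_bar, t2 = t2,
                 a_prior = a_prior, b_prior = b_prior),
    grand_mean = as.numeric(grand_mean), var_pooled = var_pooled),
    class = "batch_model")

  out <- if (inherits(x, "signal_matrix"))
    signal_matrix(corrected, x$peaks, x$samples, stage = "batch_corrected")
  else corrected
  list(corrected = out, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d batches x %d features (EB-shrunk location/scale)\n",
              length(x$batches), ncol(x$gamma_star)))
  invisible(x)
}

#' Before/after batch-correction diagnostics
#'
#' Per-feature one-way ANOVA F-statistics across batches, and the share
#' of the leading principal components' variance attributable to batch
#' (R-squared of PC scores on batch labels, weighted by the PCs'
#' variances), computed before and after correction.
#'
#' @param before,after `signal_matrix` or matrix of identical shape.
#' @param batch batch labels per sample.
#' @param n_pcs number of leading PCs to summarize (default 2).
#' @return list with `f_before`, `f_after` (per-feature, NA for constant
#'   features), `mean_f_before`, `mean_f_after`, `pc_batch_r2_before`,
#'   `pc_batch_r2_after`.
#' @export
batch_diagnostics <- function(before, after, batch, n_pcs = 2) {
  b <- signal_values(before); a <- signal_values(after)
  if (!identical(dim(b), dim(a))) stop("before/after shapes differ")
  if (inherits(before, "signal_matrix") && missing(batch))
    batch <- before$samples$batch
  batch <- factor(batch)
  f_b <- batch_f_stats(b, batch)
  f_a <- batch_f_stats(a, batch)
  list(f_before = f_b, f_after = f_a,
       mean_f_before = mean(f_b, na.rm = TRUE),
       mean_f_after = mean(f_a, na.rm = TRUE),
       pc_batch_r2_before = pc_batch_r2(b, batch, n_pcs),
       pc_batch_r2_after = pc_batch_r2(a, batch, n_pcs))
}

batch_f_stats <- function(mat, batch) {
  k <- nlevels(batch); n <- ncol(mat)
  idx <- split(seq_len(n), batch)
  gm <- rowMeans(mat)
  ssb <- Reduce(`+`, lapply(idx, function(j)
    length(j) * (rowMeans(mat[, j, drop = FALSE]) - gm)^2))
  ssw <- Reduce(`+`, lapply(idx, function(j) {
    m <- rowMeans(mat[, j, drop = FALSE])
    rowSums((mat[, j, drop = FALSE] - m)^2)
  }))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  sst <- rowSums((mat - gm)^2)
  f[sst < .Machine$double.eps * n] <- NA_real_  # constant feature
  f
}

pc_batch_r2 <- function(mat, batch, n_pcs) {
  keep <- apply(mat, 1, stats::sd) > 0
  if (sum(keep) < 2) return(NA_real_)
  pc <- stats::prcomp(t(mat[keep, , drop = FALSE]), center = TRUE)
  k <- min(n_pcs, ncol(pc$x))
  r2 <- vapply(seq_len(k), function(i)
    summary(stats::lm(pc$x[, i] ~ batch))$r.squared, numeric(1))
  w <- pc$sdev[seq_len(k)]^2
  sum(r2 * w) / sum(w)
}
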