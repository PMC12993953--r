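#' Per-peak Spearman age-association screening
#'
#' Computes, for every peak, the Spearman rank correlation between its
#' signal and sample age (mid-ranks for ties), a two-sided p-value from
#' the t-approximation on n - 2 degrees of freedom, and the
#' Benjamini-Hochberg adjusted p-value. Constant features get rho = NA
#' and can never become candidates.
#'
#' @param x `signal_matrix` or matrix, features in rows.
#' @param ages numeric vector of ages per sample (defaults to the sample
#'   sheet when `x` is a `signal_matrix`).
#' @param exact if TRUE (only allowed for n <= 8), p-values are computed
#'   by exhaustive permutation of the age ranks instead of the
#'   t-approximation.
#' @return An `age_association` data frame: peak, rho, p, p_adj,
#'   direction, is_candidate (direction/is_candidate filled by
#'   [candidate_filter]; initialized to "none"/FALSE here).
#' @export
spearman_screen <- function(x, ages = NULL, exact = FALSE) {
  mat <- signal_values(x)
  if (is.null(ages) && inherits(x, "signal_matrix")) ages <- x$samples$age
  n <- ncol(mat)
  if (n < 4) stop("at least 4 samples are required")
  if (length(ages) != n) stop("one age per sample is required")
  if (length(unique(ages)) < 2) stop("ages must not all be equal")

  ry <- rank(ages)
  rx <- t(apply(mat, 1, rank))
  ry_c <- ry - mean(ry)
  rx_c <- rx - rowMeans(rx)
  denom <- sqrt(rowSums(rx_c^2) * sum(ry_c^2))
  rho <- as.numeric(rx_c %*% ry_c) / denom
  rho[!is.finite(rho)] <- NA_real_
  rho <- pmin(1, pmax(-1, rho))

  if (exact) {
    if (n > 8) stop("exact permutation mode is limited to n <= 8")
    perms <- permutations_of(seq_len(n))
    p <- vapply(seq_len(nrow(mat)), function(g) {
      if (is.na(rho[g])) return(NA_real_)
      xr <- rx_c[g, ]
      null_rho <- vapply(perms, function(pm)
        sum(xr * ry_c[pm]) / denom[g], numeric(1))
      mean(abs(null_rho) >= abs(rho[g]) - 1e-12)
    }, numeric(1))
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- pmin(p, 1)
    p[abs(rho) == 1] <- 0  # degenerate t
  }
  p_adj <- bh_adjust(ifelse(is.na(p), 1, p))
  p_adj[is.na(p)] <- NA_real_
  ids <- if (inherits(x, "signal_matrix")) peak_ids(x$peaks)
         else rownames(mat) %||% as.character(seq_len(nrow(mat)))
  structure(data.frame(peak = ids, rho = rho, p = p, p_adj = p_adj,
                       direction = "none", is_candidate = FALSE,
                       stringsAsFactors = FALSE),
            class = c("age_association", "data.frame"))
}

permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order, each >= its raw p, capped
#'   at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Joint effect-size and p-value candidate filter
#'
#' Flags peaks with |rho| >= r_min and nominal p <= p_max (both
#' inclusive) as age-associated candidates and assigns them a direction
#' by the sign of rho. Because genome-wide FDR control at conventional
#' thresholds frequently leaves no survivors at moderate sample sizes,
#' candidate nomination uses the joint nominal filter; the BH-adjusted
#' p-values remain in the table for reporting.
#'
#' @param table an `age_association` table from [spearman_screen].
#' @param r_min minimum absolute Spearman rho (default 0.5).
#' @param p_max maximum nominal p (default 0.05).
#' @return the table with `is_candidate` and `direction` set.
#' @export
candidate_filter <- function(table, r_min = 0.5, p_max = 0.05) {
  stopifnot(is.data.frame(table), all(c("rho", "p") %in% names(table)))
  cand <- !is.na(table$rho) & !is.na(table$p) &
    abs(table$rho) >= r_min & table$p <= p_max
  table$is_candidate <- cand
  table$direction <- ifelse(cand & table$rho > 0, "positive",
                     ifelse(cand & table$rho < 0, "negative", "none"))
  table
}

#' Correlation of the first principal component with age
#'
#' PCA on the feature-centered matrix over samples; returns the PC1
#' score per sample and its Pearson correlation with age. The sign of
#' PC1 is fixed so that the loading with the largest absolute value is
#' positive, making the reported signed r deterministic.
#'
#' @param x `signal_matrix` or matrix, features in rows.
#' @param ages numeric ages per sample.
#' @return list with `scores` (PC1 per sample), `r`, `p`,
#'   `var_explained` (PC1 variance share).
#' @export
pc1_age_correlation <- function(x, ages = NULL) {
  mat <- signal_values(x)
  if (is.null(ages) && inherits(x, "signal_matrix")) ages <- x$samples$age
  if (ncol(mat) < 3) stop("at least 3 samples are required")
  keep <- apply(mat, 1, stats::sd) > 0
  pc <- stats::prcomp(t(mat[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  load1 <- pc$rotation[, 1]
  s <- sign(load1[which.max(abs(load1))])
  scores <- pc$x[, 1] * s
  ct <- stats::cor.test(scores, ages, method = "pearson")
  list(scores = unname(scores), r = unname(ct$estimate), p = ct$p.value,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Fisher's exact enrichment test for annotation overlap
#'
#' Two-sided exact test on the 2x2 table of candidate vs background
#' peaks overlapping vs not overlapping an annotation; the two-sided
#' p-value sums hypergeometric probabilities of all tables (with the same
#' margins) no more probable than the observed one.
#'
#' @param candidates_in,candidates_out counts of candidate peaks
#'   overlapping / not overlapping the annotation.
#' @param background_in,background_out the same for background peaks.
#' @return list with `odds_ratio` (sample odds ratio ad/bc, NA when a
#'   denominator is zero) and `p`.
#' @export
fisher_enrichment <- function(candidates_in, candidates_out,
                              background_in, background_out) {
  counts <- c(candidates_in, candidates_out, background_in, background_out)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all table margins must be positive")
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (candidates_out * background_in == 0) NA_real_
        else (candidates_in * background_out) / (candidates_out * background_in)
  list(odds_ratio = or, p = p)
}

#' Write an age-association table as TSV
#'
#' @param table an `age_association` table.
#' @param peaks optional [peak_set] aligned to the table rows; when given,
#'   chrom/start/end columns are prepended.
#' @param path output path.
#' @export
write_association_table <- function(table, path, peaks = NULL) {
  out <- as.data.frame(table)
  if (!is.null(peaks))
    out <- cbind(peaks[, c("chrom", "start", "end")], out)
  utils::write.table(format(out, digits = 10, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
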