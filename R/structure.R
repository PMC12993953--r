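#' Stitch enhancer peaks into domains
#'
#' Peaks on the same chromosome separated by at most `stitch_gap` bp are
#' joined transitively into a single enhancer domain spanning the
#' minimum start to the maximum end of its constituents; the domain's
#' total signal is the sum of its constituents' scores. The default gap
#' of 12,500 bp is the widely used stitching convention for
#' super-enhancer analysis.
#'
#' @param peaks a [peak_set] with per-peak `score` signal.
#' @param stitch_gap maximum gap (bp) joined across (default 12500).
#' @return data frame of class `enhancer_domains`: chrom, start, end,
#'   n_constituents, total_signal, rank (1 = lowest signal), is_super
#'   (initialized FALSE; see [classify_super]).
#' @export
stitch_enhancers <- function(peaks, stitch_gap = 12500) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!nrow(peaks))
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), n_constituents = integer(),
                                total_signal = numeric(), rank = integer(),
                                is_super = logical()),
                     class = c("enhancer_domains", "data.frame")))
  if (anyNA(peaks$score)) stop("per-peak signal (score) is required")
  gr <- as_granges(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_gap + 1,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  total <- vapply(revmap, function(i) sum(peaks$score[i]), numeric(1))
  ncon <- lengths(revmap)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                   start = GenomicRanges::start(red) - 1,
                   end = GenomicRanges::end(red),
                   n_constituents = as.integer(ncon),
                   total_signal = total,
                   rank = NA_integer_, is_super = FALSE,
                   stringsAsFactors = FALSE)
  df$rank <- rank(df$total_signal, ties.method = "first")
  structure(df, class = c("enhancer_domains", "data.frame"))
}

#' Classify super-enhancers by the rank-signal elbow
#'
#' Domains are ordered by total signal; rank and signal are scaled to
#' \[0, 1\] and the cutoff is placed where the discrete slope of the
#' scaled curve reaches 1 (the elbow where signal starts rising faster
#' than rank). Domains with signal above the cutoff are super-enhancers.
#' When the scaled curve is exactly linear every slope ties at 1; the
#' tie is resolved to the highest-ranked point, so exactly the top
#' domain is classified super.
#'
#' @param domains an `enhancer_domains` table from [stitch_enhancers].
#' @return the table with `is_super` set, plus attributes
#'   `signal_cutoff` and `cutoff_rank`.
#' @export
classify_super <- function(domains) {
  n <- nrow(domains)
  if (n < 3) {
    if (n > 0) warning("fewer than 3 domains; all classified typical")
    domains$is_super <- rep(FALSE, n)
    return(domains)
  }
  ord <- order(domains$total_signal)
  sig <- domains$total_signal[ord]
  xs <- (seq_len(n) - 1) / (n - 1)
  rng <- diff(range(sig))
  if (rng == 0) {
    warning("all domains have identical signal; all classified typical")
    domains$is_super <- FALSE
    return(domains)
  }
  ys <- (sig - min(sig)) / rng
  slopes <- diff(ys) / diff(xs)
  cand <- which(slopes >= 1 - 1e-12)
  if (!length(cand)) {
    cut_idx <- n  # no elbow; only the top point can qualify, none above it
  } else if (max(slopes) - min(slopes) < 1e-9) {
    cut_idx <- n - 1  # perfectly linear curve: tie to the highest-rank point
  } else {
    cut_idx <- cand[1]
  }
  cutoff <- sig[cut_idx]
  domains$is_super <- domains$total_signal > cutoff
  attr(domains, "signal_cutoff") <- cutoff
  attr(domains, "cutoff_rank") <- cut_idx
  domains
}

#' Per-age-group enhancer fragmentation statistics
#'
#' For each age group's classified domain set, counts super and typical
#' domains and their mean lengths, then computes the Spearman trend of
#' each metric against the group's representative (median) age.
#' Age-associated fragmentation appears as a positive count trend
#' together with a negative mean-length trend for super-enhancers.
#' Metrics constant across groups are reported with a trend of 0.
#'
#' @param domain_sets named list of classified `enhancer_domains`, one
#'   per age group.
#' @param group_ages numeric representative age per group (same order).
#' @return list with `table` (per-group n_super, mean_super_length,
#'   n_typical, mean_typical_length) and `trends` (Spearman rho of each
#'   metric vs group age).
#' @export
fragmentation_stats <- function(domain_sets, group_ages) {
  if (length(domain_sets) < 2) stop("at least 2 age groups are required")
  if (length(group_ages) != length(domain_sets))
    stop("one representative age per group is required")
  stats_one <- function(d) {
    su <- d[d$is_super, , drop = FALSE]
    ty <- d[!d$is_super, , drop = FALSE]
    c(n_super = nrow(su),
      mean_super_length = if (nrow(su)) mean(su$end - su$start) else NA_real_,
      n_typical = nrow(ty),
      mean_typical_length = if (nrow(ty)) mean(ty$end - ty$start) else NA_real_)
  }
  tab <- as.data.frame(t(vapply(domain_sets, stats_one, numeric(4))))
  tab <- cbind(group = names(domain_sets) %||%
                 as.character(seq_along(domain_sets)),
               age = group_ages, tab)
  trend <- function(v) {
    ok <- is.finite(v)
    if (sum(ok) < 2 || stats::sd(v[ok]) == 0 || stats::sd(group_ages[ok]) == 0)
      return(0)
    stats::cor(group_ages[ok], v[ok], method = "spearman")
  }
  trends <- c(n_super = trend(tab$n_super),
              mean_super_length = trend(tab$mean_super_length),
              n_typical = trend(tab$n_typical),
              mean_typical_length = trend(tab$mean_typical_length))
  list(table = tab, trends = trends)
}

#' LOESS age trajectory with inflection detection
#'
#' Fits a local linear (degree 1, tricube kernel) LOESS of a signal
#' summary against age, evaluates it on a dense age grid, and detects
#' inflection points as grid ages where the second finite difference of
#' the fitted curve changes sign with magnitude above a noise floor
#' (a fraction of the maximum absolute curvature). Curvature numerically
#' indistinguishable from zero (relative to the fitted range) is treated
#' as zero, so exactly linear or constant signals yield no inflections.
#'
#' @param ages sample ages (>= 10 samples).
#' @param signal per-sample signal summary (e.g., mean z-scored signal
#'   of a candidate peak set).
#' @param span LOESS smoothing fraction in (0, 1\] (default 0.5).
#' @param grid_step grid spacing in years (default 1).
#' @param noise_floor_frac fraction of max |second difference| below
#'   which curvature is ignored (default 0.1).
#' @return `trajectory_fit`: list with `age_grid`, `fitted`, `span`,
#'   `inflection_ages`.
#' @export
loess_trajectory <- function(ages, signal, span = 0.5, grid_step = 1,
                             noise_floor_frac = 0.1) {
  if (length(ages) < 10) stop("at least 10 samples are required")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (floor(span * length(ages)) < 2)
    stop("span window contains fewer than 2 points")
  fit <- stats::loess(signal ~ ages, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(ages), max(ages), by = grid_step)
  fitted <- unname(stats::predict(fit, data.frame(ages = grid)))
  infl <- detect_inflections(grid, fitted, grid_step, noise_floor_frac)
  structure(list(age_grid = grid, fitted = fitted, span = span,
                 inflection_ages = infl),
            class = "trajectory_fit")
}

detect_inflections <- function(grid, fitted, step, noise_floor_frac) {
  m <- length(fitted)
  if (m < 4) return(numeric(0))
  s <- diff(fitted, differences = 2) / step^2  # curvature at grid[2..m-1]
  # numerical-zero threshold scaled to both the fitted range and magnitude,
  # so constant/linear fits register no curvature
  scale_ <- max(diff(range(fitted)), 1e-6 * max(abs(fitted), 1))
  abs_tol <- 1e-7 * scale_ / step^2
  s[abs(s) < abs_tol] <- 0
  if (all(s == 0)) return(numeric(0))
  floor_ <- noise_floor_frac * max(abs(s))
  keep <- which(abs(s) >= pmax(floor_, abs_tol))
  if (length(keep) < 2) return(numeric(0))
  ga <- grid[keep + 1]
  sg <- sign(s[keep])
  flips <- which(diff(sg) != 0)
  vapply(flips, function(i) (ga[i] + ga[i + 1]) / 2, numeric(1))
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("LOESS trajectory (span %.2f) on ages %.1f-%.1f\n",
              x$span, min(x$age_grid), max(x$age_grid)))
  if (length(x$inflection_ages))
    cat("  inflection ages:", paste(round(x$inflection_ages, 1),
                                    collapse = ", "), "\n")
  else cat("  no inflections detected\n")
  invisible(x)
}

#' Write enhancer domains as extended BED
#'
#' BED6-style columns plus n_constituents, total_signal, is_super.
#' @param domains `enhancer_domains`. @param path output path.
#' @export
write_domains <- function(domains, path) {
  df <- data.frame(chrom = domains$chrom,
                   start = format(domains$start, scientific = FALSE, trim = TRUE),
                   end = format(domains$end, scientific = FALSE, trim = TRUE),
                   name = sprintf("domain_%d", seq_len(nrow(domains))),
                   score = format(domains$total_signal, trim = TRUE),
                   strand = ".",
                   n_constituents = domains$n_constituents,
                   total_signal = format(domains$total_signal, trim = TRUE),
                   is_super = domains$is_super)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
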