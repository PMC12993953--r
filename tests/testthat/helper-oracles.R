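# Brute-force oracles, deliberately independent of the package internals:
# everything here works by explicit enumeration or position-wise coverage
# arrays on small instances.

# position-wise boolean coverage merge: returns sorted non-overlapping
# intervals covering exactly the positions covered by the input, with
# gaps <= max_gap bridged
oracle_merge <- function(df, max_gap = 0) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    hi <- max(d$end)
    cov <- logical(hi)
    for (i in seq_len(nrow(d)))
      cov[(d$start[i] + 1):d$end[i]] <- TRUE  # 1-based positions
    if (max_gap > 0) {
      r <- rle(cov)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$lengths)) {
        inside <- k > 1 && k < length(r$lengths)
        if (!r$values[k] && inside && r$lengths[k] <= max_gap)
          cov[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
      }
    } else {
      # gap 0 means abutting runs are already contiguous in the array
    }
    r <- rle(cov)
    pos_end <- cumsum(r$lengths)
    pos_start <- pos_end - r$lengths + 1
    for (k in which(r$values))
      out[[length(out) + 1]] <- data.frame(chrom = ch,
                                           start = pos_start[k] - 1,
                                           end = pos_end[k])
  }
  if (!length(out)) return(data.frame(chrom = character(), start = numeric(),
                                      end = numeric()))
  do.call(rbind, out)
}

# bp-level coverage-count consensus oracle
oracle_consensus <- function(groups, min_replicates) {
  per_group <- lapply(groups, function(reps) {
    hi <- max(vapply(reps, function(p) max(p$end), numeric(1)))
    chroms <- sort(unique(unlist(lapply(reps, function(p) p$chrom))))
    res <- list()
    for (ch in chroms) {
      count <- integer(hi)
      for (p in reps) {
        d <- p[p$chrom == ch, , drop = FALSE]
        covered <- logical(hi)
        for (i in seq_len(nrow(d)))
          covered[(d$start[i] + 1):d$end[i]] <- TRUE
        count <- count + covered
      }
      keep <- count >= min_replicates
      if (!any(keep)) next
      r <- rle(keep)
      pe <- cumsum(r$lengths); ps <- pe - r$lengths + 1
      for (k in which(r$values))
        res[[length(res) + 1]] <- data.frame(chrom = ch, start = ps[k] - 1,
                                             end = pe[k])
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  merged <- do.call(rbind, per_group[!vapply(per_group, is.null, logical(1))])
  oracle_merge(merged, max_gap = 0)
}

# all-pairs interval intersection oracle
oracle_overlap_flags <- function(query, annotation) {
  vapply(seq_len(nrow(query)), function(i) {
    any(annotation$chrom == query$chrom[i] &
          annotation$start < query$end[i] &
          annotation$end > query$start[i])
  }, logical(1))
}

# hand-rolled BH step-up: adj_(i) = min_{k>=i}(p_(k) * m / k)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# full hypergeometric enumeration of the two-sided Fisher p-value
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, c1, n - c1, r1),
                  numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all assignments
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y); nx <- length(x)
  combs <- utils::combn(length(pooled), nx)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  u_obs <- u_of(seq_len(nx))
  u_all <- apply(combs, 2, u_of)
  mu <- nx * (length(pooled) - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# transitive-closure stitching oracle on the pairwise gap relation
oracle_stitch <- function(df, gap) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (df$chrom[i] == df$chrom[j]) {
      g <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
      if (g <= gap) adj[i, j] <- TRUE
    }
  }
  # transitive closure
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1
    comp[which(adj[i, ])] <- cid
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix)
    data.frame(chrom = df$chrom[ix[1]], start = min(df$start[ix]),
               end = max(df$end[ix]), n = length(ix),
               total = sum(df$score[ix]))))
  out[order(out$chrom, out$start), ]
}

# closed-form ridge: w = (X'X + n*lambda*I)^{-1} X'y on centered data
oracle_ridge <- function(x, y, lambda) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  n <- nrow(x)
  w <- solve(crossprod(xc) + n * lambda * diag(ncol(x)), crossprod(xc, yc))
  list(w = as.numeric(w),
       intercept = mean(y) - sum(colMeans(x) * w))
}

random_peak_df <- function(n, chroms = c("chrA", "chrB"), max_pos = 2000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(150, n, replace = TRUE),
             score = stats::runif(n, 1, 10))
}

as_ps <- function(df) peak_set(df$chrom, df$start, df$end,
                               score = if (!is.null(df$score)) df$score else NA)

# latent-scale view of an exact-mode density matrix (log2 of the densities,
# no background centering) for model-level tests
log2_transform_for_test <- function(sm) log2(sm$values)
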