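#' Simulate age-structured histone-modification ChIP-seq data
#'
#' Generates a toy two-chromosome peak landscape and a peaks-by-samples
#' count matrix with the statistical structure the rest of the package
#' assumes: a latent log2 density per peak composed of a baseline, an
#' age effect (linear for a fraction of peaks, half increasing and half
#' decreasing; a logistic step at a breakpoint age for another
#' fraction), additive and multiplicative batch effects, an optional
#' additive sex effect, and Gaussian noise. Read counts are drawn
#' Poisson with expectation proportional to each peak's linear-scale
#' density times its length, so the reads-in-peaks normalization of
#' [quantify_density] recovers the latent densities up to sampling
#' noise. Per-age-group replicate peak calls are emitted by jittering
#' and thresholding the true peaks, for consensus-construction tests.
#' The same seed reproduces every output bit-identically.
#'
#' @param n_peaks number of peaks (default 2000).
#' @param n_samples number of samples (default 60).
#' @param age_range ages are drawn uniformly over this range (default
#'   5-75 years) unless `ages` is supplied.
#' @param ages optional explicit age vector (histogram-matching mode).
#' @param fraction_linear fraction of peaks with a linear age effect
#'   (default 0.1).
#' @param fraction_nonlinear fraction with a logistic breakpoint effect
#'   (default 0.05); fractions must sum to <= 1.
#' @param breakpoint_ages breakpoint ages sampled per nonlinear peak
#'   (default c(40, 60)).
#' @param effect_size linear slope over the full age range / logistic
#'   amplitude, in log2 units. The default 1.7 with `noise_sd = 0.5`
#'   places the planted Spearman correlation near 0.7 for linear peaks
#'   (r = beta*sd(u)/sqrt(beta^2 var(u) + sigma^2) with u the scaled age).
#' @param n_batches number of batches, assigned round-robin (default 2).
#' @param batch_labels optional explicit per-sample batch labels,
#'   overriding the round-robin assignment (e.g., to emulate batches
#'   correlated with age cohorts).
#' @param batch_shift additive log2 shift of batches beyond the first
#'   (default 0; per-feature shifts drawn N(batch_shift, 0.1) when
#'   nonzero).
#' @param batch_scale multiplicative noise-SD factor for batches beyond
#'   the first (default 1).
#' @param noise_sd Gaussian noise SD in log2 units (default 0.5).
#' @param sex_effect optional additive log2 effect of sex on 5% of
#'   peaks (default 0).
#' @param replicates_per_group replicate peak calls per age group
#'   (default 3).
#' @param n_age_groups age groups for replicate structure (default 5).
#' @param sequencing_depth expected reads-in-peaks per sample
#'   (default 2e6).
#' @param peak_jitter replicate boundary jitter SD in bp (default 50).
#' @param detect_prob probability a replicate call contains a given peak
#'   (default 0.97).
#' @param exact if TRUE, skip Poisson sampling and return the latent
#'   densities directly (stage `density`) — the infinite-depth limit.
#' @param seed RNG seed.
#' @return list with `peaks` ([peak_set]), `signal` (`signal_matrix`,
#'   stage `raw_counts`, or `density` in exact mode), `samples` (sample
#'   sheet), `replicate_calls` (per age group, a list of [peak_set]
#'   replicate calls), and `truth` (per-peak labels/slopes/breakpoints,
#'   per-sample batch effects, the latent density matrix).
#' @export
simulate_chipseq <- function(n_peaks = 2000, n_samples = 60,
                             age_range = c(5, 75), ages = NULL,
                             fraction_linear = 0.1, fraction_nonlinear = 0.05,
                             breakpoint_ages = c(40, 60), effect_size = 1.7,
                             n_batches = 2, batch_shift = 0, batch_scale = 1,
                             noise_sd = 0.5, sex_effect = 0,
                             replicates_per_group = 3, n_age_groups = 5,
                             sequencing_depth = 2e6, peak_jitter = 50,
                             detect_prob = 0.97, exact = FALSE,
                             batch_labels = NULL, seed = 1) {
  if (fraction_linear < 0 || fraction_nonlinear < 0 ||
      fraction_linear + fraction_nonlinear > 1)
    stop("effect fractions must be in [0,1] and sum to <= 1")
  if (sequencing_depth <= 0) stop("sequencing_depth must be > 0")
  set.seed(seed)

  # non-overlapping peaks on a toy 2-chromosome genome
  widths <- round(stats::runif(n_peaks, 500, 2000))
  pitch <- 5000  # guaranteed inter-peak spacing; keeps jittered calls disjoint
  chrom <- rep(c("chrS1", "chrS2"), length.out = n_peaks)
  starts <- integer(n_peaks)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    starts[i] <- (seq_along(i) - 1) * (max(widths) + 2 * pitch) +
      round(stats::runif(length(i), 0, pitch))
  }
  peaks <- peak_set(chrom, starts, starts + widths)
  ids <- peak_ids(peaks)
  # peak_set sorts rows; recover the latent ordering by id
  perm <- match(ids, sprintf("%s:%d-%d", chrom, starts, starts + widths))

  if (is.null(ages)) ages <- stats::runif(n_samples, age_range[1], age_range[2])
  n_samples <- length(ages)
  # balanced but shuffled sex so it is not aliased with the batch blocks
  sex <- sample(rep(c("male", "female"), length.out = n_samples))
  batch <- if (is.null(batch_labels))
    paste0("batch", rep(seq_len(n_batches), length.out = n_samples))
  else as.character(batch_labels)
  if (length(batch) != n_samples) stop("one batch label per sample is required")
  grp_breaks <- seq(age_range[1], age_range[2], length.out = n_age_groups + 1)
  grp <- findInterval(ages, grp_breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_samples)),
    age = ages, sex = sex, batch = batch, tissue = "blood",
    mark = "H3K27ac", replicate_group = paste0("age_g", grp),
    condition = "healthy", stringsAsFactors = FALSE)

  truth <- build_latent(n_peaks, ages, age_range, fraction_linear,
                        fraction_nonlinear, breakpoint_ages, effect_size,
                        sex, sex_effect, batch, batch_shift, batch_scale,
                        noise_sd)
  latent <- truth$latent[perm, , drop = FALSE]  # align to sorted peaks
  density <- 2^latent
  rownames(density) <- ids

  if (exact) {
    sm <- signal_matrix(density, peaks, samples, stage = "density")
  } else {
    len_kb <- (peaks$end - peaks$start) / 1000
    wgt <- density * len_kb
    p <- sweep(wgt, 2, colSums(wgt), `/`)
    counts <- matrix(stats::rpois(length(p), sequencing_depth * p),
                     nrow(p), ncol(p))
    sm <- signal_matrix(counts, peaks, samples, stage = "raw_counts")
  }

  # per-age-group replicate peak calls with boundary jitter and dropout
  rep_calls <- lapply(seq_len(n_age_groups), function(g) {
    lapply(seq_len(replicates_per_group), function(r) {
      keep <- stats::runif(n_peaks) < detect_prob
      js <- pmax(0, round(peaks$start[keep] +
                            stats::rnorm(sum(keep), 0, peak_jitter)))
      je <- round(peaks$end[keep] + stats::rnorm(sum(keep), 0, peak_jitter))
      je <- pmax(je, js + 50)
      peak_set(peaks$chrom[keep], js, je,
               provenance = sprintf("age_g%d_rep%d", g, r))
    })
  })
  names(rep_calls) <- paste0("age_g", seq_len(n_age_groups))

  truth$peak_table <- data.frame(
    peak = ids, label = truth$label[perm], beta = truth$beta[perm],
    breakpoint = truth$breakpoint[perm], stringsAsFactors = FALSE)
  truth$latent <- latent
  truth$label <- truth$beta <- truth$breakpoint <- NULL

  list(peaks = peaks, signal = sm, samples = samples,
       replicate_calls = rep_calls, truth = truth)
}

# latent log2 density model shared by the plain and paired generators
build_latent <- function(n_peaks, ages, age_range, fraction_linear,
                         fraction_nonlinear, breakpoint_ages, effect_size,
                         sex, sex_effect, batch, batch_shift, batch_scale,
                         noise_sd) {
  n_samples <- length(ages)
  n_lin <- round(fraction_linear * n_peaks)
  n_nl <- round(fraction_nonlinear * n_peaks)
  label <- rep("null", n_peaks)
  lin_idx <- seq_len(n_lin)
  nl_idx <- n_lin + seq_len(n_nl)
  beta <- rep(0, n_peaks)
  if (n_lin) {
    sgn <- rep(c(1, -1), length.out = n_lin)
    beta[lin_idx] <- sgn * effect_size
    label[lin_idx] <- ifelse(sgn > 0, "linear+", "linear-")
  }
  breakpoint <- rep(NA_real_, n_peaks)
  amp <- rep(0, n_peaks)
  if (n_nl) {
    breakpoint[nl_idx] <- sample(breakpoint_ages, n_nl, replace = TRUE)
    amp[nl_idx] <- rep(c(1, -1), length.out = n_nl) * effect_size
    label[nl_idx] <- "nonlinear"
  }
  baseline <- stats::rnorm(n_peaks, 3, 1)
  u <- (ages - mean(age_range)) / diff(age_range)
  latent <- matrix(baseline, n_peaks, n_samples) + outer(beta, u)
  if (n_nl) {
    step <- t(vapply(nl_idx, function(g)
      stats::plogis((ages - breakpoint[g]) / 3), numeric(n_samples)))
    latent[nl_idx, ] <- latent[nl_idx, ] + amp[nl_idx] * step
  }
  if (sex_effect != 0) {
    sex_peaks <- sample(n_peaks, max(1, round(0.05 * n_peaks)))
    latent[sex_peaks, ] <- latent[sex_peaks, ] +
      sex_effect * matrix(rep(as.numeric(sex == "male"), each = length(sex_peaks)),
                          length(sex_peaks), n_samples)
  }
  batches <- unique(batch)
  gamma <- matrix(0, n_peaks, length(batches),
                  dimnames = list(NULL, batches))
  scale_fac <- stats::setNames(rep(1, length(batches)), batches)
  for (bi in seq_along(batches)) if (bi > 1) {
    if (batch_shift != 0)
      gamma[, bi] <- stats::rnorm(n_peaks, batch_shift, 0.1)
    scale_fac[bi] <- batch_scale
  }
  eps <- matrix(stats::rnorm(n_peaks * n_samples, 0, noise_sd),
                n_peaks, n_samples)
  eps <- sweep(eps, 2, scale_fac[batch], `*`)
  latent <- latent + gamma[, batch, drop = FALSE] + eps
  list(latent = latent, label = label, beta = beta, breakpoint = breakpoint,
       batch_gamma = gamma, batch_scale = scale_fac)
}

#' Simulate paired pre/post-treatment samples with planted rejuvenation
#'
#' Each subject is measured twice from the same latent peak model: the
#' pre-treatment sample at its chronological age and the post-treatment
#' sample with an effective age of `rejuvenation_factor` times the
#' chronological age (clamped to the lower end of the age range, with a
#' warning, when the factor is 0), with independent noise draws. A clock
#' trained on healthy samples should therefore predict lower
#' post-treatment ages and a negative mean scaled age gap.
#'
#' @param n_pairs number of subject pairs.
#' @param rejuvenation_factor effective-age multiplier in \[0, 1\].
#' @param n_peaks,age_range,fraction_linear,effect_size,noise_sd,seed as
#'   in [simulate_chipseq].
#' @param exact return latent densities (default TRUE).
#' @return list with `signal` (`signal_matrix`, pre and post columns),
#'   `samples` (sheet with pair_id and condition), `peaks`.
#' @export
simulate_paired_treatment <- function(n_pairs = 10, rejuvenation_factor = 0.8,
                                      n_peaks = 500, age_range = c(20, 70),
                                      fraction_linear = 0.2, effect_size = 1.7,
                                      noise_sd = 0.3, exact = TRUE, seed = 1) {
  if (rejuvenation_factor < 0 || rejuvenation_factor > 1)
    stop("rejuvenation_factor must lie in [0, 1]")
  set.seed(seed)
  true_age <- stats::runif(n_pairs, age_range[1], age_range[2])
  eff_age <- rejuvenation_factor * true_age
  if (any(eff_age < age_range[1])) {
    if (rejuvenation_factor == 0)
      warning("rejuvenation_factor 0: effective ages clamped to the minimum age")
    eff_age <- pmax(eff_age, age_range[1])
  }
  all_ages <- c(true_age, eff_age)
  sim <- simulate_chipseq(n_peaks = n_peaks, ages = all_ages,
                          age_range = age_range,
                          fraction_linear = fraction_linear,
                          fraction_nonlinear = 0, effect_size = effect_size,
                          n_batches = 1, noise_sd = noise_sd,
                          exact = exact, seed = seed + 1)
  samples <- sim$samples
  samples$age <- rep(true_age, 2)  # chronological age for both members
  samples$pair_id <- rep(sprintf("pair%02d", seq_len(n_pairs)), 2)
  samples$condition <- rep(c("pre_treatment", "post_treatment"),
                           each = n_pairs)
  sim$signal$samples <- samples
  list(signal = sim$signal, samples = samples, peaks = sim$peaks)
}

#' Simulate per-age-group enhancer landscapes with optional fragmentation
#'
#' Builds clustered enhancer constituents (which stitch into
#' super-enhancer-scale domains) plus scattered singleton enhancers, one
#' peak set per age group. With a positive `fragmentation_rate`,
#' interior constituents lose signal with age in proportion to their
#' centrality within the cluster; once they fall below the detection
#' threshold the cluster splits at stitching time into more, shorter
#' domains — the planted fragmentation signature. With rate 0 the
#' landscape is age-stationary up to signal noise.
#'
#' @param group_ages representative age per group (default 5 groups,
#'   25-65 y).
#' @param n_clusters enhancer clusters per landscape (default 30).
#' @param constituents_per_cluster peaks per cluster (default 8).
#' @param pitch spacing between constituent starts in bp (default 8000;
#'   with 1000 bp constituents the intra-cluster gap of 7000 bp stitches
#'   at the default 12.5 kb, while a dropped constituent opens a 15 kb
#'   gap that splits the domain).
#' @param constituent_width peak width in bp (default 1000).
#' @param base_signal constituent signal at the youngest age (default 10).
#' @param n_singletons scattered typical enhancers (default 200).
#' @param singleton_signal their signal (default 1).
#' @param fragmentation_rate per-year fractional signal-loss rate of
#'   fully central constituents (default 0.06); each cluster's rate is
#'   jittered by a uniform 0.5-1.5 multiplier so clusters split at
#'   staggered ages rather than in one step.
#' @param detection_threshold peaks below this signal are absent from
#'   the group's call set (default 3).
#' @param signal_noise_sd multiplicative log-normal signal noise
#'   (default 0.05).
#' @param seed RNG seed.
#' @return named list (one element per group) of [peak_set] objects with
#'   per-peak signal scores, plus attribute `group_ages`.
#' @export
simulate_enhancer_landscape <- function(group_ages = seq(25, 65, length.out = 5),
                                        n_clusters = 30,
                                        constituents_per_cluster = 8,
                                        pitch = 8000, constituent_width = 1000,
                                        base_signal = 10, n_singletons = 200,
                                        singleton_signal = 1,
                                        fragmentation_rate = 0.06,
                                        detection_threshold = 3,
                                        signal_noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  k <- constituents_per_cluster
  cluster_span <- k * pitch + 50000
  cl_start <- (seq_len(n_clusters) - 1) * cluster_span
  centrality <- 1 - abs(seq_len(k) - (k + 1) / 2) / (k / 2)  # 1 at center, ~0 at edges
  cluster_rate <- fragmentation_rate * stats::runif(n_clusters, 0.5, 1.5)
  sing_start <- max(cl_start) + cluster_span +
    (seq_len(n_singletons) - 1) * 30000
  out <- lapply(seq_along(group_ages), function(gi) {
    age <- group_ages[gi]
    dt <- age - min(group_ages)
    chrom <- c(rep("chrS1", n_clusters * k), rep("chrS2", n_singletons))
    start <- c(rep(cl_start, each = k) +
                 (rep(seq_len(k), n_clusters) - 1) * pitch, sing_start)
    sig_cl <- rep(base_signal, n_clusters * k) *
      exp(-rep(cluster_rate, each = k) * dt * rep(centrality, n_clusters))
    sig <- c(sig_cl, rep(singleton_signal, n_singletons)) *
      exp(stats::rnorm(n_clusters * k + n_singletons, 0, signal_noise_sd))
    keep <- sig >= detection_threshold | chrom == "chrS2"
    peak_set(chrom[keep], start[keep], start[keep] + constituent_width,
             score = sig[keep], provenance = sprintf("age_%g", age))
  })
  names(out) <- sprintf("age_%g", group_ages)
  attr(out, "group_ages") <- group_ages
  out
}
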