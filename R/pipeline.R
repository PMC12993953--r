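#' Run the end-to-end clock-building pipeline
#'
#' Orchestrates the stages of the workflow — consensus peak
#' construction, density quantification, batch correction, age-association
#' screening, clock training, noise evaluation, enhancer-domain
#' classification, and trajectory fitting — on either simulated inputs
#' (a `simulate` entry in the config) or files named in the config.
#' Every stage writes its outputs under `out_dir` together with a JSON
#' provenance manifest (parameters, seed, input/output MD5 hashes);
#' rerunning with an identical config reproduces byte-identical outputs.
#'
#' @param config a named list or path to a YAML file. Recognized
#'   entries: `out_dir` (required), `seed` (default 1), `simulate`
#'   (list of [simulate_chipseq] arguments; used when no `counts` path
#'   is given), `counts`, `samples`, `peaks_manifest` (TSV with columns
#'   group, path, dialect of replicate BED files), and per-stage
#'   parameter lists `consensus` (min_replicates), `quantify`
#'   (pseudocount), `screen` (r_min, p_max), `train` (n_groups, alpha,
#'   nlambda), `evaluate` (sigma_grid, n_reps), `enhancers`
#'   (stitch_gap), `trajectory` (span, grid_step).
#' @param stages ordered subset of `c("simulate", "consensus",
#'   "quantify", "correct", "screen", "train", "evaluate", "enhancers",
#'   "trajectory")`.
#' @return invisibly, a list with the in-memory stage results and the
#'   provenance manifest; exit semantics are by error (any stage failure
#'   propagates).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "consensus", "quantify",
                                    "correct", "screen", "train")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "consensus", "quantify", "correct", "screen",
             "train", "evaluate", "enhancers", "trajectory")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  set.seed(seed)

  state <- new.env(parent = emptyenv())
  manifest <- list(seed = seed, stages = list())
  record <- function(stage, params, outputs) {
    manifest$stages[[stage]] <<- list(
      params = params,
      outputs = lapply(outputs, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  }
  need <- function(what, artifact) {
    if (is.null(state[[what]]))
      stop("missing dependency: stage requires ", artifact,
           " (run the producing stage first or point the config at a file)")
    state[[what]]
  }

  # file-based inputs, when provided
  if (!is.null(config$samples)) state$samples <- read_sample_sheet(config$samples)
  if (!is.null(config$counts)) state$counts <- read_counts(config$counts, state$samples)
  if (!is.null(config$peaks_manifest)) {
    man <- utils::read.delim(config$peaks_manifest)
    state$replicate_calls <- lapply(split(man, man$group), function(g)
      lapply(seq_len(nrow(g)), function(i)
        read_bed(g$path[i], dialect = g$dialect[i] %||% "bed3")))
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        args <- config$simulate %||% list()
        args$seed <- args$seed %||% seed
        sim <- do.call(simulate_chipseq, args)
        state$samples <- sim$samples
        state$counts <- sim$signal
        state$replicate_calls <- sim$replicate_calls
        state$truth <- sim$truth
        sf <- file.path(out_dir, "samples.tsv")
        utils::write.table(sim$samples, sf, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        cf <- file.path(out_dir, "counts.tsv")
        cnt <- cbind(sim$peaks[, c("chrom", "start", "end")],
                     as.data.frame(sim$signal$values))
        utils::write.table(cnt, cf, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record("simulate", args, c(sf, cf))
      },
      consensus = {
        calls <- need("replicate_calls", "replicate peak calls")
        mr <- config$consensus$min_replicates %||% 2
        cons <- build_consensus(calls, min_replicates = mr)
        state$consensus <- cons
        f <- file.path(out_dir, "consensus.bed")
        write_bed(cons, f)
        record("consensus", list(min_replicates = mr), f)
      },
      quantify = {
        counts <- need("counts", "a raw count matrix")
        pc <- config$quantify$pseudocount %||% 1
        x <- if (counts$stage == "raw_counts") quantify_density(counts) else counts
        x <- log2_background_subtract(x, pseudocount = pc)
        state$matrix <- x
        f <- file.path(out_dir, "matrix.tsv")
        write_matrix_tsv(x, f)
        record("quantify", list(pseudocount = pc), f)
      },
      correct = {
        x <- need("matrix", "a quantified signal matrix")
        res <- fit_adjust(x)
        state$matrix <- res$corrected
        state$batch_model <- res$model
        f <- file.path(out_dir, "corrected.tsv")
        write_matrix_tsv(res$corrected, f)
        record("correct", list(), f)
      },
      screen = {
        x <- need("matrix", "a signal matrix")
        r_min <- config$screen$r_min %||% 0.5
        p_max <- config$screen$p_max %||% 0.05
        tab <- candidate_filter(spearman_screen(x), r_min = r_min,
                                p_max = p_max)
        state$associations <- tab
        f <- file.path(out_dir, "associations.tsv")
        write_association_table(tab, f, peaks = x$peaks)
        record("screen", list(r_min = r_min, p_max = p_max), f)
      },
      train = {
        x <- need("matrix", "a signal matrix")
        tr <- config$train %||% list()
        xm <- x
        if (!is.null(state$associations) && any(state$associations$is_candidate)) {
          keep <- which(state$associations$is_candidate)
          xm <- signal_matrix(x$values[keep, , drop = FALSE],
                              peak_subset(x$peaks, keep), x$samples,
                              stage = x$stage)
        }
        fit <- histone_clock(xm, n_groups = tr$n_groups %||% 11,
                             alpha = tr$alpha %||% seq(0, 1, by = 0.1),
                             nlambda = tr$nlambda %||% 100)
        state$model <- fit
        mf <- file.path(out_dir, "model.json")
        write_clock(fit, mf)
        pf <- file.path(out_dir, "cv_predictions.tsv")
        utils::write.table(
          data.frame(sample_id = x$samples$sample_id, age = fit$age,
                     cv_predicted = fit$cv$predictions),
          pf, sep = "\t", quote = FALSE, row.names = FALSE)
        record("train", tr, c(mf, pf))
      },
      evaluate = {
        fit <- need("model", "a trained clock model")
        x <- need("matrix", "a signal matrix")
        ev <- config$evaluate %||% list()
        curve <- noise_robustness(fit, x, x$samples$age,
                                  sigma_grid = ev$sigma_grid %||%
                                    seq(0, 1.5, by = 0.3),
                                  n_reps = ev$n_reps %||% 20, seed = seed)
        state$noise_curve <- curve
        f <- file.path(out_dir, "noise_curve.tsv")
        utils::write.table(
          data.frame(sigma = curve$sigma_grid, rmse_mean = curve$rmse_mean,
                     rmse_sem = curve$rmse_sem,
                     relative_rmse = curve$relative_rmse),
          f, sep = "\t", quote = FALSE, row.names = FALSE)
        record("evaluate", ev, f)
      },
      enhancers = {
        x <- need("matrix", "a signal matrix")
        gap <- config$enhancers$stitch_gap %||% 12500
        scored <- x$peaks
        scored$score <- rowMeans(x$values)
        dom <- classify_super(stitch_enhancers(scored, stitch_gap = gap))
        state$domains <- dom
        f <- file.path(out_dir, "domains.bed")
        write_domains(dom, f)
        record("enhancers", list(stitch_gap = gap), f)
      },
      trajectory = {
        x <- need("matrix", "a signal matrix")
        tj <- config$trajectory %||% list()
        keep <- if (!is.null(state$associations))
          which(state$associations$is_candidate & state$associations$direction ==
                  "positive") else seq_len(nrow(x$values))
        if (!length(keep)) keep <- seq_len(nrow(x$values))
        z <- standardize_features(x$values[keep, , drop = FALSE])$standardized
        fitT <- loess_trajectory(x$samples$age, colMeans(z),
                                 span = tj$span %||% 0.5,
                                 grid_step = tj$grid_step %||% 1)
        state$trajectory <- fitT
        f <- file.path(out_dir, "trajectory.tsv")
        utils::write.table(
          data.frame(age = fitT$age_grid, fitted = fitT$fitted),
          f, sep = "\t", quote = FALSE, row.names = FALSE)
        record("trajectory", tj, f)
      })
  }
  mf <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(state = as.list(state), manifest = manifest))
}

# subset a peak_set by row index, preserving class and provenance
peak_subset <- function(peaks, idx) {
  peak_set(peaks$chrom[idx], peaks$start[idx], peaks$end[idx],
           name = peaks$name[idx], score = peaks$score[idx],
           provenance = attr(peaks, "provenance"))
}

write_matrix_tsv <- function(x, path) {
  df <- cbind(x$peaks[, c("chrom", "start", "end")],
              as.data.frame(signif(x$values, 10)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
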