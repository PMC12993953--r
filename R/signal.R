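#' Construct a signal matrix
#'
#' The central container tying a peaks-by-samples matrix to peak
#' coordinates and sample metadata. The `stage` tag records how far along
#' the normalization pipeline the values are: raw counts, reads-in-peaks
#' density, log2 background-subtracted signal, standardized features, or
#' batch-corrected signal.
#'
#' @param values numeric matrix, peaks in rows, samples in columns.
#' @param peaks a [peak_set] aligned to the rows.
#' @param samples a data frame of sample metadata aligned to the columns;
#'   must contain at least `sample_id` (unique) and `age` (finite years).
#'   Conventional further columns: `sex`, `batch`, `tissue`, `mark`,
#'   `replicate_group`, `condition`.
#' @param stage one of `"raw_counts"`, `"density"`, `"log2bg"`,
#'   `"standardized"`, `"batch_corrected"`.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(values, peaks, samples,
                          stage = c("raw_counts", "density", "log2bg",
                                    "standardized", "batch_corrected")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!inherits(peaks, "peak_set")) stop("peaks must be a peak_set")
  if (nrow(values) != nrow(peaks))
    stop("row count of values must equal the number of peaks")
  if (ncol(values) != nrow(samples))
    stop("column count of values must equal the number of samples")
  if (!all(c("sample_id", "age") %in% names(samples)))
    stop("samples must contain sample_id and age columns")
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique")
  if (any(!is.finite(samples$age)))
    stop("ages must be finite")
  if (stage == "raw_counts") {
    if (any(values < 0, na.rm = TRUE)) stop("raw counts must be non-negative")
  } else if (any(!is.finite(values))) {
    stop("values must be finite at stage ", stage)
  }
  rownames(values) <- peak_ids(peaks)
  colnames(values) <- samples$sample_id
  structure(list(values = values, peaks = peaks,
                 samples = as.data.frame(samples), stage = stage),
            class = "signal_matrix")
}

#' Peak identifiers in "chrom:start-end" form
#' @param peaks a [peak_set].
#' @return character vector of ids.
#' @export
peak_ids <- function(peaks) {
  sprintf("%s:%d-%d", peaks$chrom, as.integer(peaks$start),
          as.integer(peaks$end))
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d peaks x %d samples [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Read a count matrix with peak coordinates
#'
#' Expects a tab-delimited file whose first three columns are
#' chrom/start/end and whose remaining columns are per-sample raw counts,
#' with a header row of sample ids.
#'
#' @param path counts TSV.
#' @param samples sample sheet data frame (see [read_sample_sheet]); its
#'   rows are matched to the count columns by `sample_id`.
#' @return A `signal_matrix` at stage `raw_counts`.
#' @export
read_counts <- function(path, samples) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) < 4) stop("counts file must have chrom/start/end plus samples")
  peaks <- peak_set(df[[1]], df[[2]], df[[3]])
  mat <- as.matrix(df[, -(1:3), drop = FALSE])
  missing <- setdiff(samples$sample_id, colnames(mat))
  if (length(missing))
    stop("samples absent from counts file: ", paste(missing, collapse = ", "))
  mat <- mat[, samples$sample_id, drop = FALSE]
  # rows must follow peak_set sort order
  ord <- order(df[[1]], df[[2]], df[[3]])
  signal_matrix(mat[ord, , drop = FALSE], peaks, samples, stage = "raw_counts")
}

#' Read a sample sheet
#'
#' @param path TSV or CSV with columns sample_id, age and optionally sex,
#'   batch, tissue, mark, replicate_group, condition. Missing optional
#'   columns are filled with defaults.
#' @return data frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age") %in% names(df)))
    stop("sample sheet must contain sample_id and age")
  defaults <- list(sex = "unknown", batch = "batch1", tissue = "unknown",
                   mark = "unknown", replicate_group = NA_character_,
                   condition = "healthy")
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- defaults[[col]]
  df$sample_id <- as.character(df$sample_id)
  df$age <- as.numeric(df$age)
  df
}

#' Reads-in-peaks density normalization
#'
#' Converts raw per-peak counts to read densities: each count is divided
#' by the peak length in kilobases and by the sample's total
#' reads-in-peaks in millions, i.e.
#' d[g,j] = c[g,j] / (L_g / 1000) / (R_j / 1e6) with R_j the column sum.
#' A sample's densities are therefore invariant to rescaling its counts.
#'
#' @param counts a `signal_matrix` at stage `raw_counts`.
#' @return A `signal_matrix` at stage `density`.
#' @export
quantify_density <- function(counts) {
  stopifnot(inherits(counts, "signal_matrix"))
  if (counts$stage != "raw_counts")
    stop("quantify_density expects stage raw_counts, got ", counts$stage)
  len_kb <- (counts$peaks$end - counts$peaks$start) / 1000
  if (any(len_kb <= 0)) stop("all peak lengths must be > 0")
  rip <- colSums(counts$values)
  zero <- which(rip == 0)
  if (length(zero))
    stop("sample(s) with zero reads-in-peaks: ",
         paste(colnames(counts$values)[zero], collapse = ", "))
  d <- sweep(counts$values / len_kb, 2, rip / 1e6, `/`)
  signal_matrix(d, counts$peaks, counts$samples, stage = "density")
}

#' Log2 transformation with background subtraction
#'
#' Applies x = log2(d + pseudocount). If a matched input-control density
#' matrix is supplied (aligned to the same peaks and samples), its
#' log2-transformed value is subtracted cell-wise; otherwise each sample
#' column is centered on its own median, a download-free surrogate for an
#' input track.
#'
#' @param density `signal_matrix` at stage `density`.
#' @param input_density optional matched input-control `signal_matrix`
#'   at stage `density`.
#' @param pseudocount positive value added before taking logs (default 1).
#' @return `signal_matrix` at stage `log2bg`.
#' @export
log2_background_subtract <- function(density, input_density = NULL,
                                     pseudocount = 1) {
  stopifnot(inherits(density, "signal_matrix"))
  if (density$stage != "density")
    stop("expected stage density, got ", density$stage)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  x <- log2(density$values + pseudocount)
  if (!is.null(input_density)) {
    stopifnot(inherits(input_density, "signal_matrix"))
    if (!identical(dim(input_density$values), dim(x)))
      stop("input_density must be aligned to the same peaks and samples")
    x <- x - log2(input_density$values + pseudocount)
  } else {
    x <- sweep(x, 2, apply(x, 2, stats::median), `-`)
  }
  signal_matrix(x, density$peaks, density$samples, stage = "log2bg")
}

#' Standardize features on a training subset
#'
#' Per-feature mean and standard deviation (unbiased, n-1 denominator)
#' are estimated on `fit_columns` only and applied to all columns. This
#' keeps held-out samples out of the scaling estimates during
#' cross-validation. Features constant on the fit set are mapped to zero
#' and flagged.
#'
#' @param x `signal_matrix` (any finite stage) or plain matrix.
#' @param fit_columns indices or sample ids of the columns used to
#'   estimate the scaling; default all columns.
#' @return list with `standardized` (same class as `x`, stage
#'   `standardized`), `mean`, `sd` (per feature; flagged features keep
#'   their fit-set mean and an sd of NA), and `constant` (logical flag).
#' @export
standardize_features <- function(x, fit_columns = NULL) {
  mat <- if (inherits(x, "signal_matrix")) x$values else as.matrix(x)
  if (is.null(fit_columns)) fit_columns <- seq_len(ncol(mat))
  if (is.character(fit_columns)) fit_columns <- match(fit_columns, colnames(mat))
  if (!length(fit_columns)) stop("fit_columns must be nonempty")
  fit <- mat[, fit_columns, drop = FALSE]
  mu <- rowMeans(fit)
  sd_ <- apply(fit, 1, stats::sd)
  constant <- sd_ == 0 | !is.finite(sd_)
  z <- (mat - mu) / ifelse(constant, 1, sd_)
  z[constant, ] <- 0
  sd_out <- ifelse(constant, NA_real_, sd_)
  out <- if (inherits(x, "signal_matrix"))
    signal_matrix(z, x$peaks, x$samples, stage = "standardized") else z
  list(standardized = out, mean = mu, sd = sd_out, constant = constant)
}

# internal: pull the numeric matrix out of either container
signal_values <- function(x) {
  if (inherits(x, "signal_matrix")) x$values else as.matrix(x)
}
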