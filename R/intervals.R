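#' Construct a peak set
#'
#' A peak set is an ordered collection of genomic intervals in BED
#' convention (0-based, half-open), sorted by (chrom, start), with optional
#' names and signal scores. It is the coordinate container for ChIP-seq
#' peaks throughout the package.
#'
#' @param chrom character vector of chromosome names (opaque strings; no
#'   alias resolution between e.g. "chr1" and "1").
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions; must satisfy
#'   `end > start`.
#' @param name optional identifiers.
#' @param score optional numeric signal values.
#' @param provenance optional label (sample id or age-group id).
#' @return An object of class `peak_set`: a data frame with columns
#'   `chrom`, `start`, `end`, `name`, `score`, sorted by (chrom, start).
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     name = NA_character_, score = NA_real_,
                     provenance = NULL) {
  n <- length(start)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (n > 0) {
    if (any(!nzchar(chrom)) || anyNA(chrom)) stop("chrom must be nonempty strings")
    if (anyNA(start) || anyNA(end)) stop("coordinates must be non-missing")
    bad <- which(end <= start)
    if (length(bad))
      stop(sprintf("invalid interval at row %d: end (%s) <= start (%s)",
                   bad[1], format(end[bad[1]]), format(start[bad[1]])))
    if (any(start < 0)) stop("start positions must be >= 0")
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_set", "data.frame"), provenance = provenance)
}

#' @export
print.peak_set <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("peak_set: %d intervals on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (is.null(prov)) "" else paste0(" [", prov, "]")))
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

# internal: peak_set <-> GRanges (BED half-open to 1-based closed)
as_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

granges_to_peaks <- function(gr, provenance = NULL) {
  peak_set(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1,
           end = GenomicRanges::end(gr),
           provenance = provenance)
}

#' Read a BED-family file into a peak set
#'
#' Supports BED3, BED6, and the ENCODE narrowPeak / broadPeak dialects.
#' Coordinates are kept in the file's 0-based half-open convention.
#'
#' @param path path to a tab-delimited file.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#'   For the peak dialects the 7th column (signalValue) is stored as the
#'   score; for bed6 the 5th column is the score.
#' @param provenance optional provenance label to attach.
#' @return A [peak_set] sorted by (chrom, start).
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6", "narrowPeak", "broadPeak"),
                     provenance = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) return(peak_set(provenance = provenance))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_fields <- switch(dialect, bed3 = 3L, bed6 = 6L,
                       narrowPeak = 7L, broadPeak = 7L)
  nf <- lengths(fields)
  if (any(nf < min_fields))
    stop(sprintf("parse error at line %d: expected >= %d tab-separated fields, got %d",
                 which(nf < min_fields)[1], min_fields, nf[which(nf < min_fields)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("parse error at line %d: coordinates are not integers", bad[1]))
  if (any(end <= start)) {
    i <- which(end <= start)[1]
    stop(sprintf("validation error at line %d: end (%s) <= start (%s)",
                 i, fields[[i]][3], fields[[i]][2]))
  }
  name <- if (min_fields >= 6L || dialect %in% c("narrowPeak", "broadPeak"))
    vapply(fields, `[[`, "", 4L) else NA_character_
  score <- switch(dialect,
    bed3 = NA_real_,
    bed6 = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))),
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L))))
  peak_set(chrom, start, end, name = name, score = score,
           provenance = provenance)
}

#' Write a peak set as BED
#'
#' Writes BED3 or BED6 (name, score, strand "."); coordinates round-trip
#' bit-exactly through [read_bed].
#'
#' @param peaks a [peak_set].
#' @param path output path.
#' @param dialect `"bed3"` or `"bed6"`.
#' @export
write_bed <- function(peaks, path, dialect = c("bed3", "bed6")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(peaks)[, c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  if (dialect == "bed6") {
    df$name <- ifelse(is.na(peaks$name), ".", peaks$name)
    df$score <- ifelse(is.na(peaks$score), "0",
                       format(peaks$score, scientific = FALSE, trim = TRUE))
    df$strand <- "."
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals within a peak set
#'
#' Joins intervals on the same chromosome separated by at most `max_gap`
#' base pairs. Abutting intervals (gap of zero under the half-open
#' convention) are joined when `max_gap = 0`, matching the usual merge
#' semantics of interval toolkits.
#'
#' @param peaks a [peak_set].
#' @param max_gap non-negative integer gap (bp) up to which intervals are
#'   joined.
#' @return A sorted, non-overlapping [peak_set].
#' @export
merge_intervals <- function(peaks, max_gap = 0) {
  stopifnot(inherits(peaks, "peak_set"))
  if (max_gap < 0) stop("max_gap must be non-negative")
  if (!nrow(peaks)) return(peaks)
  gr <- GenomicRanges::reduce(as_granges(peaks), min.gapwidth = max_gap + 1)
  granges_to_peaks(gr, provenance = attr(peaks, "provenance"))
}

#' Build a consensus peak set from replicated per-age peak calls
#'
#' Within each age group, genomic positions covered by at least
#' `min_replicates` replicate peak sets are kept and merged into a
#' subconsensus set; subconsensus sets are then merged across groups into
#' one consensus set. Replicate consistency is defined at base-pair level
#' (coverage counting), which is order-invariant.
#'
#' @param replicate_peaksets a named list; each element is a list of
#'   [peak_set] objects (the replicates of one age group).
#' @param min_replicates positive integer; groups with fewer replicates
#'   than this raise an error.
#' @return The consensus [peak_set] (sorted, non-overlapping).
#' @export
build_consensus <- function(replicate_peaksets, min_replicates = 2) {
  if (!length(replicate_peaksets)) stop("no age groups supplied")
  if (min_replicates < 1) stop("min_replicates must be >= 1")
  group_names <- names(replicate_peaksets)
  if (is.null(group_names)) group_names <- as.character(seq_along(replicate_peaksets))
  sub <- vector("list", length(replicate_peaksets))
  for (i in seq_along(replicate_peaksets)) {
    reps <- replicate_peaksets[[i]]
    if (!length(reps))
      stop("age group '", group_names[i], "' has no replicate peak sets")
    if (length(reps) < min_replicates)
      stop(sprintf("age group '%s' has %d replicate(s) but min_replicates = %d",
                   group_names[i], length(reps), min_replicates))
    # count, at each bp, how many replicates cover it (each replicate
    # merged first so double-counting within a replicate is impossible);
    # a shared seqinfo keeps the per-replicate coverage vectors aligned
    grl <- lapply(reps, function(p) GenomicRanges::reduce(as_granges(p)))
    all_chroms <- unique(unlist(lapply(grl, function(g)
      as.character(GenomicRanges::seqnames(g)))))
    max_end <- max(vapply(grl, function(g)
      if (length(g)) max(GenomicRanges::end(g)) else 0L, numeric(1)))
    si <- GenomeInfoDb::Seqinfo(seqnames = all_chroms,
                                seqlengths = rep(max_end, length(all_chroms)))
    grl <- lapply(grl, function(g) {
      GenomeInfoDb::seqlevels(g) <- all_chroms
      GenomeInfoDb::seqinfo(g) <- si
      g
    })
    cov <- Reduce(`+`, lapply(grl, GenomicRanges::coverage))
    hits <- IRanges::slice(cov, lower = min_replicates, rangesOnly = TRUE)
    sub[[i]] <- GenomicRanges::GRanges(hits)
  }
  consensus <- GenomicRanges::reduce(do.call(c, sub))
  granges_to_peaks(consensus, provenance = "consensus")
}

#' Flag peaks overlapping an annotation set
#'
#' A peak is flagged when it overlaps at least one base pair of any
#' annotation interval. Used for genomic-context enrichment (promoter,
#' enhancer) of age-associated peaks.
#'
#' @param query a [peak_set] of peaks to test.
#' @param annotation a [peak_set] of annotation intervals.
#' @return A list with `flags` (logical per query interval, in query
#'   order), `n_overlapping` and `n_total`.
#' @export
overlap_fraction <- function(query, annotation) {
  stopifnot(inherits(query, "peak_set"), inherits(annotation, "peak_set"))
  if (!nrow(query))
    return(list(flags = logical(0), n_overlapping = 0L, n_total = 0L))
  if (!nrow(annotation))
    return(list(flags = rep(FALSE, nrow(query)),
                n_overlapping = 0L, n_total = nrow(query)))
  flags <- GenomicRanges::countOverlaps(as_granges(query),
                                        as_granges(annotation)) > 0
  list(flags = unname(flags), n_overlapping = sum(flags),
       n_total = nrow(query))
}
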