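#' Tiling-array quantification settings
#'
#' @param smoothing_window_bp width in bp of the pseudomedian smoothing
#'   window centred on each probe (default 110).
#' @param min_exon_overlap_fraction minimum fraction of a probe's length that
#'   must overlap a transcript's exon union for the probe to count toward
#'   that transcript (default 0.5).
#' @param combine_replicates statistic used to combine quantile-normalized
#'   replicate signals before smoothing: `"mean"` (default) or `"median"`.
#' @return list of class `tiling_config`.
#' @export
tiling_config <- function(smoothing_window_bp = 110,
                          min_exon_overlap_fraction = 0.5,
                          combine_replicates = c("mean", "median")) {
  stopifnot(smoothing_window_bp > 0,
            min_exon_overlap_fraction > 0, min_exon_overlap_fraction <= 1)
  combine_replicates <- match.arg(combine_replicates)
  structure(list(smoothing_window_bp = smoothing_window_bp,
                 min_exon_overlap_fraction = min_exon_overlap_fraction,
                 combine_replicates = combine_replicates),
            class = "tiling_config")
}

#' dcpm (depth of coverage per million mapped reads) settings
#'
#' @param representation_cutoff bases whose representation value (number of
#'   genomic placements of reads covering the base) is at or above this
#'   cutoff are excluded from both numerator and denominator (default 96).
#' @param quality_threshold per-base score must exceed this to contribute to
#'   the numerator (default 0, i.e. all covered bases contribute).
#' @param scale library-size scale factor (default 1e6).
#' @return list of class `dcpm_config`.
#' @export
dcpm_config <- function(representation_cutoff = 96, quality_threshold = 0,
                        scale = 1e6) {
  stopifnot(representation_cutoff > 0, scale > 0)
  structure(list(representation_cutoff = representation_cutoff,
                 quality_threshold = quality_threshold, scale = scale),
            class = "dcpm_config")
}

#' Per-probe PM - MM signal
#'
#' The specific hybridization signal of a tiling probe is estimated as the
#' difference between its perfect-match and mismatch intensities, replicate
#' by replicate.  Negative differences are retained.
#'
#' @param pm,mm numeric matrices (probes x replicates) of perfect-match and
#'   mismatch intensities, identical dimensions.
#' @return numeric matrix `pm - mm`.
#' @export
pm_mm_difference <- function(pm, mm) {
  pm <- as.matrix(pm)
  mm <- as.matrix(mm)
  if (nrow(pm) == 0) stop("no probes")
  if (!identical(dim(pm), dim(mm))) {
    stop("PM and MM matrices must have identical dimensions (replicate-count mismatch?)")
  }
  pm - mm
}

#' Quantile normalization across replicate columns
#'
#' Forces identical value distributions across columns by replacing each
#' column's order statistics with the across-column mean of order statistics;
#' ranks within each column are preserved.  Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix with >= 2 columns.
#' @return normalized matrix, same dimensions.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 columns")
  if (any(apply(x, 2, function(col) all(is.na(col))))) {
    stop("column with all-missing values")
  }
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Hodges-Lehmann pseudomedian
#'
#' The median of all pairwise averages `(x_i + x_j)/2` over `i <= j`
#' (self-pairs included, so the estimator is defined for a single value).
#'
#' @param x numeric vector.
#' @return scalar pseudomedian.
#' @export
pseudomedian <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  stats::median((x[idx[, 1]] + x[idx[, 2]]) / 2)
}

#' Pseudomedian smoothing of probe signals along the chromosome
#'
#' For each probe, all probes whose centre lies within half the window width
#' of its own centre (the probe itself included) contribute their
#' replicate-combined signals, and the smoothed value is the Hodges-Lehmann
#' pseudomedian of that multiset.  With a window narrower than the probe
#' spacing each probe keeps its own value.
#'
#' @param values numeric vector of replicate-combined probe signals.
#' @param positions numeric vector of probe centre positions (bp), sorted
#'   increasing.
#' @param window_bp window width in bp.
#' @return numeric vector of smoothed per-probe values.
#' @export
pseudomedian_smooth <- function(values, positions, window_bp) {
  stopifnot(length(values) == length(positions), window_bp > 0)
  if (is.unsorted(positions)) stop("'positions' must be sorted")
  half <- window_bp / 2
  n <- length(values)
  out <- numeric(n)
  lo <- 1
  hi <- 1
  for (i in seq_len(n)) {
    while (positions[lo] < positions[i] - half) lo <- lo + 1
    while (hi < n && positions[hi + 1] <= positions[i] + half) hi <- hi + 1
    out[i] <- pseudomedian(values[lo:hi])
  }
  out
}

probe_centers <- function(start, end) (start + end) / 2

# Fraction of each probe covered by the exon union of one transcript.
probe_exon_overlap_fraction <- function(probe_start, probe_end, exon_start, exon_end) {
  probes <- IRanges::IRanges(start = probe_start + 1, end = probe_end)
  exons <- IRanges::reduce(IRanges::IRanges(start = exon_start + 1, end = exon_end))
  ov <- IRanges::findOverlaps(probes, exons)
  inter_w <- IRanges::width(IRanges::pintersect(
    probes[S4Vectors::queryHits(ov)], exons[S4Vectors::subjectHits(ov)]
  ))
  tot <- numeric(length(probes))
  if (length(ov)) {
    agg <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
    tot[as.integer(names(agg))] <- agg
  }
  tot / IRanges::width(probes)
}

#' Transcript expression from smoothed probe signals
#'
#' A probe qualifies for a transcript when at least
#' `min_exon_overlap_fraction` of its length overlaps the transcript's exon
#' union (overlap may be summed across exons).  The transcript's expression
#' is the median of its qualifying probes' smoothed signals; with no
#' qualifying probe the value is missing.
#'
#' @param probe_start,probe_end 0-based half-open probe coordinates.
#' @param smoothed numeric vector of smoothed probe signals.
#' @param exon_start,exon_end 0-based half-open exon coordinates of one
#'   transcript.
#' @param config a [tiling_config()].
#' @return scalar expression value, or `NA` if no probe qualifies.
#' @export
transcript_expression_from_probes <- function(probe_start, probe_end, smoothed,
                                              exon_start, exon_end,
                                              config = tiling_config()) {
  frac <- probe_exon_overlap_fraction(probe_start, probe_end, exon_start, exon_end)
  keep <- frac >= config$min_exon_overlap_fraction
  if (!any(keep)) return(NA_real_)
  stats::median(smoothed[keep])
}

#' Slide-median normalization
#'
#' Divides every expression value by the slide median, i.e. the median signal
#' over all probes on the array, making values comparable between samples.
#'
#' @param values numeric vector of transcript expression values.
#' @param probe_signals numeric vector of all probe signals on the array from
#'   which the slide median is taken.
#' @return normalized values.
#' @export
slide_median_normalize <- function(values, probe_signals) {
  m <- stats::median(probe_signals, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("slide median is zero or undefined")
  values / m
}

#' Full tiling-array quantification pipeline
#'
#' PM-MM differencing, quantile normalization across replicates, replicate
#' combination, pseudomedian smoothing along each chromosome, probe-to-
#' transcript assignment by exon overlap, per-transcript median and
#' slide-median normalization.
#'
#' @param probes data frame with columns `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and intensity columns `pm_1..pm_k`, `mm_1..mm_k`.
#' @param models a `transcript_models` data frame (one row per exon; see
#'   [read_transcript_models()] / [simulate_transcript_models()]).
#' @param config a [tiling_config()].
#' @return data frame `transcript_id`, `value` (slide-median normalized; `NA`
#'   when no probe qualifies).
#' @export
tiling_expression <- function(probes, models, config = tiling_config()) {
  pm_cols <- grep("^pm_", names(probes), value = TRUE)
  mm_cols <- grep("^mm_", names(probes), value = TRUE)
  if (length(pm_cols) == 0 || length(pm_cols) != length(mm_cols)) {
    stop("probe table needs matching pm_*/mm_* replicate columns")
  }
  signal <- pm_mm_difference(as.matrix(probes[pm_cols]), as.matrix(probes[mm_cols]))
  signal <- quantile_normalize(signal)
  combined <- switch(config$combine_replicates,
                     mean = rowMeans(signal),
                     median = apply(signal, 1, stats::median))

  centers <- probe_centers(probes$start, probes$end)
  smoothed <- rep(NA_real_, nrow(probes))
  for (chr in unique(probes$chrom)) {
    sel <- which(probes$chrom == chr)
    ord <- sel[order(centers[sel])]
    smoothed[ord] <- pseudomedian_smooth(combined[ord], centers[ord],
                                         config$smoothing_window_bp)
  }

  txs <- unique(models$transcript_id)
  vals <- vapply(txs, function(tx) {
    ex <- models[models$transcript_id == tx, , drop = FALSE]
    on_chr <- probes$chrom == ex$chrom[1]
    if (!any(on_chr)) return(NA_real_)
    transcript_expression_from_probes(
      probes$start[on_chr], probes$end[on_chr], smoothed[on_chr],
      ex$start, ex$end, config
    )
  }, 0)
  data.frame(transcript_id = txs,
             value = slide_median_normalize(vals, smoothed),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' dcpm for one transcript
#'
#' Average depth of coverage per million mapped reads: the sum of per-base
#' scores over exonic bases that pass the quality threshold and whose
#' representation value is below the cutoff, divided by the number of exonic
#' bases with representation below the cutoff, scaled by 1e6 and divided by
#' the high-quality mapped read count.  When every exonic base is at or above
#' the representation cutoff the denominator is zero and the value is
#' missing (`NA`, written as "nan" in exported tables).
#'
#' @param coverage data frame `chrom`, `pos` (0-based), `score`,
#'   `representation`; bases absent from the track are taken as score 0,
#'   representation 1.
#' @param exon_start,exon_end 0-based half-open exon coordinates of the
#'   transcript (single chromosome).
#' @param chrom chromosome of the transcript.
#' @param read_stats list with `high_quality_mapped_reads` (> 0).
#' @param config a [dcpm_config()].
#' @return scalar dcpm, or `NA` when the denominator is zero.
#' @export
compute_dcpm <- function(coverage, exon_start, exon_end, chrom, read_stats,
                         config = dcpm_config()) {
  M <- read_stats$high_quality_mapped_reads
  if (is.null(M) || M <= 0) stop("high_quality_mapped_reads must be > 0")
  exons <- IRanges::reduce(IRanges::IRanges(start = exon_start + 1, end = exon_end))
  total_bases <- sum(IRanges::width(exons))

  cov <- coverage[coverage$chrom == chrom, , drop = FALSE]
  in_exon <- logical(nrow(cov))
  if (nrow(cov)) {
    pos_r <- IRanges::IRanges(start = cov$pos + 1, width = 1)
    in_exon <- IRanges::overlapsAny(pos_r, exons)
  }
  cov <- cov[in_exon, , drop = FALSE]

  high_rep <- cov$representation >= config$representation_cutoff
  denominator <- total_bases - sum(high_rep)
  if (denominator == 0) return(NA_real_)
  ok <- !high_rep & cov$score > config$quality_threshold
  numerator <- sum(cov$score[ok])
  (numerator / denominator) * config$scale / M
}

#' dcpm for every transcript in a model set
#'
#' @inheritParams compute_dcpm
#' @param models a `transcript_models` data frame.
#' @return data frame `transcript_id`, `value`.
#' @export
dcpm_table <- function(coverage, models, read_stats, config = dcpm_config()) {
  txs <- unique(models$transcript_id)
  vals <- vapply(txs, function(tx) {
    ex <- models[models$transcript_id == tx, , drop = FALSE]
    compute_dcpm(coverage, ex$start, ex$end, ex$chrom[1], read_stats, config)
  }, 0)
  data.frame(transcript_id = txs, value = vals,
             stringsAsFactors = FALSE, row.names = NULL)
}
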