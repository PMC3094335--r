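#' Build a platform base set of detected genes
#'
#' Each platform has its own notion of a detected gene, and regulation and
#' enrichment are always evaluated against that universe:
#' \describe{
#'   \item{oligo}{signal at least `background_factor` times background and an
#'     unflagged data point in at least `min_arrays` of the arrays.}
#'   \item{cdna}{expression above `psl_threshold` PSL in either condition in
#'     at least `min_experiments` of the experiments.}
#'   \item{rnaseq}{non-zero dcpm in at least one data set.}
#'   \item{tiling}{all transcripts (the platform yields no zero values).}
#' }
#'
#' @param platform one of `"oligo"`, `"cdna"`, `"rnaseq"`, `"tiling"`.
#' @param data platform-specific input:
#'   oligo — list with `signal`, `background` (gene x array matrices) and
#'   `flagged` (logical matrix, TRUE when the data point is flagged);
#'   cdna — list of data frames `transcript_id`, `control`, `infected` (PSL);
#'   rnaseq — list of data frames `transcript_id`, `value` (dcpm, `NA` for
#'   missing);
#'   tiling — data frame with a `transcript_id` column.
#' @param background_factor,min_arrays oligo rule parameters (defaults 2, 4).
#' @param psl_threshold,min_experiments cdna rule parameters (defaults 40, 1).
#' @return character vector of gene/transcript ids in the base set.
#' @export
build_base_set <- function(platform = c("oligo", "cdna", "rnaseq", "tiling"),
                           data, background_factor = 2, min_arrays = 4,
                           psl_threshold = 40, min_experiments = 1) {
  platform <- match.arg(platform)
  switch(platform,
    oligo = {
      ok <- data$signal >= background_factor * data$background & !data$flagged
      rownames(data$signal)[rowSums(ok, na.rm = TRUE) >= min_arrays]
    },
    cdna = {
      ids <- unique(unlist(lapply(data, `[[`, "transcript_id")))
      n_det <- rowSums(vapply(data, function(d) {
        v <- pmax(d$control, d$infected, na.rm = TRUE)[match(ids, d$transcript_id)]
        !is.na(v) & v > psl_threshold
      }, logical(length(ids))))
      ids[n_det >= min_experiments]
    },
    rnaseq = {
      ids <- unique(unlist(lapply(data, `[[`, "transcript_id")))
      nonzero <- rowSums(vapply(data, function(d) {
        v <- d$value[match(ids, d$transcript_id)]
        !is.na(v) & v > 0
      }, logical(length(ids))))
      ids[nonzero >= 1]
    },
    tiling = unique(data$transcript_id)
  )
}

#' Bundle a platform's base set with its up/down calls at a release
#'
#' @param platform platform label.
#' @param release annotation release the ids refer to.
#' @param base_set,up_set,down_set character vectors; `up_set` and
#'   `down_set` must be subsets of `base_set` and disjoint.
#' @return list of class `platform_dataset`.
#' @export
platform_dataset <- function(platform, release, base_set, up_set, down_set) {
  if (!all(up_set %in% base_set) || !all(down_set %in% base_set)) {
    stop("up/down sets must be subsets of the base set")
  }
  if (length(intersect(up_set, down_set))) stop("up and down sets overlap")
  structure(list(platform = platform, release = release,
                 base_set = base_set, up_set = up_set, down_set = down_set),
            class = "platform_dataset")
}

check_common_release <- function(releases) {
  releases <- releases[!is.na(releases)]
  if (length(unique(releases)) > 1) {
    stop("gene sets come from different releases (",
         paste(unique(releases), collapse = ", "),
         "); convert them to a common release first")
  }
}

#' Venn region counts and pairwise overlap percentages for 2-5 gene sets
#'
#' Counts every of the `2^k - 1` membership regions, and reports pairwise
#' overlaps as percentages with both possible denominators (an "overlap of
#' 44\%" is meaningless without stating whether it is relative to the first
#' or the second list).
#'
#' @param sets named list of 2-5 character vectors.
#' @param releases optional character vector of release labels, one per set;
#'   mixed releases are an error.
#' @return list of class `overlap_report` with `regions` (data frame
#'   `region`, `count`: region names are `A&B`-style membership patterns over
#'   set names), `pairwise` (data frame `set_a`, `set_b`, `intersection`,
#'   `pct_of_a`, `pct_of_b`), `union_size`.
#' @export
venn_counts <- function(sets, releases = NULL) {
  k <- length(sets)
  if (k < 2 || k > 5) stop("need 2 to 5 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  if (!is.null(releases)) check_common_release(releases)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = combos))
  regions <- data.frame(region = combos, count = as.integer(counts),
                        stringsAsFactors = FALSE)

  pairs <- utils::combn(names(sets), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    n_ab <- length(intersect(sets[[a]], sets[[b]]))
    data.frame(set_a = a, set_b = b, intersection = n_ab,
               pct_of_a = 100 * n_ab / max(length(sets[[a]]), 1),
               pct_of_b = 100 * n_ab / max(length(sets[[b]]), 1),
               stringsAsFactors = FALSE)
  }))
  structure(list(regions = regions, pairwise = pairwise,
                 union_size = length(universe)),
            class = "overlap_report")
}

#' Shared and specific gene lists across data sets
#'
#' Evaluates a declarative combination specification against named gene
#' sets: each combination names the sets a gene must belong to (`all_of`)
#' and the sets it must not (`none_of`).
#'
#' @param sets named list of character vectors (e.g. up-regulated genes per
#'   pathogen).
#' @param combinations named list; each element is a list with `all_of`
#'   (character, required) and optional `none_of`.
#' @param releases optional release labels, one per set; mixed releases are
#'   an error.
#' @return named list of character vectors, one per combination.
#' @export
shared_and_specific <- function(sets, combinations, releases = NULL) {
  if (length(combinations) == 0) stop("empty combination spec")
  if (!is.null(releases)) check_common_release(releases)
  lapply(combinations, function(cmb) {
    if (is.null(cmb$all_of) || length(cmb$all_of) == 0) {
      stop("each combination needs an 'all_of' element")
    }
    inside <- Reduce(intersect, sets[cmb$all_of])
    if (!is.null(cmb$none_of) && length(cmb$none_of)) {
      inside <- setdiff(inside, unique(unlist(sets[cmb$none_of])))
    }
    inside
  })
}

#' Biomarker selection across platforms
#'
#' Two complementary lists: (1) genes called up on at least `min_platforms`
#' platforms — a high-confidence multi-technique catalogue; (2) genes with a
#' low uninfected baseline (below the `low_expression_quantile` of non-zero
#' baselines in the base set) but a strong induction (fold change above
#' `high_induction_fold`) — low-expression candidates that the
#' multi-platform intersection misses because some platforms cannot see
#' them.
#'
#' @param datasets list of [platform_dataset()] objects at one release.
#' @param baseline named numeric vector of uninfected expression values
#'   (e.g. dcpm), used for list 2.
#' @param fold_change named numeric vector of linear fold changes
#'   (infected/control), used for list 2.
#' @param min_platforms minimum platform count for list 1 (default 2).
#' @param high_induction_fold fold cutoff for list 2 (default 20).
#' @param low_expression_quantile baseline quantile defining "low
#'   expression" (default 0.25 of non-zero baselines).
#' @return list with `multi_platform` and `low_expression_high_induction`.
#' @export
select_biomarkers <- function(datasets, baseline = NULL, fold_change = NULL,
                              min_platforms = 2, high_induction_fold = 20,
                              low_expression_quantile = 0.25) {
  stopifnot(min_platforms >= 2, high_induction_fold > 1)
  check_common_release(vapply(datasets, `[[`, "", "release"))
  ups <- lapply(datasets, `[[`, "up_set")
  tab <- table(unlist(ups))
  multi <- names(tab)[tab >= min_platforms]

  low_high <- character()
  if (!is.null(baseline) && !is.null(fold_change)) {
    nz <- baseline[!is.na(baseline) & baseline > 0]
    cutoff <- stats::quantile(nz, low_expression_quantile, type = 7, names = FALSE)
    common <- intersect(names(baseline), names(fold_change))
    b <- baseline[common]
    f <- fold_change[common]
    low_high <- common[!is.na(b) & !is.na(f) & b > 0 & b < cutoff &
                         f > high_induction_fold]
  }
  list(multi_platform = sort(multi),
       low_expression_high_induction = sort(low_high))
}

#' Peptide-length class analysis of up-regulated gene lists
#'
#' Encoded-protein lengths are divided into `n_classes` classes (equal-count
#' quantile boundaries over the all-transcript length distribution by
#' default, equal-width optionally); each gene list's percentage per class
#' is tabulated, and the short-peptide excess (< `short_cutoff_aa` residues)
#' between two groups of lists is tested with a 2x2 Pearson chi-square.
#'
#' @param up_sets named list of character vectors (gene ids per condition).
#' @param protein_lengths named numeric vector of protein lengths (aa) for
#'   the all-transcript universe; genes without a length are excluded.
#' @param n_classes number of length classes (default 5).
#' @param short_cutoff_aa cutoff in residues for the "short peptide" test
#'   (default 90).
#' @param equal_width use equal-width rather than equal-count classes.
#' @param group_a,group_b names of `up_sets` entries forming the two groups
#'   of the short-peptide test (e.g. fungal versus bacterial lists); omit
#'   either to skip the test.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `class_table` (data frame of per-list percentages per
#'   class, including an `all` reference row), `boundaries`, and `short_test`
#'   (htest or `NULL`).
#' @export
peptide_length_analysis <- function(up_sets, protein_lengths, n_classes = 5,
                                    short_cutoff_aa = 90, equal_width = FALSE,
                                    group_a = NULL, group_b = NULL,
                                    correct = FALSE) {
  protein_lengths <- protein_lengths[!is.na(protein_lengths)]
  if (length(protein_lengths) == 0) stop("all protein lengths missing")
  if (equal_width) {
    boundaries <- seq(min(protein_lengths), max(protein_lengths),
                      length.out = n_classes + 1)
  } else {
    boundaries <- stats::quantile(protein_lengths,
                                  seq(0, 1, length.out = n_classes + 1),
                                  type = 7, names = FALSE)
  }
  boundaries[1] <- -Inf
  boundaries[n_classes + 1] <- Inf
  # spiky length distributions can duplicate quantile boundaries; collapse
  boundaries <- unique(boundaries)
  n_eff <- length(boundaries) - 1
  classify <- function(len) {
    cut(len, breaks = boundaries, labels = FALSE, include.lowest = TRUE)
  }
  pct_per_class <- function(lens) {
    cls <- classify(lens)
    100 * tabulate(cls, nbins = n_eff) / length(cls)
  }
  rows <- c(list(all = pct_per_class(protein_lengths)),
            lapply(up_sets, function(ids) {
              lens <- protein_lengths[intersect(ids, names(protein_lengths))]
              if (length(lens) == 0) rep(NA_real_, n_eff)
              else pct_per_class(lens)
            }))
  class_table <- as.data.frame(do.call(rbind, rows))
  names(class_table) <- paste0("class_", seq_len(n_eff))

  short_test <- NULL
  if (!is.null(group_a) && !is.null(group_b)) {
    count_short <- function(groups) {
      ids <- unique(unlist(up_sets[groups]))
      lens <- protein_lengths[intersect(ids, names(protein_lengths))]
      c(short = sum(lens < short_cutoff_aa), long = sum(lens >= short_cutoff_aa))
    }
    tab <- rbind(a = count_short(group_a), b = count_short(group_b))
    short_test <- stats::chisq.test(tab, correct = correct)
  }
  list(class_table = class_table, boundaries = boundaries,
       short_test = short_test)
}

#' Conservation enrichment of an up-regulated gene set
#'
#' Compares the conserved fraction among up-regulated genes with the
#' conserved fraction among the remaining expressed genes, via a 2x2 Pearson
#' chi-square (no continuity correction by default).
#'
#' @param up_set,expressed_set,conserved_set character vectors;
#'   `up_set` must be a subset of `expressed_set`.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `table` (2x2 counts: up / expressed-not-up versus
#'   conserved / not), `conserved_fraction_up`,
#'   `conserved_fraction_expressed`, and `test` (htest).
#' @export
conservation_enrichment <- function(up_set, expressed_set, conserved_set,
                                    correct = FALSE) {
  up_set <- unique(up_set)
  expressed_set <- unique(expressed_set)
  if (length(up_set) == 0) stop("empty up_set")
  if (!all(up_set %in% expressed_set)) {
    stop("up_set must be a subset of expressed_set")
  }
  rest <- setdiff(expressed_set, up_set)
  tab <- rbind(
    up = c(conserved = sum(up_set %in% conserved_set),
           not_conserved = sum(!up_set %in% conserved_set)),
    expressed_not_up = c(sum(rest %in% conserved_set),
                         sum(!rest %in% conserved_set))
  )
  list(
    table = tab,
    conserved_fraction_up = tab["up", 1] / length(up_set),
    conserved_fraction_expressed = tab[2, 1] / max(length(rest), 1),
    test = stats::chisq.test(tab, correct = correct)
  )
}

#' Spearman correlation between two per-transcript expression tables
#'
#' Rank correlation of expression values for transcripts quantified on two
#' platforms (e.g. tiling array versus RNA-seq); transcripts missing on
#' either platform are dropped.
#'
#' @param table_a,table_b data frames `transcript_id`, `value`.
#' @return list with `rho` and `n` (transcripts compared).
#' @export
cross_platform_correlation <- function(table_a, table_b) {
  common <- intersect(table_a$transcript_id, table_b$transcript_id)
  a <- table_a$value[match(common, table_a$transcript_id)]
  b <- table_b$value[match(common, table_b$transcript_id)]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 transcripts in common")
  list(rho = stats::cor(a[ok], b[ok], method = "spearman"), n = sum(ok))
}
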