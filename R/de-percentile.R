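#' Percentile fold-change caller settings
#'
#' @param up_percentile percentile (within the positive log2 fold changes)
#'   above which a transcript is called up-regulated (default 81.25).
#' @param down_percentile percentile (within the negative log2 fold changes)
#'   below which a transcript is called down-regulated (default 18.75).
#' @param epsilon log2 fold changes within `[-epsilon, epsilon]` are treated
#'   as unchanged (default 1e-5).
#' @return list of class `percentile_config`.
#' @export
percentile_config <- function(up_percentile = 81.25, down_percentile = 18.75,
                              epsilon = 1e-5) {
  stopifnot(down_percentile > 0, up_percentile < 100,
            down_percentile < up_percentile, epsilon >= 0)
  structure(list(up_percentile = up_percentile,
                 down_percentile = down_percentile, epsilon = epsilon),
            class = "percentile_config")
}

#' Log2 fold changes with explicit zero handling
#'
#' Paired expression values with a zero on either side have no finite ratio;
#' rather than imputing an arbitrary small value, the status is recorded so
#' that downstream callers can exclude and flag these transcripts.
#'
#' @param pairs data frame `transcript_id`, `control`, `infected`
#'   (non-negative; `NA` allowed).
#' @return data frame `transcript_id`, `log2_fc`, `status` in
#'   `finite` / `plus_infinite` / `minus_infinite` / `undefined` / `missing`.
#' @export
log2_fold_changes <- function(pairs) {
  ctrl <- pairs$control
  inf <- pairs$infected
  if (any(ctrl < 0 | inf < 0, na.rm = TRUE)) stop("negative expression value")
  status <- rep("finite", nrow(pairs))
  status[is.na(ctrl) | is.na(inf)] <- "missing"
  status[!is.na(ctrl) & !is.na(inf) & ctrl == 0 & inf > 0] <- "plus_infinite"
  status[!is.na(ctrl) & !is.na(inf) & ctrl > 0 & inf == 0] <- "minus_infinite"
  status[!is.na(ctrl) & !is.na(inf) & ctrl == 0 & inf == 0] <- "undefined"
  fc <- ifelse(status == "finite", log2(inf / ctrl), NA_real_)
  data.frame(transcript_id = pairs$transcript_id, log2_fc = fc,
             status = status, stringsAsFactors = FALSE)
}

new_calls <- function(transcript_id, verdict, method, score, flag = "") {
  data.frame(transcript_id = transcript_id, verdict = verdict,
             method = method, score = score, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentile fold-change regulation caller
#'
#' Among transcripts whose log2 fold change exceeds `epsilon`, those strictly
#' above the `up_percentile`-th percentile (linear interpolation between
#' closest ranks, computed within that positive subset) are called up;
#' symmetrically, among fold changes below `-epsilon`, those strictly below
#' the `down_percentile`-th percentile of the negative subset are called
#' down.  Records with infinite or undefined fold changes are excluded from
#' the percentile computation and flagged in the output.
#'
#' @param fc data frame from [log2_fold_changes()].
#' @param config a [percentile_config()].
#' @return calls data frame: `transcript_id`, `verdict` (up/down/none),
#'   `method`, `score` (log2 fold change), `flag` (fold-change status for
#'   non-finite records).
#' @export
percentile_fc_call <- function(fc, config = percentile_config()) {
  finite <- fc[fc$status == "finite", , drop = FALSE]
  if (nrow(finite) == 0) {
    warning("no finite fold changes; no calls made")
  }
  verdict <- rep("none", nrow(fc))
  pos <- finite$log2_fc[finite$log2_fc > config$epsilon]
  if (length(pos)) {
    thr_up <- stats::quantile(pos, config$up_percentile / 100, type = 7,
                              names = FALSE)
    verdict[fc$status == "finite" & fc$log2_fc > config$epsilon &
              fc$log2_fc > thr_up] <- "up"
  }
  neg <- finite$log2_fc[finite$log2_fc < -config$epsilon]
  if (length(neg)) {
    thr_dn <- stats::quantile(neg, config$down_percentile / 100, type = 7,
                              names = FALSE)
    verdict[fc$status == "finite" & fc$log2_fc < -config$epsilon &
              fc$log2_fc < thr_dn] <- "down"
  }
  flag <- ifelse(fc$status == "finite", "", fc$status)
  new_calls(fc$transcript_id, verdict, "percentile", fc$log2_fc, flag)
}

#' Flag infection-specific and lost-on-infection transcripts
#'
#' Transcripts with no expression before infection but positive expression
#' after are the most infection-specific candidates; the mirror case is
#' expression lost on infection.  Transcripts at zero in both conditions are
#' not flagged.
#'
#' @param pairs data frame `transcript_id`, `control`, `infected`.
#' @return data frame `transcript_id`, `flag` in
#'   `infection_specific` / `lost_on_infection` / `none`.
#' @export
infection_specific <- function(pairs) {
  flag <- rep("none", nrow(pairs))
  flag[!is.na(pairs$control) & !is.na(pairs$infected) &
         pairs$control == 0 & pairs$infected > 0] <- "infection_specific"
  flag[!is.na(pairs$control) & !is.na(pairs$infected) &
         pairs$control > 0 & pairs$infected == 0] <- "lost_on_infection"
  data.frame(transcript_id = pairs$transcript_id, flag = flag,
             stringsAsFactors = FALSE)
}

#' Legacy oligo-array regulation caller
#'
#' Replicated two-colour oligo-array ratios are first filtered for
#' reproducibility: a gene is eligible when its normalized expression ratio
#' (infected/control) is beyond the no-change band (> `high` or < `low`) in
#' at least `n_required` of the arrays.  The uppermost `100 - down_percentile`
#' slice of eligible genes, ranked by their median ratio, is called up, and
#' the lowest slice down.
#'
#' @param ratios numeric matrix of expression ratios, genes in rows (rownames
#'   are gene ids), one column per array.
#' @param n_arrays expected array count (default 14); a different matrix
#'   width is an error unless `n_arrays` is set to match.
#' @param n_required minimum number of beyond-band arrays (default 10).
#' @param low,high the no-change ratio band (defaults 0.99 and 1.01).
#' @param config a [percentile_config()] supplying the percentile cutoffs.
#' @return calls data frame (eligible genes only); `score` is the median
#'   ratio.
#' @export
legacy_oligo_call <- function(ratios, n_arrays = 14, n_required = 10,
                              low = 0.99, high = 1.01,
                              config = percentile_config()) {
  ratios <- as.matrix(ratios)
  if (is.null(rownames(ratios))) stop("'ratios' must have gene ids as rownames")
  if (ncol(ratios) != n_arrays) {
    stop(sprintf("expected %d arrays, got %d (set n_arrays to override)",
                 n_arrays, ncol(ratios)))
  }
  beyond <- rowSums(ratios > high | ratios < low, na.rm = TRUE)
  eligible <- beyond >= n_required
  med <- apply(ratios[eligible, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  verdict <- rep("none", length(med))
  if (length(med)) {
    thr_up <- stats::quantile(med, config$up_percentile / 100, type = 7,
                              names = FALSE)
    thr_dn <- stats::quantile(med, config$down_percentile / 100, type = 7,
                              names = FALSE)
    verdict[med > thr_up] <- "up"
    verdict[med < thr_dn] <- "down"
  }
  new_calls(names(med), verdict, "oligo", unname(med))
}

#' Legacy cDNA-array regulation caller
#'
#' Two paired hybridization experiments in PSL units.  A gene above the
#' detection threshold in both experiments contributes the mean of its two
#' fold changes; above threshold in exactly one, that experiment's fold
#' change; in neither, the gene is excluded from the base set.  The log2
#' fold changes are then subjected to the percentile rule.
#'
#' @param set_I,set_II data frames `transcript_id`, `control`, `infected`
#'   (PSL units).
#' @param psl_threshold detection threshold in PSL (default 40); a gene is
#'   detected in an experiment when either condition exceeds it.
#' @param config a [percentile_config()].
#' @return calls data frame over the detected base set; `score` is the log2
#'   of the (mean) fold change.
#' @export
legacy_cdna_call <- function(set_I, set_II, psl_threshold = 40,
                             config = percentile_config()) {
  all_ids <- union(set_I$transcript_id, set_II$transcript_id)
  get <- function(set, ids) set[match(ids, set$transcript_id), , drop = FALSE]
  a <- get(set_I, all_ids)
  b <- get(set_II, all_ids)
  det_a <- !is.na(a$transcript_id) &
    (pmax(a$control, a$infected, na.rm = TRUE) > psl_threshold)
  det_b <- !is.na(b$transcript_id) &
    (pmax(b$control, b$infected, na.rm = TRUE) > psl_threshold)
  det_a[is.na(det_a)] <- FALSE
  det_b[is.na(det_b)] <- FALSE
  base <- det_a | det_b
  fc_a <- ifelse(det_a & a$control > 0, a$infected / a$control, NA)
  fc_b <- ifelse(det_b & b$control > 0, b$infected / b$control, NA)
  mean_fc <- rowMeans(cbind(fc_a, fc_b), na.rm = TRUE)
  mean_fc[!base] <- NA
  keep <- base & is.finite(mean_fc) & mean_fc > 0
  fc <- data.frame(transcript_id = all_ids[keep],
                   log2_fc = log2(mean_fc[keep]),
                   status = "finite", stringsAsFactors = FALSE)
  calls <- percentile_fc_call(fc, config)
  calls$method <- "cdna"
  calls
}
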