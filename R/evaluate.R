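#' Top-k up calls of a caller, ranked by score
#'
#' Callers differ in how many transcripts they call up; to compare their
#' error profiles fairly, each caller is truncated to its `k` strongest up
#' calls (largest score).
#'
#' @param calls a calls data frame (`transcript_id`, `verdict`, `score`).
#' @param k number of calls to keep.
#' @return character vector of transcript ids (length <= k).
#' @export
top_up_calls <- function(calls, k) {
  up <- calls[calls$verdict == "up" & !is.na(calls$score), , drop = FALSE]
  up <- up[order(-up$score), , drop = FALSE]
  utils::head(up$transcript_id, k)
}

#' Share of calls that are low-expression false positives
#'
#' Fraction of the called transcripts that sit in the lowest-baseline slice
#' of the data and are not truly up-regulated — the failure mode of naive
#' fold-change selection, since relative variation inflates at low
#' expression.
#'
#' @param called_ids character vector of called transcript ids.
#' @param truth truth data frame from [simulate_expression()]
#'   (`transcript_id`, `label`, `baseline`).
#' @param baseline_quantile slice boundary (default 0.1: the lowest decile).
#' @return fraction in `[0, 1]` of `called_ids` that are low-expression
#'   false positives.
#' @export
lowexpr_false_positive_share <- function(called_ids, truth,
                                         baseline_quantile = 0.1) {
  if (length(called_ids) == 0) return(0)
  cutoff <- stats::quantile(truth$baseline[!is.na(truth$baseline)],
                            baseline_quantile, type = 7, names = FALSE)
  idx <- match(called_ids, truth$transcript_id)
  is_low <- !is.na(truth$baseline[idx]) & truth$baseline[idx] <= cutoff
  is_fp <- truth$label[idx] != "up"
  sum(is_low & is_fp, na.rm = TRUE) / length(called_ids)
}
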