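# Hand-built release histories for targeted lineage tests.
#
# `live_sets` is a named list (release -> character vector of live wbids);
# every wbid ever mentioned appears in every release table, dead when not
# listed live.  Names are derived mechanically from the wbid.
toy_history <- function(live_sets, events = NULL) {
  releases <- names(live_sets)
  all_ids <- unique(unlist(live_sets))
  if (!is.null(events)) {
    all_ids <- unique(c(all_ids, unlist(strsplit(
      c(events$source_wbids, events$target_wbids), ","
    ))))
    all_ids <- all_ids[nzchar(all_ids)]
  }
  tables <- lapply(live_sets, function(live) {
    data.frame(
      wbid = all_ids,
      sequence_name = paste0("seq-", all_ids),
      public_name = paste0("pub-", all_ids),
      transcript_names = paste0("seq-", all_ids, ".1"),
      status = ifelse(all_ids %in% live, "live", "dead"),
      stringsAsFactors = FALSE
    )
  })
  release_history(releases, tables, events)
}

toy_events <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(effective_release = r[[1]], event_type = r[[2]],
               source_wbids = r[[3]], target_wbids = r[[4]],
               note = "", stringsAsFactors = FALSE)
  }))
}

# Independent brute-force pseudomedian: full enumeration of pairwise
# averages with i <= j.
pseudomedian_bruteforce <- function(x) {
  avgs <- c()
  for (i in seq_along(x)) {
    for (j in i:length(x)) {
      avgs <- c(avgs, (x[i] + x[j]) / 2)
    }
  }
  median(avgs)
}

# Independent upper-tail hypergeometric by explicit summation of
# choose() terms.
hyper_tail_bruteforce <- function(k, n, K, N) {
  if (k == 0) return(1)
  terms <- vapply(k:min(n, K), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, 0)
  sum(terms)
}

# Sorted final identifiers recorded by the history generator's truth map.
truth_final_ids <- function(truth) {
  sort(unique(unlist(strsplit(truth$final_ids[nzchar(truth$final_ids)], ","))))
}

expect_same_conversion <- function(a, b) {
  expect_setequal(a$output_wbids, b$output_wbids)
  expect_setequal(a$killed$wbid, b$killed$wbid)
  expect_setequal(a$merged$source, b$merged$source)
  expect_setequal(a$split_sources, b$split_sources)
  expect_setequal(a$passthrough, b$passthrough)
  expect_setequal(a$unresolved, b$unresolved)
}
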