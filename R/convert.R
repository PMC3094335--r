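#' Resolve heterogeneous gene identifiers at a release
#'
#' Published gene lists mix stable gene IDs, CDS/sequence names, public names
#' and transcript names.  Each input is tried, in fixed precedence order, as a
#' stable wbid, then a sequence name, then a public name, then a transcript
#' name (a transcript resolves to its parent gene).  Matching is
#' case-sensitive first; a case-insensitive fallback is attempted and logged
#' in the `match_kind` column.  Unresolved inputs are reported, never dropped.
#'
#' @param ids character vector of identifiers (any mix of kinds).
#' @param release release label at which to resolve.
#' @param history a [release_history()].
#' @return data frame with columns `input`, `wbid` (`NA` if unresolved),
#'   `match_kind` (`"wbid"`, `"sequence_name"`, `"public_name"`,
#'   `"transcript_name"`, each possibly suffixed `"/case-insensitive"`, or
#'   `NA`).
#' @export
resolve_identifiers <- function(ids, release, history) {
  if (length(ids) == 0) stop("empty input list")
  stopifnot(inherits(history, "release_history"))
  release_ordinal(history, release)
  tab <- history$tables[[release]]
  live <- tab[tab$status == "live", , drop = FALSE]

  tx <- split_ids(live$transcript_names)
  tx_parent <- rep(live$wbid, lengths(tx))
  tx_name <- unlist(tx, use.names = FALSE)

  lookup <- function(keys, values, query, exact = TRUE) {
    if (!exact) {
      keys <- tolower(keys)
      query <- tolower(query)
    }
    keep <- nzchar(keys)
    values[keep][match(query, keys[keep])]
  }

  layers <- list(
    wbid = function(q, exact) lookup(live$wbid, live$wbid, q, exact),
    sequence_name = function(q, exact) lookup(live$sequence_name, live$wbid, q, exact),
    public_name = function(q, exact) lookup(live$public_name, live$wbid, q, exact),
    transcript_name = function(q, exact) lookup(tx_name, tx_parent, q, exact)
  )

  wbid <- rep(NA_character_, length(ids))
  kind <- rep(NA_character_, length(ids))
  for (exact in c(TRUE, FALSE)) {
    for (layer in names(layers)) {
      todo <- is.na(wbid)
      if (!any(todo)) break
      hit <- layers[[layer]](ids[todo], exact)
      found <- !is.na(hit)
      wbid[todo][found] <- hit[found]
      kind[todo][found] <- if (exact) layer else paste0(layer, "/case-insensitive")
    }
  }
  data.frame(input = ids, wbid = wbid, match_kind = kind, stringsAsFactors = FALSE)
}

# Events strictly after `from` and up to `to`, in replay order.
events_between <- function(history, from, to) {
  ord <- match(history$events$effective_release, history$releases)
  i_from <- release_ordinal(history, from)
  i_to <- release_ordinal(history, to)
  history$events[ord > i_from & ord <= i_to, , drop = FALSE]
}

#' Convert a gene list between annotation releases
#'
#' Forward-replays every lineage event recorded after `from_release` and up to
#' `to_release` on each resolved input gene.  Merged genes map to the
#' surviving target (deduplicated: the output is a gene set); killed genes are
#' omitted from the output and reported with their release of death; genes
#' that were split have all their successor identifiers appended at the end of
#' the output list (event order, then lexicographic within an event).
#' Backward conversion is rejected: merges are not invertible.
#'
#' @param ids character vector of identifiers (any mix of kinds; see
#'   [resolve_identifiers()]).
#' @param from_release,to_release release labels, `from` ordinal <= `to`
#'   ordinal.
#' @param history a [release_history()].
#' @param output_format one of `"wbid"`, `"sequence_name"`, `"public_name"`.
#'   Gene-to-transcript output is not supported (a gene maps to several
#'   transcripts, so no faithful list conversion exists).
#' @return a list of class `conversion_report` with elements `output`
#'   (converted identifiers, rendered in `output_format`), `resolved`
#'   (input/wbid map), `unresolved`, `killed` (with release of death),
#'   `merged` (source/target map with the effective release), `split_added`,
#'   `passthrough` and `counts`.
#' @examples
#' h <- mini_history()
#' convert_list("R07E5.12", "WS150", "WS210", h, output_format = "sequence_name")
#' @export
convert_list <- function(ids, from_release, to_release, history,
                         output_format = c("wbid", "sequence_name", "public_name")) {
  output_format <- match.arg_transcript_guard(output_format)
  replay_engine(ids, from_release, to_release, history, output_format,
                engine = "batched")
}

#' Reference replayer for conversion equivalence testing
#'
#' Same contract as [convert_list()], implemented as a deliberately naive
#' per-gene scan over every event.  It exists solely as an independent second
#' route for equivalence testing of the batched replayer and is exported so
#' that users can cross-check conversions they find surprising.
#'
#' @inheritParams convert_list
#' @return as [convert_list()].
#' @export
replay_oracle <- function(ids, from_release, to_release, history,
                          output_format = c("wbid", "sequence_name", "public_name")) {
  output_format <- match.arg_transcript_guard(output_format)
  replay_engine(ids, from_release, to_release, history, output_format,
                engine = "pergene")
}

match.arg_transcript_guard <- function(output_format) {
  if (length(output_format) == 1 && identical(output_format, "transcript_name")) {
    stop("unsupported output format: a gene list cannot be converted to transcript names")
  }
  match.arg(output_format, c("wbid", "sequence_name", "public_name"))
}

replay_engine <- function(ids, from_release, to_release, history, output_format,
                          engine) {
  stopifnot(inherits(history, "release_history"))
  i_from <- release_ordinal(history, from_release)
  i_to <- release_ordinal(history, to_release)
  if (i_from > i_to) {
    stop("backward conversion (newer to older release) is not supported")
  }
  res <- resolve_identifiers(ids, from_release, history)
  ev <- events_between(history, from_release, to_release)
  genes <- res$wbid[!is.na(res$wbid)]
  genes <- genes[!duplicated(genes)]

  fates <- if (engine == "batched") {
    replay_batched(genes, ev)
  } else {
    lapply_fates_pergene(genes, ev)
  }
  assemble_report(ids, res, fates, ev, history, from_release, to_release,
                  output_format)
}

# Batched replay: one pass over events, vectorized over the tracked relation
# origin -> current identifier.
replay_batched <- function(genes, ev) {
  n <- length(genes)
  origin <- genes
  current <- genes
  alive <- rep(TRUE, n)
  merged_any <- stats::setNames(rep(FALSE, length(genes)), genes)
  split_any <- stats::setNames(rep(FALSE, length(genes)), genes)
  kill_release <- stats::setNames(rep(NA_character_, length(genes)), genes)
  merge_release <- stats::setNames(rep(NA_character_, length(genes)), genes)
  split_targets <- list()

  if (nrow(ev)) {
    src_l <- split_ids(ev$source_wbids)
    tgt_l <- split_ids(ev$target_wbids)
    for (k in seq_len(nrow(ev))) {
      type <- ev$event_type[k]
      if (type == "create" || type == "rename") next
      src <- src_l[[k]]
      if (type == "merge") {
        hit <- alive & current %in% src
        if (any(hit)) {
          current[hit] <- tgt_l[[k]][1]
          o_hit <- unique(origin[hit])
          merged_any[o_hit] <- TRUE
          first <- is.na(merge_release[o_hit])
          merge_release[o_hit[first]] <- ev$effective_release[k]
        }
      } else if (type == "split") {
        hit <- which(alive & current == src[1])
        if (length(hit)) {
          tgt <- sort(tgt_l[[k]])
          split_any[unique(origin[hit])] <- TRUE
          split_targets[[length(split_targets) + 1]] <- tgt
          origin <- c(origin[-hit], rep(origin[hit], each = length(tgt)))
          current <- c(current[-hit], rep(tgt, times = length(hit)))
          alive <- c(alive[-hit], rep(TRUE, length(hit) * length(tgt)))
        }
      } else if (type == "kill") {
        hit <- alive & current %in% src
        if (any(hit)) {
          alive[hit] <- FALSE
          kill_release[unique(origin[hit])] <- ev$effective_release[k]
        }
      } else if (type == "resurrect") {
        hit <- !alive & current %in% src
        alive[hit] <- TRUE
      }
    }
  }
  list(origin = origin, current = current, alive = alive,
       merged_any = merged_any, split_any = split_any,
       kill_release = kill_release, merge_release = merge_release,
       split_targets = unique(unlist(split_targets, use.names = FALSE)))
}

# Naive replay: each gene walks the full event list on its own.
lapply_fates_pergene <- function(genes, ev) {
  src_l <- split_ids(ev$source_wbids)
  tgt_l <- split_ids(ev$target_wbids)
  merged_any <- stats::setNames(rep(FALSE, length(genes)), genes)
  split_any <- stats::setNames(rep(FALSE, length(genes)), genes)
  kill_release <- stats::setNames(rep(NA_character_, length(genes)), genes)
  merge_release <- stats::setNames(rep(NA_character_, length(genes)), genes)
  origin <- character()
  current <- character()
  alive <- logical()
  all_split_targets <- character()

  for (g in genes) {
    ids_now <- g
    live_now <- TRUE
    for (k in seq_len(nrow(ev))) {
      type <- ev$event_type[k]
      if (type == "create" || type == "rename") next
      src <- src_l[[k]]
      if (type == "merge") {
        hit <- live_now & ids_now %in% src
        if (any(hit)) {
          ids_now[hit] <- tgt_l[[k]][1]
          merged_any[g] <- TRUE
          if (is.na(merge_release[g])) merge_release[g] <- ev$effective_release[k]
        }
      } else if (type == "split") {
        hit <- which(live_now & ids_now == src[1])
        if (length(hit)) {
          tgt <- sort(tgt_l[[k]])
          split_any[g] <- TRUE
          all_split_targets <- c(all_split_targets, tgt)
          ids_now <- c(ids_now[-hit], rep(tgt, times = length(hit)))
          live_now <- c(live_now[-hit], rep(TRUE, length(hit) * length(tgt)))
        }
      } else if (type == "kill") {
        hit <- live_now & ids_now %in% src
        if (any(hit)) {
          live_now[hit] <- FALSE
          kill_release[g] <- ev$effective_release[k]
        }
      } else if (type == "resurrect") {
        hit <- !live_now & ids_now %in% src
        live_now[hit] <- TRUE
      }
    }
    origin <- c(origin, rep(g, length(ids_now)))
    current <- c(current, ids_now)
    alive <- c(alive, live_now)
  }
  list(origin = origin, current = current, alive = alive,
       merged_any = merged_any, split_any = split_any,
       kill_release = kill_release, merge_release = merge_release,
       split_targets = unique(all_split_targets))
}

# Classify each input, assemble the output list and the change report.
assemble_report <- function(ids, res, fates, ev, history, from_release,
                            to_release, output_format) {
  genes <- names(fates$merged_any)
  surviving <- function(g) {
    idx <- fates$origin == g & fates$alive
    unique(fates$current[idx])
  }
  fate_of <- function(g) {
    ids_left <- surviving(g)
    if (length(ids_left) == 0) "killed"
    else if (fates$split_any[[g]]) "split"
    else if (fates$merged_any[[g]]) "merged"
    else "passthrough"
  }
  fate <- vapply(genes, fate_of, "")

  unresolved <- res$input[is.na(res$wbid)]
  killed <- data.frame(
    wbid = genes[fate == "killed"],
    release = unname(fates$kill_release[genes[fate == "killed"]]),
    stringsAsFactors = FALSE
  )
  merged_src <- genes[fate == "merged"]
  merged <- data.frame(
    source = merged_src,
    target = vapply(merged_src, function(g) surviving(g)[1], ""),
    release = unname(fates$merge_release[merged_src]),
    stringsAsFactors = FALSE
  )
  split_src <- genes[fate == "split"]
  passthrough <- genes[fate == "passthrough"]

  # Output: passthrough and merge targets in input order, then split
  # successors appended (event order, lexicographic within event), global
  # dedup because the output is a gene set.
  head_ids <- character()
  for (g in genes) {
    if (fate[[g]] == "passthrough") head_ids <- c(head_ids, g)
    else if (fate[[g]] == "merged") head_ids <- c(head_ids, merged$target[merged$source == g])
  }
  # surviving successors of split genes; ordered by split-event order (then
  # lexicographic), with successors renamed by later merges sorted last
  split_surv <- unique(fates$current[fates$alive & fates$origin %in% split_src])
  pos <- match(split_surv, fates$split_targets)
  split_out <- split_surv[order(is.na(pos), pos, split_surv)]
  out_wbids <- c(head_ids[!duplicated(head_ids)],
                 setdiff(split_out, head_ids))
  out_wbids <- out_wbids[!duplicated(out_wbids)]

  counts <- c(
    input = length(ids),
    unresolved = length(unresolved),
    killed = nrow(killed),
    merged = nrow(merged),
    split = length(split_src),
    passthrough = length(passthrough),
    output = length(out_wbids)
  )

  structure(
    list(
      output = render_format(out_wbids, history, to_release, output_format),
      output_wbids = out_wbids,
      resolved = res[!is.na(res$wbid), c("input", "wbid")],
      unresolved = unresolved,
      killed = killed,
      merged = merged,
      split_sources = split_src,
      split_added = setdiff(split_out, head_ids),
      passthrough = passthrough,
      counts = counts,
      from_release = from_release,
      to_release = to_release,
      output_format = output_format
    ),
    class = "conversion_report"
  )
}

render_format <- function(wbids, history, release, output_format) {
  if (output_format == "wbid") return(wbids)
  tab <- history$tables[[release]]
  vals <- tab[[output_format]][match(wbids, tab$wbid)]
  blank <- is.na(vals) | !nzchar(vals)
  vals[blank] <- wbids[blank]  # fall back to the stable id when unnamed
  vals
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("<conversion_report> ", x$counts[["input"]], " inputs -> ",
      x$counts[["output"]], " outputs (", x$output_format, ")\n", sep = "")
  cat(sprintf(
    "  passthrough %d | merged %d | split %d | killed %d | unresolved %d\n",
    x$counts[["passthrough"]], x$counts[["merged"]], x$counts[["split"]],
    x$counts[["killed"]], x$counts[["unresolved"]]
  ))
  invisible(x)
}

#' Detect the most likely source release of a gene list
#'
#' Publications often omit the annotation release their gene lists refer to.
#' Every release in the history is scored by the fraction of the input
#' identifiers that resolve there; the argmax is returned.  Ties are broken
#' toward the most recent release.
#'
#' @inheritParams resolve_identifiers
#' @return list with `release` (label) and `scores` (named numeric vector,
#'   fraction resolvable per release).
#' @export
detect_release <- function(ids, history) {
  if (length(ids) == 0) stop("empty input list")
  scores <- vapply(history$releases, function(rel) {
    mean(!is.na(resolve_identifiers(ids, rel, history)$wbid))
  }, 0)
  if (all(scores == 0)) {
    stop("no input identifier resolves in any release; cannot detect a source release")
  }
  best <- max(scores)
  winner <- history$releases[max(which(scores == best))]
  list(release = winner, scores = scores)
}

#' Write a conversion report to JSON and/or TSV
#'
#' The JSON form is machine-readable; the TSV form mirrors the three sections
#' a curator inspects: the output list, the change list (merges, splits,
#' kills with their releases), and the not-found list.
#'
#' @param report a `conversion_report` from [convert_list()].
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_conversion_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "conversion_report"))
  if (!is.null(json_path)) {
    payload <- list(
      output = report$output,
      counts = as.list(report$counts),
      merged = report$merged,
      split_sources = report$split_sources,
      split_added = report$split_added,
      killed = report$killed,
      unresolved = report$unresolved,
      to_release = report$to_release,
      output_format = report$output_format
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    on.exit(close(con))
    writeLines("# output list", con)
    writeLines(report$output, con)
    writeLines("# changes", con)
    if (nrow(report$merged)) {
      writeLines(paste("merge", report$merged$source, report$merged$target, sep = "\t"), con)
    }
    if (length(report$split_sources)) {
      writeLines(paste("split", report$split_sources, sep = "\t"), con)
    }
    if (nrow(report$killed)) {
      writeLines(paste("kill", report$killed$wbid, report$killed$release, sep = "\t"), con)
    }
    writeLines("# not found", con)
    writeLines(report$unresolved, con)
  }
  invisible(report)
}
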