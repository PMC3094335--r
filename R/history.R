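EVENT_TYPES <-c("merge", "split", "kill", "create", "rename", "resurrect")

#' Construct a release history
#'
#' A `release_history` bundles an ordered set of annotation releases, one
#' gene-identifier correspondence table per release, and the lineage events
#' (merges, splits, kills, creations, renames, resurrections) that transform
#' one release into the next.  It is the substrate for all identifier
#' conversion: conversion replays the events recorded between two releases.
#'
#' @param releases character vector of release labels in chronological order
#'   (e.g. `c("WS150", "WS152", "WS210")`).  The position in this vector is the
#'   release ordinal.
#' @param tables named list (one element per release, same order) of data
#'   frames with columns `wbid`, `sequence_name`, `public_name`,
#'   `transcript_names` (comma-joined), `status` (`"live"` or `"dead"`).
#' @param events data frame of lineage events with columns
#'   `effective_release`, `event_type`, `source_wbids` (comma-joined),
#'   `target_wbids` (comma-joined), `note`.  `effective_release` is the first
#'   release at which the change holds.
#' @param inconsistencies data frame describing load-time consistency
#'   violations (may be empty); see [load_history()].
#'
#' @return an object of class `release_history`.
#' @seealso [load_history()], [convert_list()], [simulate_history()]
#' @export
release_history <- function(releases, tables, events,
                            inconsistencies = empty_inconsistency_log()) {
  stopifnot(is.character(releases), length(releases) >= 1)
  if (anyDuplicated(releases)) {
    stop("release names must be unique")
  }
  if (!identical(sort(names(tables)), sort(releases))) {
    stop("'tables' must have exactly one entry per release")
  }
  tables <- tables[releases]
  tables <- lapply(tables, validate_gene_table)
  events <- validate_events(events, releases)
  structure(
    list(
      releases = releases,
      tables = tables,
      events = events,
      inconsistencies = inconsistencies
    ),
    class = "release_history"
  )
}

#' @export
print.release_history <- function(x, ...) {
  cat(sprintf(
    "<release_history> %d releases (%s .. %s), %d events, %d logged inconsistencies\n",
    length(x$releases), x$releases[1], x$releases[length(x$releases)],
    nrow(x$events), nrow(x$inconsistencies)
  ))
  invisible(x)
}

release_ordinal <- function(history, release) {
  ord <- match(release, history$releases)
  if (anyNA(ord)) {
    stop(sprintf("unknown release '%s'", paste(release[is.na(ord)], collapse = ", ")))
  }
  ord
}

validate_gene_table <- function(tab) {
  needed <- c("wbid", "sequence_name", "public_name", "transcript_names", "status")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("correspondence table lacks columns: ", paste(missing, collapse = ", "))
  }
  tab <- as.data.frame(tab)[needed]
  for (col in needed) tab[[col]] <- as.character(tab[[col]])
  tab$status <- tolower(tab$status)
  if (!all(tab$status %in% c("live", "dead"))) {
    stop("status must be 'live' or 'dead'")
  }
  if (any(!nzchar(tab$wbid))) stop("empty wbid in correspondence table")
  if (anyDuplicated(tab$wbid)) stop("duplicate wbid in correspondence table")
  live <- tab[tab$status == "live", ]
  for (col in c("sequence_name", "public_name")) {
    vals <- live[[col]][nzchar(live[[col]])]
    if (anyDuplicated(vals)) {
      stop(sprintf("live %s values must be unique within a release", col))
    }
  }
  tab
}

split_ids <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

join_ids <- function(x) vapply(x, paste, "", collapse = ",")

validate_events <- function(events, releases) {
  needed <- c("effective_release", "event_type", "source_wbids", "target_wbids")
  if (is.null(events) || nrow(as.data.frame(events)) == 0) {
    events <- data.frame(
      effective_release = character(), event_type = character(),
      source_wbids = character(), target_wbids = character(),
      note = character(), stringsAsFactors = FALSE
    )
    return(events)
  }
  events <- as.data.frame(events)
  missing <- setdiff(needed, names(events))
  if (length(missing)) {
    stop("event log lacks columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(events$note)) events$note <- ""
  for (col in c(needed, "note")) events[[col]] <- as.character(events[[col]])
  bad_type <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad_type)) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "))
  }
  bad_rel <- setdiff(unique(events$effective_release), releases)
  if (length(bad_rel)) {
    stop("event effective_release not in releases: ", paste(bad_rel, collapse = ", "))
  }
  src <- split_ids(events$source_wbids)
  tgt <- split_ids(events$target_wbids)
  ns <- lengths(src)
  nt <- lengths(tgt)
  ok <- switch_arity_ok(events$event_type, ns, nt)
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop(sprintf(
      "event %d ('%s') violates arity: %d source(s), %d target(s)",
      i, events$event_type[i], ns[i], nt[i]
    ))
  }
  # stable replay order: by release ordinal, then original row order
  ord <- order(match(events$effective_release, releases), seq_len(nrow(events)))
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  events
}

switch_arity_ok <- function(type, ns, nt) {
  (type == "merge" & ns >= 2 & nt == 1) |
    (type == "split" & ns == 1 & nt >= 2) |
    (type == "kill" & ns >= 1 & nt == 0) |
    (type == "create" & ns == 0 & nt >= 1) |
    (type == "rename" & ns == 1 & nt == 1) |
    (type == "resurrect" & ns == 1 & nt == 1)
}

empty_inconsistency_log <- function() {
  data.frame(
    release = character(), wbid = character(), problem = character(),
    repaired = logical(), stringsAsFactors = FALSE
  )
}

#' Load a release history from correspondence tables and an event log
#'
#' Reads one correspondence table per release plus a normalized lineage event
#' log, runs a consistency check (replaying all events must reproduce the
#' live/dead status recorded in each release table), and optionally repairs
#' violations with a patch file of manually curated events.  Annotation
#' databases occasionally retire a gene without a formal kill record; the
#' patch mechanism lets a curator declare the implied event so downstream
#' conversion stays exact.
#'
#' @param correspondence_paths named character vector of TSV paths, names are
#'   release labels, in chronological order.  Columns: `wbid`,
#'   `sequence_name`, `public_name`, `transcript_names`, `status`.
#' @param event_log_path TSV path with columns `effective_release`,
#'   `event_type`, `source_wbids`, `target_wbids`, `note`.
#' @param patch_path optional TSV of additional events (same schema) merged
#'   into the log before the consistency check.
#'
#' @return a [release_history()] whose `inconsistencies` element logs each
#'   status transition that no event explains; the `repaired` column marks
#'   violations that a patch event resolved.
#' @export
load_history <- function(correspondence_paths, event_log_path, patch_path = NULL) {
  if (is.null(names(correspondence_paths)) || any(!nzchar(names(correspondence_paths)))) {
    stop("'correspondence_paths' must be named by release")
  }
  releases <- names(correspondence_paths)
  tables <- lapply(correspondence_paths, read_tsv_checked)
  names(tables) <- releases
  events <- read_tsv_checked(event_log_path)
  base_inc <- find_inconsistencies(releases, tables, validate_events(events, releases))
  if (!is.null(patch_path)) {
    patches <- read_tsv_checked(patch_path)
    events <- rbind_events(events, patches)
  }
  events <- validate_events(events, releases)
  remaining <- find_inconsistencies(releases, tables, events)
  key <- function(d) paste(d$release, d$wbid, d$problem)
  repaired_keys <- setdiff(key(base_inc), key(remaining))
  log <- base_inc
  log$repaired <- key(log) %in% repaired_keys
  history <- release_history(releases, tables, events, inconsistencies = log)
  n_bad <- sum(!log$repaired)
  if (n_bad > 0) {
    warning(sprintf("%d unrepaired history inconsistencies logged", n_bad))
  }
  history
}

rbind_events <- function(a, b) {
  cols <- c("effective_release", "event_type", "source_wbids", "target_wbids", "note")
  a <- as.data.frame(a)
  b <- as.data.frame(b)
  if (is.null(a$note)) a$note <- ""
  if (is.null(b$note)) b$note <- ""
  rbind(a[cols], b[cols])
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                      na.strings = NULL, quote = ""),
    error = function(e) stop(sprintf("parse error in %s: %s", path, conditionMessage(e)))
  )
  out
}

#' Load a release history from a directory
#'
#' Convenience wrapper around [load_history()] for directories written by
#' [write_history()]: expects one `<release>.tsv` per release, `events.tsv`,
#' an optional `patch.tsv`, and a `releases.txt` manifest giving the release
#' order (release labels are matched to file names case-insensitively).
#'
#' @param dir directory path.
#' @return a [release_history()].
#' @export
load_history_dir <- function(dir) {
  manifest <- file.path(dir, "releases.txt")
  if (!file.exists(manifest)) {
    stop("no releases.txt manifest in ", dir)
  }
  releases <- readLines(manifest)
  releases <- trimws(releases[nzchar(trimws(releases))])
  paths <- file.path(dir, paste0(tolower(releases), ".tsv"))
  names(paths) <- releases
  patch <- file.path(dir, "patch.tsv")
  load_history(paths, file.path(dir, "events.tsv"),
               patch_path = if (file.exists(patch)) patch else NULL)
}

# Flag live->absent/dead transitions between consecutive releases that no
# kill/merge/split event at the later release explains.
find_inconsistencies <- function(releases, tables, events) {
  log <- empty_inconsistency_log()
  if (length(releases) < 2) return(log)
  rel_ev <- events[events$event_type %in% c("kill", "merge", "split"), , drop = FALSE]
  src_l <- split_ids(rel_ev$source_wbids)
  for (i in seq_len(length(releases) - 1)) {
    prev <- tables[[i]]
    nxt <- tables[[i + 1]]
    live_prev <- prev$wbid[prev$status == "live"]
    live_next <- nxt$wbid[nxt$status == "live"]
    gone <- setdiff(live_prev, live_next)
    explained <- unlist(src_l[rel_ev$effective_release == releases[i + 1]],
                        use.names = FALSE)
    unexplained <- setdiff(gone, explained)
    if (length(unexplained)) {
      log <- rbind(log, data.frame(
        release = releases[i + 1], wbid = unexplained,
        problem = "gene no longer live but no kill/merge/split event recorded",
        repaired = FALSE, stringsAsFactors = FALSE
      ))
    }
  }
  log
}
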