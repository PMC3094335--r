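#' EASE score and Fisher exact upper tail for a category
#'
#' The Fisher p-value is the upper-tail hypergeometric probability of
#' observing at least `k` category members in a list of size `n` drawn from
#' a population of `N` containing `K` category members.  The EASE score is
#' the same computation after removing one gene from the hit cell (margins
#' unchanged) — a jackknife-style penalization that deflates categories
#' supported by a single gene; with `k <= 1` the EASE score is 1 by
#' definition.  `ease_p >= fisher_p` always.
#'
#' @param k hits (list members in the category).
#' @param n list size.
#' @param K category size within the population.
#' @param N population size.
#' @return named list `ease_p`, `fisher_p`.
#' @export
ease_score <- function(k, n, K, N) {
  if (k > n || n > N || k > K || K > N || any(c(k, n, K, N) < 0)) {
    stop("invalid contingency margins: need k <= min(n, K) and n, K <= N")
  }
  fisher_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  ease_p <- if (k <= 1) 1 else {
    stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
  }
  list(ease_p = ease_p, fisher_p = fisher_p)
}

#' Category overrepresentation analysis of a gene list
#'
#' Scores every category of a database against a gene list drawn from a
#' base-set population, reporting the conservative EASE score alongside the
#' plain Fisher upper tail and a Benjamini-Hochberg adjusted q-value over
#' the tested categories (advisory).  Categories are intersected with the
#' base set first; those smaller than `min_category_size` after intersection
#' are skipped.
#'
#' @param gene_list character vector, subset of `base_set`.
#' @param base_set character vector: the population of detected genes.
#' @param db a [category_db()].
#' @param release optional release label of `gene_list`; if both this and
#'   `db$release` are known they must match (refresh the database with
#'   [refresh_categories()] otherwise).
#' @param min_category_size smallest category (after base-set intersection)
#'   tested (default 2).
#' @return data frame sorted by `ease_p`: `category`, `description`, `k`,
#'   `n`, `K`, `N`, `ease_p`, `fisher_p`, `adjusted_q`.
#' @export
enrich <- function(gene_list, base_set, db, release = NULL,
                   min_category_size = 2) {
  gene_list <- unique(gene_list)
  base_set <- unique(base_set)
  if (length(gene_list) == 0) stop("empty gene list")
  if (!all(gene_list %in% base_set)) {
    stop("gene_list must be a subset of base_set")
  }
  if (!is.null(release) && !is.na(db$release) && !identical(release, db$release)) {
    stop(sprintf(
      "gene list is %s but category database is %s; run refresh_categories() first",
      release, db$release
    ))
  }
  N <- length(base_set)
  n <- length(gene_list)
  rows <- lapply(names(db$categories), function(nm) {
    cat_genes <- intersect(db$categories[[nm]], base_set)
    K <- length(cat_genes)
    if (K < min_category_size) return(NULL)
    k <- length(intersect(cat_genes, gene_list))
    p <- ease_score(k, n, K, N)
    data.frame(category = nm, description = db$descriptions[[nm]],
               k = k, n = n, K = K, N = N,
               ease_p = p$ease_p, fisher_p = p$fisher_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no category intersects the base set at min_category_size")
  }
  out$adjusted_q <- stats::p.adjust(out$ease_p, method = "BH")
  out <- out[order(out$ease_p, -out$k), ]
  rownames(out) <- NULL
  out
}

#' Refresh a category database to a new annotation release
#'
#' Functional annotations culled from the literature go stale as gene
#' identifiers change; every category's gene set is converted with
#' [convert_list()], dropping killed genes (logged), deduplicating merge
#' survivors, and appending split successors.  Categories left empty are
#' flagged for removal and dropped.
#'
#' @param db a [category_db()] with a known `release`.
#' @param to_release target release label.
#' @param history a [release_history()] covering both releases.
#' @return list with `db` (refreshed [category_db()]) and `log` (data frame
#'   `category`, `change`, `detail`).
#' @export
refresh_categories <- function(db, to_release, history) {
  if (is.na(db$release)) stop("category database has no release tag")
  log <- list()
  note <- function(category, change, detail) {
    log[[length(log) + 1]] <<- data.frame(
      category = category, change = change, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  new_cats <- list()
  for (nm in names(db$categories)) {
    rep <- tryCatch(
      convert_list(db$categories[[nm]], db$release, to_release, history),
      error = function(e) {
        stop(sprintf("category '%s': %s", nm, conditionMessage(e)))
      }
    )
    for (i in seq_len(nrow(rep$killed))) {
      note(nm, "killed", sprintf("%s (at %s)", rep$killed$wbid[i],
                                 rep$killed$release[i]))
    }
    for (i in seq_len(nrow(rep$merged))) {
      note(nm, "merged", sprintf("%s -> %s", rep$merged$source[i],
                                 rep$merged$target[i]))
    }
    for (s in rep$split_sources) note(nm, "split", s)
    for (u in rep$unresolved) note(nm, "unresolved", u)
    if (length(rep$output_wbids) == 0) {
      note(nm, "emptied", "all genes killed or unresolved; category removed")
    } else {
      new_cats[[nm]] <- rep$output_wbids
    }
  }
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(category = character(), change = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(
    db = category_db(new_cats, db$descriptions[names(new_cats)], to_release),
    log = log_df
  )
}
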