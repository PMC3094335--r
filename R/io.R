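#' Read transcript models from a GFF3 file
#'
#' Imports `exon` features with their `mRNA` parents (and the mRNA's `gene`
#' parent where present) from a GFF3 subset via [rtracklayer::import()] and
#' returns the flat exon table used by the quantification functions.
#'
#' @param path GFF3 file with `gene`, `mRNA` and `exon` features; exons carry
#'   a `Parent` attribute naming their mRNA.
#' @return a `transcript_models` data frame: one row per exon, columns
#'   `transcript_id`, `gene_id`, `chrom`, `start` (0-based), `end`
#'   (half-open), `strand`.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- tolower(as.character(gr$type))
  mrna <- gr[feats %in% c("mrna", "transcript")]
  exons <- gr[feats == "exon"]
  if (length(exons) == 0) stop("no exon features in ", path)
  parent <- vapply(as.list(exons$Parent), function(p) {
    if (length(p) == 0) NA_character_ else sub("^Transcript:", "", p[[1]])
  }, "")
  mrna_ids <- sub("^Transcript:", "", as.character(mrna$ID))
  gene_of <- vapply(as.list(mrna$Parent), function(p) {
    if (length(p) == 0) NA_character_ else sub("^Gene:", "", p[[1]])
  }, "")
  gene_id <- gene_of[match(parent, mrna_ids)]
  gene_id[is.na(gene_id)] <- parent[is.na(gene_id)]
  out <- data.frame(
    transcript_id = parent,
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons) - 1L,
    end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$transcript_id, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("transcript_models", "data.frame")
  out
}

#' Read a per-base coverage track
#'
#' @param path TSV with columns `chrom`, `pos` (0-based), `score`,
#'   `representation`.
#' @return data frame with those columns, numeric where appropriate.
#' @export
read_coverage <- function(path) {
  cov <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "score", "representation")
  missing <- setdiff(needed, names(cov))
  if (length(missing)) stop("coverage lacks columns: ", paste(missing, collapse = ", "))
  cov$pos <- as.numeric(cov$pos)
  cov$score <- as.numeric(cov$score)
  cov$representation <- as.numeric(cov$representation)
  if (any(cov$representation < 1)) stop("representation values must be >= 1")
  cov
}

#' Read a tiling probe intensity table
#'
#' @param path TSV with columns `probe_id`, `chrom`, `start`, `end` and
#'   paired replicate intensity columns `pm_1..`, `mm_1..`.
#' @return data frame ready for [tiling_expression()].
#' @export
read_probes <- function(path) {
  probes <- utils::read.delim(path, stringsAsFactors = FALSE)
  pm <- grep("^pm_", names(probes))
  mm <- grep("^mm_", names(probes))
  if (length(pm) == 0 || length(pm) != length(mm)) {
    stop("probe table needs matching pm_*/mm_* columns")
  }
  probes
}

#' Read / write a gene list with a release header
#'
#' Gene-set files are one identifier per line; the first line may carry the
#' annotation release as `# release: WS210`.  Set algebra across data sets
#' refuses mixed releases, so the header travels with the list.
#'
#' @param path text file path.
#' @return for the reader, a list with `ids` (character) and `release`
#'   (label or `NA`).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  release <- NA_character_
  m <- grepl("^#\\s*release:", lines)
  if (any(m)) {
    release <- trimws(sub("^#\\s*release:", "", lines[which(m)[1]]))
  }
  ids <- trimws(lines[!grepl("^#", lines)])
  list(ids = ids[nzchar(ids)], release = release)
}

#' @rdname read_gene_list
#' @param ids character vector of identifiers.
#' @param release release label written to the header (optional).
#' @export
write_gene_list <- function(ids, path, release = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(release)) writeLines(paste0("# release: ", release), con)
  writeLines(ids, con)
  invisible(path)
}

#' Read / write a GMT-like category database
#'
#' One category per line: name, description, then tab-separated gene ids.
#' A leading `# release: <label>` header records the annotation release the
#' gene ids refer to.
#'
#' @param path GMT file path.
#' @return a `category_db` list with `categories` (named list of character
#'   vectors), `descriptions` (named character) and `release`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  release <- NA_character_
  m <- grepl("^#\\s*release:", lines)
  if (any(m)) release <- trimws(sub("^#\\s*release:", "", lines[which(m)[1]]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) without genes: ", paste(which(bad), collapse = ", "))
  categories <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(categories) <- vapply(parts, `[[`, "", 1)
  descriptions <- vapply(parts, `[[`, "", 2)
  names(descriptions) <- names(categories)
  category_db(categories, descriptions, release)
}

#' @rdname read_gmt
#' @param db a `category_db`.
#' @export
write_gmt <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(db$release)) writeLines(paste0("# release: ", db$release), con)
  for (nm in names(db$categories)) {
    writeLines(paste(c(nm, db$descriptions[[nm]], db$categories[[nm]]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Construct a category database
#'
#' @param categories named list of character vectors (gene ids); empty
#'   categories are rejected.
#' @param descriptions named character vector (defaults to category names).
#' @param release annotation release the gene ids refer to (`NA` if unknown).
#' @return list of class `category_db`.
#' @export
category_db <- function(categories, descriptions = NULL, release = NA_character_) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  if (any(lengths(categories) == 0)) stop("category gene sets must be non-empty")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(categories), names(categories))
  }
  structure(list(categories = categories,
                 descriptions = descriptions,
                 release = release),
            class = "category_db")
}

#' Read / write a paired expression table
#'
#' TSV with columns `transcript_id`, `control`, `infected`; missing values
#' are written as `nan` (a transcript whose dcpm denominator was zero, for
#' example).
#'
#' @param path TSV path.
#' @return data frame `transcript_id`, `control`, `infected` with `NA` for
#'   `nan` entries.
#' @export
read_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("nan", "NA", "NaN"))
  needed <- c("transcript_id", "control", "infected")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) stop("pairs table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$transcript_id)) stop("duplicate transcript_id")
  tab$control <- as.numeric(tab$control)
  tab$infected <- as.numeric(tab$infected)
  tab
}

#' @rdname read_pairs
#' @param pairs data frame `transcript_id`, `control`, `infected`.
#' @export
write_pairs <- function(pairs, path) {
  out <- pairs
  out$control <- ifelse(is.na(out$control), "nan", format(out$control, trim = TRUE))
  out$infected <- ifelse(is.na(out$infected), "nan", format(out$infected, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
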