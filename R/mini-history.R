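#' A six-release mini annotation history
#'
#' A small packaged history (releases WS150, WS152, WS210, WS216, WS217,
#' WS220; six genes) encoding two well-documented C. elegans gene merges:
#' R07E5.12 was merged into R07E5.10 effective WS152, and C03B8.1 was merged
#' into C03B8.3 effective WS217.  Useful for examples and as a smoke test of
#' the loader and converter.
#'
#' @return a [release_history()] loaded from the TSV fixtures shipped under
#'   `inst/extdata/mini_history`.
#' @examples
#' h <- mini_history()
#' convert_list("C03B8.1", "WS216", "WS220", h, output_format = "sequence_name")
#' @export
mini_history <- function() {
  dir <- system.file("extdata", "mini_history", package = "wormbridge",
                     mustWork = TRUE)
  releases <- c("WS150", "WS152", "WS210", "WS216", "WS217", "WS220")
  paths <- file.path(dir, paste0(tolower(releases), ".tsv"))
  names(paths) <- releases
  load_history(paths, file.path(dir, "events.tsv"))
}
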