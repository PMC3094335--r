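test_that("mini history loads cleanly and encodes the documented merges", {
  h <- mini_history()
  expect_s3_class(h, "release_history")
  expect_equal(nrow(h$events), 2)
  expect_equal(nrow(h$inconsistencies), 0)
})

test_that("event arity is validated at load", {
  lv <- list(A = c("g1", "g2"), B = c("g1", "g2"))
  bad <- toy_events(list("B", "merge", "g1", "g2"))  # merge needs >= 2 sources
  expect_error(toy_history(lv, bad), "arity")
  expect_error(
    toy_history(lv, toy_events(list("B", "teleport", "g1", "g2"))),
    "unknown event_type"
  )
})

test_that("an informal gene retirement is logged and repairable via a patch", {
  dir <- withr::local_tempdir()
  write_tab <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  mk <- function(status_g1) data.frame(
    wbid = c("g1", "g2"), sequence_name = c("seq-g1", "seq-g2"),
    public_name = c("pub-g1", "pub-g2"),
    transcript_names = c("seq-g1.1", "seq-g2.1"),
    status = c(status_g1, "live"), stringsAsFactors = FALSE
  )
  paths <- c(A = write_tab(mk("live"), "a.tsv"), B = write_tab(mk("dead"), "b.tsv"))
  ev <- write_tab(data.frame(effective_release = character(),
                             event_type = character(), source_wbids = character(),
                             target_wbids = character(), note = character()),
                  "events.tsv")
  # without a patch: one unrepaired inconsistency, warned about
  expect_warning(h0 <- load_history(paths, ev), "unrepaired")
  expect_equal(sum(!h0$inconsistencies$repaired), 1)
  # with a patch declaring the implied kill: repaired, no warning
  patch <- write_tab(data.frame(effective_release = "B", event_type = "kill",
                                source_wbids = "g1", target_wbids = "",
                                note = "implied kill"), "patch.tsv")
  expect_no_warning(h1 <- load_history(paths, ev, patch))
  expect_equal(nrow(h1$inconsistencies), 1)
  expect_true(all(h1$inconsistencies$repaired))
  expect_equal(nrow(h1$events), 1)
})

test_that("identifiers resolve by kind with fixed precedence", {
  h <- mini_history()
  r <- resolve_identifiers("R07E5.12", "WS150", h)
  expect_equal(r$wbid, "WBGene00000001")
  expect_equal(r$match_kind, "sequence_name")

  mixed <- resolve_identifiers(
    c("WBGene00000005", "C03B8.1", "lys-7", "R07E5.10a"), "WS150", h
  )
  expect_equal(mixed$wbid,
               c("WBGene00000005", "WBGene00000003",
                 "WBGene00000006", "WBGene00000002"))
  expect_equal(mixed$match_kind[4], "transcript_name")

  expect_true(is.na(resolve_identifiers("no-such-gene-1", "WS150", h)$wbid))
  expect_error(resolve_identifiers(character(), "WS150", h), "empty")
})

test_that("case-insensitive resolution is a logged fallback", {
  h <- mini_history()
  r <- resolve_identifiers("r07e5.12", "WS150", h)
  expect_equal(r$wbid, "WBGene00000001")
  expect_match(r$match_kind, "case-insensitive")
})

test_that("the documented merges convert forward correctly", {
  h <- mini_history()
  r1 <- convert_list("R07E5.12", "WS150", "WS210", h,
                     output_format = "sequence_name")
  expect_equal(r1$output, "R07E5.10")
  expect_equal(r1$merged$release, "WS152")

  r2 <- convert_list("C03B8.1", "WS216", "WS220", h,
                     output_format = "sequence_name")
  expect_equal(r2$output, "C03B8.3")
  expect_equal(r2$merged$release, "WS217")

  # the merge is invisible when converting before it happened
  r3 <- convert_list("C03B8.1", "WS150", "WS216", h,
                     output_format = "sequence_name")
  expect_equal(r3$output, "C03B8.1")
  expect_equal(nrow(r3$merged), 0)
})

test_that("identity conversion returns the list unchanged with an empty report", {
  h <- mini_history()
  ids <- c("WBGene00000005", "WBGene00000006", "WBGene00000002")
  r <- convert_list(ids, "WS210", "WS210", h)
  expect_identical(r$output, ids)
  expect_equal(nrow(r$merged), 0)
  expect_equal(nrow(r$killed), 0)
  expect_length(r$split_added, 0)
})

test_that("killed genes are omitted from output and reported with their release", {
  lv <- list(A = c("g1", "g2"), B = c("g2"))
  h <- toy_history(lv, toy_events(list("B", "kill", "g1", "")))
  r <- convert_list(c("g1", "g2"), "A", "B", h)
  expect_equal(r$output, "g2")
  expect_equal(r$killed, data.frame(wbid = "g1", release = "B",
                                    stringsAsFactors = FALSE))
})

test_that("split successors are appended at the end of the output", {
  lv <- list(A = c("g1", "g2"), B = c("g2", "g3", "g4"))
  h <- toy_history(lv, toy_events(list("B", "split", "g1", "g4,g3")))
  r <- convert_list(c("g1", "g2"), "A", "B", h)
  expect_equal(r$output, c("g2", "g3", "g4"))  # successors last, sorted
  expect_equal(r$split_sources, "g1")
  expect_setequal(r$split_added, c("g3", "g4"))
})

test_that("chained merges follow the surviving identifier", {
  lv <- list(A = c("a", "b", "c", "d"), B = c("c", "d"), C = c("e"))
  h <- toy_history(lv, toy_events(
    list("B", "merge", "a,b", "c"),
    list("C", "merge", "c,d", "e")
  ))
  r <- convert_list("a", "A", "C", h)
  expect_equal(r$output, "e")
  o <- replay_oracle("a", "A", "C", h)
  expect_equal(o$output, "e")
})

test_that("unsupported directions and formats are rejected", {
  h <- mini_history()
  expect_error(convert_list("R07E5.10", "WS210", "WS150", h), "backward")
  expect_error(convert_list("R07E5.10", "WS150", "WS210", h,
                            output_format = "transcript_name"),
               "transcript")
  expect_error(convert_list("R07E5.10", "WS150", "WS999", h), "unknown release")
})

test_that("release detection scores resolvability and prefers recency on ties", {
  h <- mini_history()
  # R07E5.12 resolves only in WS150, where every input resolves
  d <- detect_release(c("R07E5.12", "F08G5.6", "lys-7"), h)
  expect_equal(d$release, "WS150")
  expect_equal(unname(d$scores["WS150"]), 1)
  expect_lt(max(d$scores[-1]), 1)
  # stable names resolve everywhere: tie broken toward the newest release
  expect_equal(detect_release(c("F08G5.6", "lys-7"), h)$release, "WS220")
  expect_error(detect_release(character(), h), "empty")
  expect_error(detect_release(c("nope-1", "nope-2"), h), "detect")
})

test_that("conversion accounting partitions the input on random histories", {
  for (seed in 1:8) {
    sim <- simulate_history(history_sim_config(
      n_genes = 40, n_releases = 5,
      merge_rate = 0.05, split_rate = 0.03, kill_rate = 0.05,
      create_rate = 0.03, rename_rate = 0.03, seed = seed
    ))
    h <- sim$history
    from <- h$releases[1]
    to <- h$releases[length(h$releases)]
    ids <- sim$truth$origin
    r <- convert_list(ids, from, to, h)
    counts <- r$counts
    expect_equal(
      counts[["input"]],
      counts[["unresolved"]] + counts[["killed"]] + counts[["merged"]] +
        counts[["split"]] + counts[["passthrough"]]
    )
    expect_equal(
      counts[["output"]],
      length(unique(c(r$passthrough, r$merged$target))) + length(r$split_added)
    )
    # every output id is live in the target release
    tab <- h$tables[[to]]
    expect_true(all(tab$status[match(r$output_wbids, tab$wbid)] == "live"))
  }
})

test_that("batched conversion, naive oracle and truth map agree", {
  for (seed in 11:30) {
    sim <- simulate_history(history_sim_config(
      n_genes = 50, n_releases = 6,
      merge_rate = 0.04, split_rate = 0.02, kill_rate = 0.04,
      create_rate = 0.02, rename_rate = 0.02, resurrect_rate = 0.01,
      seed = seed
    ))
    h <- sim$history
    from <- h$releases[1]
    to <- h$releases[length(h$releases)]
    a <- convert_list(sim$truth$origin, from, to, h)
    b <- replay_oracle(sim$truth$origin, from, to, h)
    expect_same_conversion(a, b)
    expect_identical(sort(a$output_wbids), truth_final_ids(sim$truth))
    # report partition matches the generator's per-gene fates
    for (f in c("killed", "merged", "split", "passthrough")) {
      expected <- sim$truth$origin[sim$truth$fate == f]
      got <- switch(f, killed = a$killed$wbid, merged = a$merged$source,
                    split = a$split_sources, passthrough = a$passthrough)
      expect_setequal(got, expected)
    }
  }
})

test_that("stepwise conversion composes and losses are monotone", {
  for (seed in 41:48) {
    sim <- simulate_history(history_sim_config(
      n_genes = 40, n_releases = 6,
      merge_rate = 0.05, split_rate = 0.03, kill_rate = 0.05,
      create_rate = 0.02, rename_rate = 0.02, resurrect_rate = 0,
      seed = seed
    ))
    h <- sim$history
    rels <- h$releases
    mid <- rels[3]
    last <- rels[length(rels)]
    ids <- sim$truth$origin
    direct <- convert_list(ids, rels[1], last, h)
    step1 <- convert_list(ids, rels[1], mid, h)
    step2 <- convert_list(step1$output_wbids, mid, last, h)
    expect_setequal(step2$output_wbids, direct$output_wbids)
    # kills accumulate: everything dead by the midpoint stays dead
    expect_true(all(step1$killed$wbid %in% direct$killed$wbid))
  }
})

test_that("conversion reports serialize to JSON and TSV", {
  h <- mini_history()
  r <- convert_list(c("R07E5.12", "F08G5.6"), "WS150", "WS210", h)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_conversion_report(r, json_path = jp, tsv_path = tp)
  parsed <- jsonlite::read_json(jp)
  expect_equal(unlist(parsed$output),
               c("WBGene00000002", "WBGene00000005"))
  expect_true(any(grepl("^merge\t", readLines(tp))))
})
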