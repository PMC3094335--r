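test_that("platform base-set rules apply exactly", {
  # RNA-seq: non-zero dcpm in at least one data set
  d1 <- data.frame(transcript_id = c("a", "b", "c"), value = c(0, 2, NA))
  d2 <- data.frame(transcript_id = c("a", "b", "c"), value = c(0, 0, 1))
  expect_setequal(build_base_set("rnaseq", list(d1, d2)), c("b", "c"))

  # oligo: >= 2x background, unflagged, in >= 4 of 6 arrays
  genes <- c("in4of6", "weak", "flagged")
  sig <- matrix(10, nrow = 3, ncol = 6, dimnames = list(genes, NULL))
  bg <- matrix(5, nrow = 3, ncol = 6, dimnames = list(genes, NULL))
  sig["in4of6", 5:6] <- 1       # still 4 passing arrays
  bg["weak", ] <- 5.3           # 1.9x background everywhere
  flagged <- matrix(FALSE, 3, 6, dimnames = list(genes, NULL))
  flagged["flagged", 1:3] <- TRUE  # only 3 unflagged passes left
  expect_equal(
    build_base_set("oligo", list(signal = sig, background = bg, flagged = flagged)),
    "in4of6"
  )

  # cdna: > 40 PSL in either condition in >= 1 experiment
  e1 <- data.frame(transcript_id = c("hi", "lo"), control = c(50, 30),
                   infected = c(20, 35))
  e2 <- data.frame(transcript_id = c("hi", "lo"), control = c(45, 38),
                   infected = c(90, 39))
  expect_equal(build_base_set("cdna", list(e1, e2)), "hi")

  # tiling: everything
  expect_setequal(
    build_base_set("tiling", data.frame(transcript_id = c("x", "y"))),
    c("x", "y")
  )
})

test_that("platform datasets enforce subset and disjointness invariants", {
  expect_error(platform_dataset("rnaseq", "WS210", c("a", "b"), "c", character()),
               "subsets")
  expect_error(platform_dataset("rnaseq", "WS210", c("a", "b"), "a", "a"),
               "overlap")
  ds <- platform_dataset("rnaseq", "WS210", c("a", "b", "c"), "a", "b")
  expect_s3_class(ds, "platform_dataset")
})

test_that("venn regions partition the union", {
  r <- venn_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  counts <- setNames(r$regions$count, r$regions$region)
  expect_equal(unname(counts[c("A", "B", "A&B")]), c(1, 1, 2))
  expect_equal(sum(r$regions$count), r$union_size)
  expect_equal(r$pairwise$intersection, 2)
  expect_equal(r$pairwise$pct_of_a, 100 * 2 / 3)

  disjoint <- venn_counts(list(A = c("1"), B = c("2"), C = c("3")))
  multi <- grepl("&", disjoint$regions$region)
  expect_true(all(disjoint$regions$count[multi] == 0))
})

test_that("five-set venn counts match exhaustive membership enumeration", {
  set.seed(31)
  sets <- lapply(1:5, function(i) sample(as.character(1:60), 25))
  names(sets) <- LETTERS[1:5]
  r <- venn_counts(sets)
  universe <- unique(unlist(sets))
  # brute force: classify every element by its exact membership pattern
  expected <- table(vapply(universe, function(el) {
    paste(names(sets)[vapply(sets, function(s) el %in% s, TRUE)], collapse = "&")
  }, ""))
  got <- setNames(r$regions$count, r$regions$region)
  for (region in names(expected)) {
    expect_equal(unname(got[region]), unname(expected[region]))
  }
  expect_equal(sum(r$regions$count), length(universe))
})

test_that("set algebra refuses mixed releases", {
  expect_error(venn_counts(list(A = "1", B = "2"), releases = c("WS150", "WS210")),
               "different releases")
  expect_error(
    shared_and_specific(list(A = "1", B = "2"),
                        list(x = list(all_of = c("A", "B"))),
                        releases = c("WS150", "WS210")),
    "different releases"
  )
})

test_that("combination specs evaluate as set algebra", {
  sets <- list(fungus1 = c("a", "b", "c"), fungus2 = c("b", "c", "d"),
               bact1 = c("c", "e"), bact2 = c("f"))
  out <- shared_and_specific(sets, list(
    all_four = list(all_of = names(sets)),
    both_fungi = list(all_of = c("fungus1", "fungus2")),
    fungi_not_bacteria = list(all_of = c("fungus1", "fungus2"),
                              none_of = c("bact1", "bact2"))
  ))
  expect_equal(out$all_four, character())
  expect_setequal(out$both_fungi, c("b", "c"))
  expect_equal(out$fungi_not_bacteria, "b")   # c is also bacterial
  single <- shared_and_specific(list(only = c("x", "y")),
                                list(self = list(all_of = "only")))
  expect_setequal(single$self, c("x", "y"))
  expect_error(shared_and_specific(sets, list()), "empty")
})

test_that("biomarker list 1 is the multi-platform intersection", {
  mk <- function(platform, up) {
    platform_dataset(platform, "WS210",
                     base_set = c("g1", "g2", "g3", "g4"), up_set = up,
                     down_set = character())
  }
  ds <- list(mk("cdna", c("g1", "g2")), mk("tiling", c("g1", "g3")),
             mk("rnaseq", c("g1", "g2")))
  expect_equal(select_biomarkers(ds, min_platforms = 3)$multi_platform, "g1")
  two <- select_biomarkers(ds, min_platforms = 2)$multi_platform
  expect_setequal(two, c("g1", "g2"))   # g3 is up on a single platform
  # monotone shrinkage in min_platforms
  expect_true(all(select_biomarkers(ds, min_platforms = 3)$multi_platform %in% two))
})

test_that("biomarker list 2 needs both low baseline and strong induction", {
  ds <- list(
    platform_dataset("rnaseq", "WS210", sprintf("g%d", 1:8),
                     c("g1", "g2"), character()),
    platform_dataset("tiling", "WS210", sprintf("g%d", 1:8),
                     c("g1", "g3"), character())
  )
  baseline <- setNames(c(0.1, 0.2, 50, 60, 70, 80, 90, 100), sprintf("g%d", 1:8))
  fold <- setNames(c(25, 19, 25, 2, 2, 2, 2, 2), sprintf("g%d", 1:8))
  out <- select_biomarkers(ds, baseline, fold)
  expect_equal(out$low_expression_high_induction, "g1")  # g2 fails fold,
  # g3 fails the low-expression condition despite 25-fold induction
})

test_that("peptide classes are quintiles and sum to 100%", {
  lens <- setNames(1:100, sprintf("g%03d", 1:100))
  res <- peptide_length_analysis(list(some = sprintf("g%03d", 1:10)), lens)
  expect_equal(unname(unlist(res$class_table["all", ])), rep(20, 5))
  expect_equal(sum(res$class_table["some", ]), 100)
  # interior boundaries near 20/40/60/80 for uniform lengths
  expect_equal(res$boundaries[2:5], c(20.8, 40.6, 60.4, 80.2))
})

test_that("the short-peptide chi-square equals the Pearson formula", {
  # group a: 30 short of 100; group b: 10 short of 100
  lens <- setNames(c(40 + (1:40), 150 + (1:160)), sprintf("g%03d", 1:200))
  a_ids <- sprintf("g%03d", c(1:30, 41:110))    # 30 short + 70 long
  b_ids <- sprintf("g%03d", c(31:40, 111:200))  # 10 short + 90 long
  res <- peptide_length_analysis(list(a = a_ids, b = b_ids), lens,
                                 group_a = "a", group_b = "b")
  tab <- rbind(c(30, 70), c(10, 90))
  expected <- sum((tab - outer(rowSums(tab), colSums(tab)) / sum(tab))^2 /
                    (outer(rowSums(tab), colSums(tab)) / sum(tab)))
  expect_equal(unname(res$short_test$statistic), expected)
  expect_equal(res$short_test$parameter[["df"]], 1)

  # identical proportions: statistic 0
  same <- peptide_length_analysis(list(a = a_ids, b = a_ids), lens,
                                  group_a = "a", group_b = "b")
  expect_equal(unname(same$short_test$statistic), 0)
  expect_error(peptide_length_analysis(list(a = a_ids), setNames(NA_real_, "g001")),
               "missing")
})

test_that("conservation enrichment builds the right 2x2 table", {
  up <- sprintf("u%03d", 1:100)        # 5% conserved
  rest <- sprintf("r%03d", 1:900)      # 20% conserved
  conserved <- c(up[1:5], rest[1:180])
  res <- conservation_enrichment(up, c(up, rest), conserved)
  expect_equal(unname(res$table["up", ]), c(5, 95))
  expect_equal(unname(res$table[2, ]), c(180, 720))
  expect_equal(res$conserved_fraction_up, 0.05)
  expect_equal(res$conserved_fraction_expressed, 0.2)
  tab <- res$table
  expected <- sum((tab - outer(rowSums(tab), colSums(tab)) / sum(tab))^2 /
                    (outer(rowSums(tab), colSums(tab)) / sum(tab)))
  expect_equal(unname(res$test$statistic), expected)

  flat <- conservation_enrichment(up, c(up, rest), c(up[1:10], rest[1:90]))
  expect_equal(unname(flat$test$statistic), 0)
  expect_error(conservation_enrichment(c("zz"), up, conserved), "subset")
  expect_error(conservation_enrichment(character(), up, conserved), "empty")
})

test_that("cross-platform correlation matches a rank-based oracle", {
  set.seed(32)
  n <- 200
  a <- data.frame(transcript_id = sprintf("t%03d", 1:n),
                  value = rlnorm(n))
  b <- data.frame(transcript_id = sprintf("t%03d", 1:n),
                  value = a$value * exp(rnorm(n, 0, 0.3)))
  got <- cross_platform_correlation(a, b)
  # oracle: Pearson correlation of the rank vectors
  expect_equal(got$rho, cor(rank(a$value), rank(b$value)))
  expect_equal(got$n, n)
  expect_error(cross_platform_correlation(a[1:2, ], b[1:2, ]), "fewer than 3")
})
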