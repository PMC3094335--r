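test_that("PM - MM differencing is elementwise and keeps negatives", {
  pm <- matrix(c(100, 20, 7, 50, 60, 70), nrow = 3)
  mm <- matrix(c(30, 50, 2, 10, 10, 10), nrow = 3)
  expect_equal(pm_mm_difference(pm, mm), pm - mm)
  expect_equal(pm_mm_difference(100, 30)[1, 1], 70)
  expect_equal(pm_mm_difference(20, 50)[1, 1], -30)
  expect_error(pm_mm_difference(pm, mm[, 1, drop = FALSE]), "mismatch")
})

test_that("quantile normalization equalizes sorted columns", {
  out <- quantile_normalize(cbind(c(1, 3, 5), c(2, 4, 8)))
  # mean-of-order-statistics by hand: (1+2)/2, (3+4)/2, (5+8)/2
  expect_equal(out[, 1], c(1.5, 3.5, 6.5))
  expect_equal(out[, 2], c(1.5, 3.5, 6.5))

  same <- cbind(c(2, 9, 4), c(2, 9, 4))
  expect_equal(quantile_normalize(same), same)

  set.seed(1)
  x <- matrix(rnorm(300), ncol = 3)
  qn <- quantile_normalize(x)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_equal(sort(qn[, 2]), sort(qn[, 3]))
  expect_equal(sum(qn), sum(x))                  # total mass conserved
  expect_equal(order(qn[, 2]), order(x[, 2]))    # ranks preserved
  expect_error(quantile_normalize(x[, 1, drop = FALSE]), "2 columns")
})

test_that("pseudomedian matches full pairwise-average enumeration", {
  expect_equal(pseudomedian(c(1, 2, 3)), 2)       # averages {1,1.5,2,2,2.5,3}
  expect_equal(pseudomedian(c(0, 0, 10)), 2.5)    # averages {0,0,0,5,5,10}
  expect_equal(pseudomedian(7), 7)                # self-pair only
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(sample(2:12, 1))
    expect_equal(pseudomedian(x), pseudomedian_bruteforce(x))
  }
  # symmetric sample: pseudomedian at the centre
  expect_equal(pseudomedian(c(-3, -1, 0, 1, 3) + 10), 10)
})

test_that("pseudomedian smoothing windows probes by centre distance", {
  pos <- c(0, 30, 60, 300)
  val <- c(1, 2, 3, 50)
  # window 110: probes within +-55bp of each centre
  sm <- pseudomedian_smooth(val, pos, 110)
  expect_equal(sm[1], pseudomedian(c(1, 2)))
  expect_equal(sm[2], pseudomedian(c(1, 2, 3)))
  expect_equal(sm[3], pseudomedian(c(2, 3)))
  expect_equal(sm[4], 50)                          # isolated probe
  # degenerate window: every probe keeps its own value
  expect_equal(pseudomedian_smooth(val, pos, 1e-9), val)
  # brute-force window construction on random layouts
  set.seed(3)
  p <- sort(runif(40, 0, 500))
  v <- rnorm(40)
  sm <- pseudomedian_smooth(v, p, 110)
  for (i in c(1, 7, 20, 40)) {
    inwin <- abs(p - p[i]) <= 55
    expect_equal(sm[i], pseudomedian_bruteforce(v[inwin]))
  }
})

test_that("probes qualify for a transcript by summed exon overlap", {
  # exons [100,200) and [240,340); probe length 50 (or 100 when straddling)
  es <- c(100, 240)
  ee <- c(200, 340)
  cfg <- tiling_config()
  # probe fully inside (value 4); probes at 40% overlap excluded
  val <- transcript_expression_from_probes(
    probe_start = c(120, 70, 200), probe_end = c(170, 120, 250),
    smoothed = c(4, 100, 100), exon_start = es, exon_end = ee, config = cfg
  )
  expect_equal(val, 4)
  # median over qualifying probes
  val <- transcript_expression_from_probes(
    probe_start = c(120, 130, 140), probe_end = c(170, 180, 190),
    smoothed = c(2, 4, 6), exon_start = es, exon_end = ee, config = cfg
  )
  expect_equal(val, 4)
  # probe straddling the intron: 10bp in exon 1 + 50bp in exon 2 = 60% of 100bp
  frac_probe <- transcript_expression_from_probes(
    probe_start = 190, probe_end = 290, smoothed = 9,
    exon_start = es, exon_end = ee, config = cfg
  )
  expect_equal(frac_probe, 9)
  # and just under the threshold: 49bp of 100bp
  expect_true(is.na(transcript_expression_from_probes(
    probe_start = 49, probe_end = 149, smoothed = 9,
    exon_start = es, exon_end = ee, config = cfg
  )))
})

test_that("transcript expression is order-invariant and scale-homogeneous", {
  es <- 0
  ee <- 1000
  set.seed(4)
  ps <- sort(sample(0:950, 20))
  pe <- ps + 50
  sm <- runif(20, 1, 10)
  v1 <- transcript_expression_from_probes(ps, pe, sm, es, ee)
  shuffle <- sample(20)
  v2 <- transcript_expression_from_probes(ps[shuffle], pe[shuffle], sm[shuffle], es, ee)
  expect_equal(v1, v2)
  v3 <- transcript_expression_from_probes(ps, pe, 3 * sm, es, ee)
  expect_equal(v3, 3 * v1)
})

test_that("slide-median normalization divides by the array-wide median", {
  expect_equal(slide_median_normalize(c(1, 2, 3), c(1, 2, 3)), c(0.5, 1, 1.5))
  expect_equal(slide_median_normalize(c(7, 7), rep(7, 5)), c(1, 1))
  set.seed(5)
  sig <- rlnorm(101)
  expect_equal(median(slide_median_normalize(sig, sig)), 1)
  expect_error(slide_median_normalize(1:3, c(-1, 0, 1)), "zero")
})

test_that("dcpm follows its closed form on uniform coverage", {
  exon_start <- c(0, 500)
  exon_end <- c(200, 800)   # 500 exonic bases
  rs <- list(high_quality_mapped_reads = 2e6)
  # zero coverage
  empty <- data.frame(chrom = character(), pos = numeric(),
                      score = numeric(), representation = numeric())
  expect_equal(compute_dcpm(empty, exon_start, exon_end, "chrI", rs), 0)
  # uniform depth d over all exonic bases, representation 1
  d <- 3.5
  cov <- data.frame(chrom = "chrI",
                    pos = c(0:199, 500:799),
                    score = d, representation = 1)
  expect_equal(compute_dcpm(cov, exon_start, exon_end, "chrI", rs),
               d * 1e6 / 2e6)
  # linear in scores, inverse in mapped reads
  cov2 <- cov
  cov2$score <- 2 * cov$score
  expect_equal(compute_dcpm(cov2, exon_start, exon_end, "chrI", rs),
               2 * compute_dcpm(cov, exon_start, exon_end, "chrI", rs))
  rs_half <- list(high_quality_mapped_reads = 1e6)
  expect_equal(compute_dcpm(cov, exon_start, exon_end, "chrI", rs_half),
               2 * compute_dcpm(cov, exon_start, exon_end, "chrI", rs))
  expect_error(compute_dcpm(cov, exon_start, exon_end, "chrI",
                            list(high_quality_mapped_reads = 0)), "> 0")
})

test_that("bases at or above the representation cutoff are excluded", {
  rs <- list(high_quality_mapped_reads = 1e6)
  # all bases multi-mapping: denominator zero, value missing
  cov <- data.frame(chrom = "chrI", pos = 0:99, score = 5, representation = 96)
  expect_true(is.na(compute_dcpm(cov, 0, 100, "chrI", rs)))
  # half the bases excluded: they leave both numerator and denominator
  cov$representation[1:50] <- 1
  expect_equal(compute_dcpm(cov, 0, 100, "chrI", rs), 5 * 1e6 / 1e6)
  # bases absent from the track still count in the denominator (score 0)
  cov3 <- data.frame(chrom = "chrI", pos = 0:49, score = 4, representation = 1)
  expect_equal(compute_dcpm(cov3, 0, 100, "chrI", rs), (4 * 50 / 100) * 1e6 / 1e6)
})

test_that("GFF3 transcript models round-trip through rtracklayer", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\ttest\tgene\t1\t1000\t.\t+\t.\tID=Gene:WBGene00000001",
    "chrI\ttest\tmRNA\t1\t1000\t.\t+\t.\tID=Transcript:T1;Parent=Gene:WBGene00000001",
    "chrI\ttest\texon\t1\t200\t.\t+\t.\tParent=Transcript:T1",
    "chrI\ttest\texon\t301\t500\t.\t+\t.\tParent=Transcript:T1"
  ), gff)
  m <- read_transcript_models(gff)
  expect_equal(nrow(m), 2)
  expect_equal(m$transcript_id, c("T1", "T1"))
  expect_equal(m$gene_id, c("WBGene00000001", "WBGene00000001"))
  expect_equal(m$start, c(0, 300))   # 0-based half-open
  expect_equal(m$end, c(200, 500))
})

test_that("the tiling pipeline recovers planted signals on clean probes", {
  models <- simulate_transcript_models(5)
  planted <- stats::setNames(c(1, 2, 4, 8, 16), unique(models$transcript_id))
  sim <- simulate_probes_and_coverage(
    models, planted,
    platform_sim_config(pm_background = 0, mm_fraction = 0, noise_sd = 0,
                        signal_per_unit = 10, seed = 9)
  )
  te <- tiling_expression(sim$probes, models)
  # slide median is the planted median (4) x signal scale; values normalize to
  # planted / median(planted)
  expect_equal(te$value, unname(planted / 4))
})
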