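#' Configuration for synthetic annotation histories
#'
#' @param n_genes number of genes alive in the first release.
#' @param n_releases number of releases (>= 1).
#' @param merge_rate,split_rate,kill_rate,create_rate,rename_rate,resurrect_rate
#'   expected number of events of each type per release transition, expressed
#'   as a fraction of the currently live gene count.
#' @param seed integer seed; mandatory, all generators are deterministic.
#' @return a list of class `history_sim_config`.
#' @export
history_sim_config <- function(n_genes = 100, n_releases = 5,
                               merge_rate = 0.02, split_rate = 0.01,
                               kill_rate = 0.02, create_rate = 0.02,
                               rename_rate = 0.02, resurrect_rate = 0.005,
                               seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(n_genes >= 1, n_releases >= 1,
            merge_rate >= 0, split_rate >= 0, kill_rate >= 0,
            create_rate >= 0, rename_rate >= 0, resurrect_rate >= 0)
  structure(as.list(environment()), class = "history_sim_config")
}

#' Simulate an annotation history with known gene fates
#'
#' Generates an ordered set of releases, per-release correspondence tables
#' and a structurally valid event log (merges keep one of their source
#' identifiers as the surviving composite gene, splits retire the parent and
#' create fresh successors, kills retire genes, creations add genes, renames
#' change names only, resurrections revive previously killed genes).  A truth
#' map records, for every gene alive in the first release, its fate over the
#' full span and its final identifier(s) — the ground truth that
#' [convert_list()] must reproduce.
#'
#' @param config a [history_sim_config()].
#' @return list with `history` (a [release_history()]) and `truth`
#'   (data frame: `origin`, `fate` in killed/merged/split/passthrough,
#'   `final_ids` comma-joined, `kill_release`).
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "history_sim_config"))
  set.seed(config$seed)
  counter <- config$n_genes
  new_gene_row <- function(i) {
    data.frame(
      wbid = sprintf("WBGene%08d", i),
      sequence_name = sprintf("S%04d.%d", (i - 1) %/% 10 + 1, (i - 1) %% 10 + 1),
      public_name = sprintf("syg-%d", i),
      transcript_names = sprintf("S%04d.%da", (i - 1) %/% 10 + 1, (i - 1) %% 10 + 1),
      status = "live", stringsAsFactors = FALSE
    )
  }
  state <- do.call(rbind, lapply(seq_len(config$n_genes), new_gene_row))
  releases <- sprintf("R%03d", seq_len(config$n_releases))
  tables <- list()
  tables[[releases[1]]] <- state
  events <- list()

  originals <- state$wbid
  # truth bookkeeping: origin -> current live ids, flags
  tr_current <- as.list(originals)
  names(tr_current) <- originals
  tr_alive <- lapply(tr_current, function(x) TRUE)
  tr_merged <- stats::setNames(rep(FALSE, length(originals)), originals)
  tr_split <- stats::setNames(rep(FALSE, length(originals)), originals)
  tr_killrel <- stats::setNames(rep(NA_character_, length(originals)), originals)

  touch <- function(ids, fun) {
    for (o in originals) {
      cur <- tr_current[[o]]
      hit <- tr_alive[[o]] & cur %in% ids
      if (any(hit)) fun(o, hit)
    }
  }

  for (r in seq_len(max(config$n_releases - 1, 0))) {
    rel <- releases[r + 1]
    live <- state$wbid[state$status == "live"]
    dead <- state$wbid[state$status == "dead"]
    n_live <- length(live)

    draw <- function(rate) stats::rpois(1, rate * n_live)
    n_merge <- draw(config$merge_rate)
    n_split <- draw(config$split_rate)
    n_kill <- draw(config$kill_rate)
    n_create <- draw(config$create_rate)
    n_rename <- draw(config$rename_rate)
    n_res <- min(stats::rpois(1, config$resurrect_rate * n_live), length(dead))

    need <- 2 * n_merge + n_split + n_kill + n_rename
    if (need > n_live) {
      warning("event rates imply more affected genes than are live; clamping")
      while (2 * n_merge + n_split + n_kill + n_rename > n_live) {
        if (n_kill > 0) n_kill <- n_kill - 1
        else if (n_merge > 0) n_merge <- n_merge - 1
        else if (n_split > 0) n_split <- n_split - 1
        else n_rename <- n_rename - 1
      }
    }
    pool <- sample(live, 2 * n_merge + n_split + n_kill + n_rename)
    take <- function(k) {
      if (k == 0) return(character())
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    merge_src <- take(2 * n_merge)
    split_src <- take(n_split)
    kill_src <- take(n_kill)
    rename_src <- take(n_rename)
    res_src <- if (n_res > 0) sample(dead, n_res) else character()

    add_event <- function(type, src, tgt, note = "") {
      events[[length(events) + 1]] <<- data.frame(
        effective_release = rel, event_type = type,
        source_wbids = paste(src, collapse = ","),
        target_wbids = paste(tgt, collapse = ","),
        note = note, stringsAsFactors = FALSE
      )
    }

    for (m in seq_len(n_merge)) {
      src <- merge_src[c(2 * m - 1, 2 * m)]
      tgt <- sample(src, 1)
      add_event("merge", src, tgt)
      state$status[state$wbid %in% setdiff(src, tgt)] <- "dead"
      touch(src, function(o, hit) {
        tr_current[[o]][hit] <<- tgt
        tr_merged[o] <<- TRUE
      })
    }
    for (s in split_src) {
      tgt <- character(2)
      for (j in 1:2) {
        counter <- counter + 1
        row <- new_gene_row(counter)
        state <- rbind(state, row)
        tgt[j] <- row$wbid
      }
      add_event("split", s, tgt)
      state$status[state$wbid == s] <- "dead"
      tgt <- sort(tgt)
      touch(s, function(o, hit) {
        cur <- tr_current[[o]]
        alv <- tr_alive[[o]]
        tr_current[[o]] <<- c(cur[!hit], rep(tgt, times = sum(hit)))
        tr_alive[[o]] <<- c(alv[!hit], rep(TRUE, sum(hit) * length(tgt)))
        tr_split[o] <<- TRUE
      })
    }
    if (n_kill > 0) {
      add_event("kill", kill_src, character())
      state$status[state$wbid %in% kill_src] <- "dead"
      touch(kill_src, function(o, hit) {
        tr_alive[[o]][hit] <<- FALSE
        tr_killrel[o] <<- rel
      })
    }
    for (k in seq_len(n_create)) {
      counter <- counter + 1
      row <- new_gene_row(counter)
      state <- rbind(state, row)
      add_event("create", character(), row$wbid)
    }
    for (g in rename_src) {
      i <- which(state$wbid == g)
      counter <- counter + 1
      state$sequence_name[i] <- sprintf("S%04d.%d", (counter - 1) %/% 10 + 1,
                                        (counter - 1) %% 10 + 1)
      state$public_name[i] <- sprintf("syg-%d", counter)
      add_event("rename", g, g, "renamed")
    }
    for (g in res_src) {
      state$status[state$wbid == g] <- "live"
      add_event("resurrect", g, g)
      for (o in originals) {
        cur <- tr_current[[o]]
        hit <- !tr_alive[[o]] & cur == g
        if (any(hit)) tr_alive[[o]][hit] <- TRUE
      }
    }
    rownames(state) <- NULL
    tables[[rel]] <- state
  }

  events_df <- if (length(events)) do.call(rbind, events) else NULL
  history <- release_history(releases, tables, events_df)

  truth <- do.call(rbind, lapply(originals, function(o) {
    final <- unique(tr_current[[o]][tr_alive[[o]]])
    fate <- if (length(final) == 0) "killed"
    else if (tr_split[[o]]) "split"
    else if (tr_merged[[o]]) "merged"
    else "passthrough"
    data.frame(origin = o, fate = fate,
               final_ids = paste(sort(final), collapse = ","),
               kill_release = if (fate == "killed") tr_killrel[[o]] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  list(history = history, truth = truth)
}

#' Write a release history to TSV files
#'
#' Emits one correspondence table per release (`<release>.tsv`),
#' `events.tsv`, and a `releases.txt` manifest recording the release order,
#' in the schema read back by [load_history()] / [load_history_dir()].
#'
#' @param history a [release_history()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of correspondence paths.
#' @export
write_history <- function(history, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (rel in history$releases) {
    p <- file.path(dir, paste0(tolower(rel), ".tsv"))
    utils::write.table(history$tables[[rel]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[rel] <- p
  }
  utils::write.table(history$events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(history$releases, file.path(dir, "releases.txt"))
  invisible(paths)
}

#' Configuration for synthetic paired expression tables
#'
#' The generator emulates the statistical structure of single-sample paired
#' (uninfected, infected) expression measurements: log-normal baselines, a
#' planted fraction of truly up-/down-regulated transcripts at a fixed fold,
#' multiplicative noise whose log-scale standard deviation inflates as the
#' baseline decreases (`sd = s0 + s1 / (baseline + 1)`), and a zero-inflated
#' class expressed only after infection.
#'
#' @param n_transcripts number of transcripts.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters
#'   (natural-log scale).
#' @param up_fraction,up_fold planted up-regulation: fraction of transcripts
#'   and linear fold applied to the infected value.
#' @param down_fraction,down_fold planted down-regulation (infected divided
#'   by the fold).
#' @param noise_s0,noise_s1 heteroscedastic noise constants: the sd of the
#'   log2 ratio is `noise_s0 + noise_s1 / (baseline + 1)`.
#' @param zero_inflation_rate fraction of transcripts with zero control
#'   expression but positive infected expression (infection-specific).
#' @param seed integer seed; mandatory.
#' @return list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_transcripts = 5000,
                                  baseline_meanlog = 1, baseline_sdlog = 1.5,
                                  up_fraction = 0.05, up_fold = 4,
                                  down_fraction = 0.05, down_fold = 4,
                                  noise_s0 = 0.15, noise_s1 = 1.75,
                                  zero_inflation_rate = 0.03,
                                  seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(up_fraction >= 0, down_fraction >= 0, zero_inflation_rate >= 0,
            up_fraction + down_fraction + zero_inflation_rate <= 1,
            up_fold > 1, down_fold > 1, noise_s0 >= 0, noise_s1 >= 0)
  structure(as.list(environment()), class = "expression_sim_config")
}

#' Simulate a paired expression table with known regulation labels
#'
#' @param config an [expression_sim_config()].
#' @return list with `pairs` (data frame `transcript_id`, `control`,
#'   `infected`) and `truth` (data frame `transcript_id`, `label` in
#'   null/up/down/infection_specific, `baseline`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  id <- sprintf("TX%06d", seq_len(n))
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)

  n_up <- round(config$up_fraction * n)
  n_down <- round(config$down_fraction * n)
  n_zero <- round(config$zero_inflation_rate * n)
  label <- rep("null", n)
  idx <- sample.int(n, n_up + n_down + n_zero)
  label[idx[seq_len(n_up)]] <- "up"
  label[idx[n_up + seq_len(n_down)]] <- "down"
  label[idx[n_up + n_down + seq_len(n_zero)]] <- "infection_specific"

  sd_log2 <- config$noise_s0 + config$noise_s1 / (baseline + 1)
  noise <- 2 ^ stats::rnorm(n, 0, sd_log2)
  fold <- ifelse(label == "up", config$up_fold,
                 ifelse(label == "down", 1 / config$down_fold, 1))
  control <- baseline
  infected <- baseline * fold * noise
  zi <- label == "infection_specific"
  control[zi] <- 0
  infected[zi] <- stats::rlnorm(sum(zi), config$baseline_meanlog,
                                config$baseline_sdlog)

  list(
    pairs = data.frame(transcript_id = id, control = control,
                       infected = infected, stringsAsFactors = FALSE),
    truth = data.frame(transcript_id = id, label = label, baseline = baseline,
                       stringsAsFactors = FALSE)
  )
}

#' Configuration for synthetic probes and coverage
#'
#' @param probe_length,probe_step probe tiling geometry in bp.
#' @param n_replicates PM/MM replicate count (2 or 3 on real arrays).
#' @param pm_background additive background intensity on PM probes.
#' @param mm_fraction MM intensity as a fraction of the PM intensity.
#' @param noise_sd additive Gaussian noise sd on probe intensities.
#' @param signal_per_unit PM signal per unit of planted expression.
#' @param depth_per_unit per-base read depth per unit of planted expression.
#' @param mapped_reads high-quality mapped read count for the sample.
#' @param representation_high value planted on bases of
#'   `high_representation_transcripts` (at or above the dcpm cutoff, so those
#'   transcripts quantify as missing).
#' @param high_representation_transcripts transcript ids whose bases all get
#'   `representation_high`.
#' @param seed integer seed; mandatory.
#' @return list of class `platform_sim_config`.
#' @export
platform_sim_config <- function(probe_length = 25, probe_step = 25,
                                n_replicates = 3,
                                pm_background = 50, mm_fraction = 0.3,
                                noise_sd = 0, signal_per_unit = 100,
                                depth_per_unit = 1,
                                mapped_reads = 1e6,
                                representation_high = 96,
                                high_representation_transcripts = character(),
                                seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(probe_length > 0, probe_step > 0, n_replicates >= 2,
            mm_fraction >= 0, mm_fraction < 1, noise_sd >= 0,
            mapped_reads > 0)
  structure(as.list(environment()), class = "platform_sim_config")
}

#' Generate synthetic transcript models
#'
#' Simple non-overlapping two-exon models laid head to tail along one
#' chromosome; adequate geometry for exercising probe overlap and coverage
#' aggregation.
#'
#' @param n_transcripts number of models.
#' @param exon_length,intron_length,gap_length geometry in bp.
#' @return a `transcript_models` data frame (see [read_transcript_models()]):
#'   columns `transcript_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   one row per exon, 0-based half-open coordinates.
#' @export
simulate_transcript_models <- function(n_transcripts = 10, exon_length = 200,
                                       intron_length = 50, gap_length = 500) {
  span <- 2 * exon_length + intron_length
  rows <- lapply(seq_len(n_transcripts), function(i) {
    offset <- (i - 1) * (span + gap_length)
    data.frame(
      transcript_id = sprintf("TX%06d", i),
      gene_id = sprintf("WBGene%08d", i),
      chrom = "chrI",
      start = c(offset, offset + exon_length + intron_length),
      end = c(offset + exon_length, offset + span),
      strand = "+", stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transcript_models", "data.frame")
  out
}

#' Simulate tiling probes and per-base coverage for known expression
#'
#' Probes tile the exons of each model at fixed step; PM intensity is
#' background plus signal proportional to the planted expression (plus
#' optional noise), MM is a fixed fraction of PM.  The coverage track has
#' per-base depth proportional to planted expression, representation 1
#' everywhere except transcripts listed in
#' `config$high_representation_transcripts`.
#'
#' @param models a `transcript_models` data frame
#'   (e.g. [simulate_transcript_models()]).
#' @param expression named numeric vector of planted expression, one entry
#'   per transcript id in `models`.
#' @param config a [platform_sim_config()].
#' @return list with `probes` (data frame: `probe_id`, `chrom`, `start`,
#'   `end`, `pm_1..`, `mm_1..`), `coverage` (data frame: `chrom`, `pos`,
#'   `score`, `representation`), and `read_stats`
#'   (list with `high_quality_mapped_reads`).
#' @export
simulate_probes_and_coverage <- function(models, expression, config) {
  stopifnot(inherits(config, "platform_sim_config"))
  set.seed(config$seed)
  txs <- unique(models$transcript_id)
  if (!all(txs %in% names(expression))) {
    stop("'expression' must name every transcript in 'models'")
  }
  probes <- list()
  coverage <- list()
  pid <- 0
  for (tx in txs) {
    ex <- models[models$transcript_id == tx, , drop = FALSE]
    e <- expression[[tx]]
    for (j in seq_len(nrow(ex))) {
      starts <- seq(ex$start[j], ex$end[j] - config$probe_length,
                    by = config$probe_step)
      for (s in starts) {
        pid <- pid + 1
        pm <- config$pm_background + config$signal_per_unit * e +
          stats::rnorm(config$n_replicates, 0, config$noise_sd)
        mm <- config$mm_fraction * pm +
          stats::rnorm(config$n_replicates, 0, config$noise_sd)
        probes[[pid]] <- data.frame(
          probe_id = sprintf("P%06d", pid), chrom = ex$chrom[j],
          start = s, end = s + config$probe_length,
          t(stats::setNames(pm, paste0("pm_", seq_along(pm)))),
          t(stats::setNames(mm, paste0("mm_", seq_along(mm)))),
          stringsAsFactors = FALSE
        )
      }
      pos <- seq(ex$start[j], ex$end[j] - 1)
      rep_val <- if (tx %in% config$high_representation_transcripts) {
        config$representation_high
      } else 1
      coverage[[length(coverage) + 1]] <- data.frame(
        chrom = ex$chrom[j], pos = pos,
        score = config$depth_per_unit * e,
        representation = rep_val, stringsAsFactors = FALSE
      )
    }
  }
  list(
    probes = do.call(rbind, probes),
    coverage = do.call(rbind, coverage),
    read_stats = list(high_quality_mapped_reads = config$mapped_reads)
  )
}
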