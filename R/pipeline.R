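# End-to-end orchestration of the design cascade with per-stage checkpoints
# and a funnel report.

#' Configuration for the design pipeline
#'
#' @param species Named list of references, one per species: each element
#'   either a `transcriptome` object or a list of file paths
#'   `list(fasta =, map =, utr =)` (utr optional) readable by
#'   [read_transcriptome()].
#' @param mirnas Mature miRNA sequences: a character vector (RNA or DNA
#'   alphabet) or the path to a FASTA file. May be empty (the seed filter is
#'   then vacuous).
#' @param human_species Name of the primary reference used for quiescence
#'   scoring and heptamer frequencies; defaults to the first species.
#' @param quartile,decile Retained lower fractions of the quiescence and
#'   heptamer-frequency filters; defaults 0.25 and 0.10.
#' @param n_extensions Random 23-mer candidates generated per retained
#'   decamer; default 10,000.
#' @param k_worst Candidates retained per decamer (largest alignment
#'   profiles); default 10.
#' @param max_decamers Optional seeded subsample size of the full decamer
#'   enumeration, for fast runs; `NULL` (default) = full enumeration.
#' @param rng_seed Master seed; the whole run is deterministic given it.
#' @param scorer Quiescence scorer `f(decamers, utrs) -> numeric`
#'   (lower = more quiescent); default [score_quiescence_surrogate()].
#' @param scorer_name Label recorded in checkpoints/report.
#' @param seed_orientation Heptamer orientation, see [seed_target_heptamer()].
#' @param scheme Penalty scheme for the extension stage.
#' @param out_dir Optional directory for per-stage checkpoint TSVs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(species,
                            mirnas = character(0),
                            human_species = NULL,
                            quartile = 0.25,
                            decile = 0.10,
                            n_extensions = 10000L,
                            k_worst = 10L,
                            max_decamers = NULL,
                            rng_seed = 1L,
                            scorer = score_quiescence_surrogate,
                            scorer_name = "seed_complement_gene_count",
                            seed_orientation = c("complement", "guide"),
                            scheme = penalty_scheme(),
                            out_dir = NULL) {
  stopifnot(is.list(species), length(species) >= 1L)
  if (is.null(names(species)) || any(names(species) == "")) {
    stop("species must be a named list", call. = FALSE)
  }
  if (is.null(human_species)) human_species <- names(species)[1L]
  if (!human_species %in% names(species)) {
    stop("human_species '", human_species, "' not among the species", call. = FALSE)
  }
  for (f in c(quartile, decile)) {
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
      stop("quartile/decile fractions must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(species = species, mirnas = mirnas,
                 human_species = human_species,
                 quartile = quartile, decile = decile,
                 n_extensions = check_count(n_extensions, "n_extensions", 1L),
                 k_worst = check_count(k_worst, "k_worst", 1L),
                 max_decamers = if (!is.null(max_decamers))
                   check_count(max_decamers, "max_decamers", 1L),
                 rng_seed = check_count(rng_seed, "rng_seed"),
                 scorer = scorer, scorer_name = scorer_name,
                 seed_orientation = match.arg(seed_orientation),
                 scheme = check_scheme(scheme),
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_references <- function(config) {
  txs <- lapply(names(config$species), function(sp) {
    x <- config$species[[sp]]
    if (inherits(x, "transcriptome")) return(x)
    if (is.list(x) && !is.null(x$fasta) && !is.null(x$map)) {
      return(read_transcriptome(x$fasta, x$map, utr_fasta = x$utr, species = sp))
    }
    stop("species '", sp, "' must be a transcriptome or list(fasta=, map=, utr=)",
         call. = FALSE)
  })
  names(txs) <- names(config$species)
  mirnas <- config$mirnas
  if (is.character(mirnas) && length(mirnas) == 1L && file.exists(mirnas)) {
    mirnas <- read_mirna_fasta(mirnas)
  }
  list(species = txs, mirnas = mirnas)
}

ck_write <- function(df, dir, file) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

ck_read <- function(dir, file) {
  read.delim(file.path(dir, file), colClasses = NA, stringsAsFactors = FALSE)
}

ck_have <- function(resume, dir, file) {
  resume && !is.null(dir) && file.exists(file.path(dir, file))
}

#' Run the full transgene regulator siRNA design cascade
#'
#' Executes the six stages in order - decamer enumeration, miRNA seed filter,
#' quiescence quartile, seed-heptamer-frequency decile, per-species
#' complementary-match ranking, and random 23-mer extension with
#' position-weighted alignment scoring - validating the monotone-funnel
#' invariant between stages. Fully deterministic given the config (all
#' randomness derives from `rng_seed`). If `config$out_dir` is set, each
#' stage writes a checkpoint TSV; with `resume = TRUE` existing checkpoints
#' are loaded instead of recomputed, reproducing downstream outputs
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param resume Reuse existing checkpoint TSVs in `config$out_dir`.
#' @return Object of class `design_run`: `report` (stage funnel), `decamers`
#'   (ranked stage-5 table), `candidates` (final ranked 23-mer table with
#'   sense strands), `heptamers` (the reference heptamer table), `config`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  refs <- load_references(config)   # fail before any stage if inputs invalid
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  human <- refs$species[[config$human_species]]
  report <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  note <- function(stage, n_in, n_out, filter = TRUE) {
    if (filter && n_out > n_in) {
      stop("funnel invariant violated at stage '", stage, "': ",
           n_out, " > ", n_in, call. = FALSE)
    }
    report[nrow(report) + 1L, ] <<- list(stage, n_in, n_out)
  }

  # stage 1: enumeration (optionally a seeded subsample)
  if (ck_have(resume, dir, "01_decamers.tsv")) {
    d1 <- ck_read(dir, "01_decamers.tsv")
  } else {
    d1 <- enumerate_decamers()
    if (!is.null(config$max_decamers) && config$max_decamers < nrow(d1)) {
      keep <- withr::with_seed(config$rng_seed,
                               sort(sample.int(nrow(d1), config$max_decamers)))
      d1 <- d1[keep, , drop = FALSE]
      rownames(d1) <- NULL
    }
    ck_write(d1, dir, "01_decamers.tsv")
  }
  note("enumerate", nrow(d1), nrow(d1), filter = FALSE)

  # stage 2: miRNA seed exclusion
  if (ck_have(resume, dir, "02_seed_filtered.tsv")) {
    d2 <- ck_read(dir, "02_seed_filtered.tsv")
  } else {
    seeds <- mirna_seed_set(refs$mirnas)
    d2 <- filter_mirna_seeds(d1, seeds)
    ck_write(d2, dir, "02_seed_filtered.tsv")
  }
  note("mirna_seed_filter", nrow(d1), nrow(d2))

  # stage 3: quiescence quartile
  if (ck_have(resume, dir, "03_quiescence.tsv")) {
    d3 <- ck_read(dir, "03_quiescence.tsv")
  } else {
    d2$quiescence <- config$scorer(d2, utr_seqs(human))
    d3 <- quartile_filter(d2, config$quartile)
    ck_write(d3, dir, "03_quiescence.tsv")
  }
  note("quiescence_quartile", nrow(d2), nrow(d3))

  # stage 4: seed-heptamer frequency decile over the collapsed primary species
  if (ck_have(resume, dir, "04_heptamer.tsv")) {
    d4 <- ck_read(dir, "04_heptamer.tsv")
    hept <- NULL
  } else {
    collapsed <- collapse_transcriptome(human)
    hept <- heptamer_table(collapsed, species = config$human_species)
    d3$seed_target_heptamer <- seed_target_heptamer(d3, config$seed_orientation)
    d3$seed_heptamer_freq <- heptamer_frequency(d3, hept, config$seed_orientation)
    d4 <- decile_filter(d3, config$decile)
    ck_write(d4, dir, "04_heptamer.tsv")
    if (!is.null(dir)) {
      ck_write(data.frame(heptamer = names(hept), count = as.integer(hept)),
               dir, "04_heptamer_table.tsv")
    }
  }
  note("heptamer_decile", nrow(d3), nrow(d4))

  # stage 5: per-species complementary-match counts and three-key ranking
  if (ck_have(resume, dir, "05_ranked.tsv")) {
    d5 <- ck_read(dir, "05_ranked.tsv")
  } else {
    counts <- count_matches_by_species(d4, refs$species)
    colnames(counts) <- paste0("matches.", colnames(counts))
    d5 <- cbind(d4, counts)
    d5$total_matches <- as.integer(rowSums(counts))
    d5$human_seed_freq <- d5$seed_heptamer_freq
    d5 <- rank_decamers(d5)
    ck_write(d5, dir, "05_ranked.tsv")
  }
  note("match_rank", nrow(d4), nrow(d5), filter = FALSE)

  # stage 6: extension, profile scoring, worst-aligned selection, final rank
  if (ck_have(resume, dir, "06_final.tsv")) {
    final <- ck_read(dir, "06_final.tsv")
  } else {
    picks <- vector("list", nrow(d5))
    for (i in seq_len(nrow(d5))) {
      ext_seed <- as.integer((config$rng_seed + 7919 * i) %% 2147483647)
      cand <- extend_decamer(d5$decamer[i], config$n_extensions, ext_seed)
      prof <- alignment_profile(cand, refs$species, config$scheme)
      sel <- select_worst_aligned(prof, config$k_worst)
      sel$decamer <- d5$decamer[i]
      sel$quiescence <- d5$quiescence[i]
      sel$decamer_rank <- d5$rank[i]
      picks[[i]] <- sel
    }
    final <- do.call(rbind, picks)
    if (is.null(final)) {
      final <- data.frame(rank = integer(0), antisense = character(0),
                          sense = character(0), profile = numeric(0),
                          n_best = integer(0), decamer = character(0),
                          quiescence = numeric(0), decamer_rank = integer(0))
    } else {
      final <- final_rank(final)
      final$sense <- vapply(final$antisense,
                            function(a) make_duplex(a)$sense, character(1),
                            USE.NAMES = FALSE)
      lead <- c("rank", "antisense", "sense", "decamer", "profile", "n_best",
                "quiescence", "decamer_rank")
      final <- final[c(lead, setdiff(names(final), lead))]
    }
    ck_write(final, dir, "06_final.tsv")
  }
  note("extend_select", nrow(d5), nrow(final), filter = FALSE)
  if (nrow(final) > nrow(d5) * config$k_worst) {
    stop("stage 'extend_select' emitted more than k * survivors candidates",
         call. = FALSE)
  }

  if (!is.null(dir)) {
    ck_write(report, dir, "funnel.tsv")
    if (nrow(final)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(
        setNames(c(rbind(final$antisense, final$sense)),
                 c(rbind(sprintf("cand%04d_antisense", final$rank),
                         sprintf("cand%04d_sense", final$rank))))),
        file.path(dir, "06_final_duplexes.fa"))
    }
  }
  structure(list(report = report, decamers = d5, candidates = final,
                 heptamers = hept, config = config),
            class = "design_run")
}

#' @export
print.design_run <- function(x, ...) {
  cat("<design_run> scorer:", x$config$scorer_name, "| seed:",
      x$config$rng_seed, "\n\nFunnel:\n")
  print(x$report, row.names = FALSE)
  cat("\nTop candidates:\n")
  show <- head(x$candidates, 5L)
  print(show[intersect(c("rank", "antisense", "sense", "profile", "quiescence"),
                       names(show))], row.names = FALSE)
  invisible(x)
}
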