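# Synthetic transcriptomes, miRNA sets and planted-site fixtures.

#' Parameters for the synthetic transcriptome generator
#'
#' Genes are assembled from shared "exon blocks": every isoform of a gene is a
#' splice of an ordered subset of the gene's blocks, so isoforms share long
#' exact substrings and the isoform-collapsing stage has real work to do. The
#' terminal block of the canonical (all-blocks, longest) isoform doubles as the
#' gene 3'UTR, which makes the UTR a suffix of at least one isoform by
#' construction.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Inclusive integer range, isoforms sampled per gene.
#' @param exon_block_length Inclusive range (nt) for non-terminal block lengths.
#' @param blocks_per_gene Inclusive range for the number of blocks per gene.
#' @param utr_length Inclusive range (nt) for the terminal (3'UTR) block.
#' @param base_composition Probability 4-vector for A, C, G, T; must sum to 1.
#' @param rng_seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_genes = 50L,
                             isoforms_per_gene = c(1L, 4L),
                             exon_block_length = c(100L, 300L),
                             blocks_per_gene = c(3L, 6L),
                             utr_length = c(150L, 300L),
                             base_composition = rep(0.25, 4),
                             rng_seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  isoforms_per_gene <- check_range(isoforms_per_gene, "isoforms_per_gene")
  exon_block_length <- check_range(exon_block_length, "exon_block_length")
  blocks_per_gene <- check_range(blocks_per_gene, "blocks_per_gene")
  utr_length <- check_range(utr_length, "utr_length")
  if (!is.numeric(base_composition) || length(base_composition) != 4L ||
      any(base_composition < 0) || abs(sum(base_composition) - 1) > 1e-9) {
    stop("base_composition must be 4 probabilities summing to 1", call. = FALSE)
  }
  structure(list(n_genes = n_genes,
                 isoforms_per_gene = isoforms_per_gene,
                 exon_block_length = exon_block_length,
                 blocks_per_gene = blocks_per_gene,
                 utr_length = utr_length,
                 base_composition = base_composition,
                 rng_seed = check_count(rng_seed, "rng_seed")),
            class = "synthetic_params")
}

new_transcriptome <- function(species, genes, utrs = NULL) {
  structure(list(species = species, genes = genes, utrs = utrs),
            class = "transcriptome")
}

#' Validate a transcriptome object
#'
#' Checks the structural invariants: unique transcript ids each belonging to
#' exactly one gene, non-empty upper-case DNA sequences, and every recorded
#' 3'UTR being a suffix of at least one isoform of its gene.
#'
#' @param x A `transcriptome` object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_transcriptome <- function(x) {
  stopifnot(inherits(x, "transcriptome"))
  if (length(x$genes) == 0L) return(invisible(x))
  if (is.null(names(x$genes)) || anyDuplicated(names(x$genes))) {
    stop("gene ids must be unique and named", call. = FALSE)
  }
  tx_ids <- unlist(lapply(x$genes, names), use.names = FALSE)
  if (anyDuplicated(tx_ids)) {
    stop("transcript id assigned to more than one record: ",
         tx_ids[duplicated(tx_ids)][1L], call. = FALSE)
  }
  for (g in names(x$genes)) check_dna(x$genes[[g]], paste0("isoforms of ", g))
  if (!is.null(x$utrs)) {
    for (g in names(x$utrs)) {
      if (!g %in% names(x$genes)) stop("UTR for unknown gene ", g, call. = FALSE)
      utr <- x$utrs[[g]]
      check_dna(utr, paste0("3'UTR of ", g))
      if (!any(endsWith(x$genes[[g]], utr))) {
        stop("3'UTR of ", g, " is not a suffix of any isoform", call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Generate a seeded synthetic transcriptome
#'
#' Each gene samples a set of exon blocks once; the canonical isoform splices
#' all blocks (and is therefore the longest), additional isoforms splice random
#' subsets that always include the first block, so any two isoforms of a gene
#' share at least one full block. The terminal block of the canonical isoform
#' is recorded as the gene 3'UTR.
#'
#' @param params A [synthetic_params()] object.
#' @param species Species label stored on the object.
#' @return A `transcriptome` object.
#' @export
#' @examples
#' tx <- generate_transcriptome(synthetic_params(n_genes = 3, rng_seed = 7))
#' gene_map(tx)
generate_transcriptome <- function(params, species = "synthetic") {
  stopifnot(inherits(params, "synthetic_params"))
  if (params$n_genes == 0L) {
    return(new_transcriptome(species, setNames(list(), character(0)),
                             setNames(character(0), character(0))))
  }
  withr::with_seed(params$rng_seed, {
    genes <- vector("list", params$n_genes)
    utrs <- character(params$n_genes)
    gids <- sprintf("%s_g%04d", species, seq_len(params$n_genes))
    for (i in seq_len(params$n_genes)) {
      n_blocks <- sample_range(params$blocks_per_gene)
      block_len <- c(if (n_blocks > 1L)
                       vapply(seq_len(n_blocks - 1L), function(.)
                         sample_range(params$exon_block_length), integer(1)),
                     sample_range(params$utr_length))
      blocks <- vapply(block_len, function(l)
        paste(sample(DNA_BASES, l, replace = TRUE, prob = params$base_composition),
              collapse = ""), character(1))
      n_iso <- sample_range(params$isoforms_per_gene)
      iso <- character(n_iso)
      iso[1L] <- paste(blocks, collapse = "")            # canonical: all blocks
      if (n_iso > 1L) {
        for (j in 2:n_iso) {
          keep <- c(TRUE, stats::runif(n_blocks - 1L) < 0.5)
          iso[j] <- paste(blocks[keep], collapse = "")
        }
      }
      names(iso) <- sprintf("%s.t%d", gids[i], seq_len(n_iso))
      genes[[i]] <- iso
      utrs[i] <- blocks[n_blocks]
    }
    names(genes) <- gids
    names(utrs) <- gids
    validate_transcriptome(new_transcriptome(species, genes, utrs))
  })
}

#' Generate a set of mature miRNA sequences
#'
#' Random sequences over the RNA alphabet, standing in for a miRBase mature
#' set when exercising the seed filter on synthetic data.
#'
#' @param n Number of sequences (may be 0).
#' @param length_range Inclusive length range in nt.
#' @param rng_seed Integer seed.
#' @return Character vector of RNA sequences (A/C/G/U).
#' @export
generate_mirna_set <- function(n, length_range = c(19L, 24L), rng_seed = 1L) {
  n <- check_count(n, "n")
  length_range <- check_range(length_range, "length_range")
  if (n == 0L) return(character(0))
  withr::with_seed(rng_seed, {
    lens <- vapply(seq_len(n), function(.) sample_range(length_range), integer(1))
    out <- vapply(lens, function(l)
      paste(sample(RNA_BASES, l, replace = TRUE), collapse = ""), character(1))
    names(out) <- sprintf("mir-%04d", seq_len(n))
    out
  })
}

#' Substitute a canonical target site into a UTR
#'
#' Overwrites `utr` at `position` (1-based) with the canonical site pattern for
#' `guide` of the requested class (see [canonical_site()]); the UTR length is
#' unchanged. Used to build fixtures with known site content.
#'
#' @param utr UTR sequence (DNA).
#' @param guide Guide (antisense) sequence, 5'->3'; 23 nt for `"full_23"`,
#'   otherwise at least 8 nt.
#' @param site_type One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"full_23"`.
#' @param position 1-based start of the planted site in the UTR.
#' @return The modified UTR sequence.
#' @export
#' @examples
#' plant_site(strrep("T", 30), strrep("A", 23), "8mer", 5)
plant_site <- function(utr, guide, site_type, position) {
  check_dna(utr, "utr")
  site <- canonical_site(guide, site_type)
  position <- check_count(position, "position", min = 1L)
  if (position + nchar(site) - 1L > nchar(utr)) {
    stop("site of length ", nchar(site), " at position ", position,
         " does not fit in a UTR of length ", nchar(utr), call. = FALSE)
  }
  substr(utr, position, position + nchar(site) - 1L) <- site
  utr
}

#' Generate the full synthetic study inputs
#'
#' Convenience wrapper producing one transcriptome per species plus a mature
#' miRNA set, with per-species seeds derived deterministically from `rng_seed`.
#' Defaults mirror the design cascade's reference set: four species (human,
#' mouse, rat, cynomolgus), 50 genes each, and 500 mature miRNAs.
#'
#' @param species Character vector of species labels; the first is treated as
#'   the primary (human-like) reference by [pipeline_config()].
#' @param params [synthetic_params()] shared by all species (per-species seeds
#'   are derived from `rng_seed`, so species differ).
#' @param n_mirnas Size of the mature miRNA set.
#' @param rng_seed Master seed.
#' @return List with elements `species` (named list of transcriptomes) and
#'   `mirnas` (character vector, RNA alphabet).
#' @export
generate_study <- function(species = c("human", "mouse", "rat", "cyno"),
                           params = synthetic_params(),
                           n_mirnas = 500L,
                           rng_seed = 1L) {
  rng_seed <- check_count(rng_seed, "rng_seed")
  txs <- lapply(seq_along(species), function(i) {
    p <- params
    p$rng_seed <- (rng_seed + 101L * i) %% .Machine$integer.max
    generate_transcriptome(p, species = species[i])
  })
  names(txs) <- species
  list(species = txs,
       mirnas = generate_mirna_set(n_mirnas,
                                   rng_seed = (rng_seed + 7907L) %% .Machine$integer.max))
}

# ---- accessors ----

#' Transcript sequences of a transcriptome
#' @param x A `transcriptome`.
#' @return Named character vector, names = transcript ids.
#' @export
transcript_seqs <- function(x) {
  stopifnot(inherits(x, "transcriptome"))
  if (length(x$genes) == 0L) return(setNames(character(0), character(0)))
  ids <- unlist(lapply(x$genes, names), use.names = FALSE)
  setNames(unlist(x$genes, use.names = FALSE), ids)
}

#' Gene-to-transcript mapping table
#' @param x A `transcriptome`.
#' @return data.frame with columns `gene_id`, `transcript_id`.
#' @export
gene_map <- function(x) {
  stopifnot(inherits(x, "transcriptome"))
  data.frame(
    gene_id = rep(names(x$genes), lengths(x$genes)),
    transcript_id = unlist(lapply(x$genes, names), use.names = FALSE)
  )
}

#' Per-gene 3'UTR sequences
#' @param x A `transcriptome`.
#' @return Named character vector (possibly empty).
#' @export
utr_seqs <- function(x) {
  stopifnot(inherits(x, "transcriptome"))
  if (is.null(x$utrs)) setNames(character(0), character(0)) else x$utrs
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("<transcriptome> species:", x$species,
      "|", length(x$genes), "genes,",
      sum(lengths(x$genes)), "transcripts,",
      length(utr_seqs(x)), "3'UTRs\n")
  invisible(x)
}

# ---- FASTA / TSV I/O ----

#' Write a transcriptome to FASTA + TSV files
#'
#' Emits `<prefix>_transcripts.fa`, `<prefix>_gene_map.tsv` (columns gene_id,
#' transcript_id) and, if UTRs are present, `<prefix>_utr.fa` (record id =
#' gene id).
#'
#' @param x A `transcriptome`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to the species label.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_transcriptome <- function(x, dir, prefix = x$species) {
  stopifnot(inherits(x, "transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, "_transcripts.fa")),
             map = file.path(dir, paste0(prefix, "_gene_map.tsv")))
  seqs <- transcript_seqs(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), paths[["fasta"]])
  write.table(gene_map(x), paths[["map"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  utrs <- utr_seqs(x)
  if (length(utrs)) {
    paths[["utr"]] <- file.path(dir, paste0(prefix, "_utr.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(utrs), paths[["utr"]])
  }
  invisible(paths)
}

#' Read a transcriptome from FASTA + TSV files
#'
#' @param fasta Transcript FASTA path.
#' @param map Gene-to-transcript TSV path (columns gene_id, transcript_id).
#' @param utr_fasta Optional per-gene 3'UTR FASTA path.
#' @param species Species label to record.
#' @return A validated `transcriptome`.
#' @export
read_transcriptome <- function(fasta, map, utr_fasta = NULL, species = "unknown") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  seq_chr <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  mp <- read.delim(map, colClasses = "character")
  if (!all(c("gene_id", "transcript_id") %in% names(mp))) {
    stop("gene map must have columns gene_id, transcript_id", call. = FALSE)
  }
  missing <- setdiff(mp$transcript_id, names(seq_chr))
  if (length(missing)) {
    stop("transcripts in map but not in FASTA: ", missing[1L], call. = FALSE)
  }
  genes <- lapply(split(mp$transcript_id, mp$gene_id)[unique(mp$gene_id)],
                  function(ids) seq_chr[ids])
  utrs <- NULL
  if (!is.null(utr_fasta)) {
    u <- Biostrings::readDNAStringSet(utr_fasta)
    utrs <- setNames(as.character(u), sub("\\s.*$", "", names(u)))
  }
  validate_transcriptome(new_transcriptome(species, genes, utrs))
}

#' Write mature miRNA sequences as RNA FASTA
#' @param mirnas Named character vector (RNA or DNA alphabet).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  if (is.null(names(mirnas))) names(mirnas) <- sprintf("mir-%04d", seq_along(mirnas))
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(chartr("T", "U", toupper(mirnas))), path)
  invisible(path)
}

#' Read mature miRNA sequences from FASTA
#' @param path FASTA path (RNA or DNA alphabet records).
#' @return Named character vector in the RNA alphabet.
#' @export
read_mirna_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  setNames(chartr("T", "U", toupper(as.character(s))), sub("\\s.*$", "", names(s)))
}
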