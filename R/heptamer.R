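# Stage 4: heptamer frequencies over isoform-collapsed genes and the
# lowest-decile filter.

aln_consensus <- function(aln) {
  # aln: character matrix, one row per isoform in the order added, "-" = gap.
  # Majority base among non-gap characters per column; ties resolved toward
  # the earliest-added isoform; single-coverage columns keep their one base.
  vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    bases <- col[col != "-"]
    tab <- table(bases)
    cands <- names(tab)[tab == max(tab)]
    if (length(cands) == 1L) cands else col[col %in% cands][1L]
  }, character(1))
}

#' Collapse a gene's isoforms into one consensus sequence
#'
#' Heptamer counting must see each shared exon once and each isoform-specific
#' region once. A single isoform collapses to itself. Multiple isoforms are
#' merged by progressive global multiple alignment: longest isoform first,
#' each next isoform aligned to the running consensus (match +1, mismatch -1,
#' gap -2), then one base per alignment column - the majority base among
#' non-gap characters, ties resolved toward the earliest-added isoform.
#' Columns covered by a single isoform contribute that isoform's base.
#'
#' @param isoforms Character vector of isoform sequences (>= 1).
#' @return The collapsed sequence (character scalar).
#' @export
#' @examples
#' collapse_gene(c("ACGTACGTACGT", "ACGTACGT"))  # "ACGTACGTACGT"
collapse_gene <- function(isoforms) {
  isoforms <- unname(unlist(isoforms, use.names = FALSE))
  if (length(isoforms) == 0L) stop("gene has no isoforms", call. = FALSE)
  check_dna(isoforms, "isoform")
  if (length(isoforms) == 1L) return(isoforms)
  seqs <- isoforms[order(-nchar(isoforms), seq_along(isoforms))]
  aln <- matrix(strsplit(seqs[1L], "")[[1L]], nrow = 1L)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  for (i in 2:length(seqs)) {
    cons <- paste(aln_consensus(aln), collapse = "")
    pa <- Biostrings::pairwiseAlignment(seqs[i], cons, type = "global",
                                        substitutionMatrix = sm,
                                        gapOpening = 0, gapExtension = 2)
    pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    new <- matrix("-", nrow = nrow(aln) + 1L, ncol = length(sub))
    new[seq_len(nrow(aln)), sub != "-"] <- aln
    new[nrow(aln) + 1L, ] <- pat
    aln <- new
  }
  paste(aln_consensus(aln), collapse = "")
}

#' Collapse every gene of a transcriptome
#' @param x A `transcriptome`.
#' @return Named character vector, gene id -> collapsed sequence.
#' @export
collapse_transcriptome <- function(x) {
  stopifnot(inherits(x, "transcriptome"))
  vapply(x$genes, collapse_gene, character(1))
}

#' Heptamer occurrence table over collapsed gene sequences
#'
#' Counts every length-7 window (overlapping windows included) of every
#' collapsed sequence. The total count equals
#' `sum over genes of max(0, length - 6)`.
#'
#' @param collapsed Named character vector of collapsed gene sequences.
#' @param species Optional provenance label.
#' @return Named integer vector of counts, class `heptamer_table`, with
#'   attributes `species` and `n_genes`.
#' @export
heptamer_table <- function(collapsed, species = NA_character_) {
  if (length(collapsed)) check_dna(collapsed, "collapsed sequence")
  kmers <- unlist(lapply(collapsed, function(s) {
    n <- nchar(s)
    if (n < 7L) character(0) else substring(s, 1:(n - 6L), 7:n)
  }), use.names = FALSE)
  tab <- table(kmers)
  structure(setNames(as.integer(tab), names(tab)),
            species = species, n_genes = length(collapsed),
            class = "heptamer_table")
}

#' Seed-target heptamer of a decamer
#'
#' The heptamer whose transcriptome frequency is minimised is, by default, the
#' seed-COMPLEMENTARY heptamer: the reverse complement of guide positions 2-8,
#' i.e. the actual mRNA site a loaded guide would engage (TargetScan
#' convention). `orientation = "guide"` instead returns positions 2-8 of the
#' guide itself.
#'
#' @param decamers data.frame with a `decamer` column, or character vector.
#' @param orientation `"complement"` (default) or `"guide"`.
#' @return Character vector of 7-mers.
#' @export
#' @examples
#' seed_target_heptamer("TACGTACGTA")  # revcomp("ACGTACG") = "CGTACGT"
seed_target_heptamer <- function(decamers, orientation = c("complement", "guide")) {
  orientation <- match.arg(orientation)
  decamers <- as_decamer_frame(decamers)
  seed <- substr(decamers$decamer, 2L, 8L)
  if (orientation == "complement") revcomp(seed) else seed
}

#' Annotate decamers with their seed-heptamer frequency
#'
#' @param decamers data.frame with a `decamer` column, or character vector.
#' @param table A [heptamer_table()]; heptamers absent from it count 0.
#' @param orientation Passed to [seed_target_heptamer()].
#' @return Numeric vector of frequencies (counts).
#' @export
heptamer_frequency <- function(decamers, table,
                               orientation = c("complement", "guide")) {
  stopifnot(inherits(table, "heptamer_table"))
  hepts <- seed_target_heptamer(decamers, orientation)
  freq <- unclass(table)[hepts]
  freq[is.na(freq)] <- 0L
  as.numeric(unname(freq))
}

#' Retain the lowest decile of seed-heptamer frequency
#'
#' Same tie-inclusive nearest-rank rule as [quartile_filter()], applied at
#' fraction 0.10 to the `seed_heptamer_freq` column.
#'
#' @param records data.frame with a numeric `seed_heptamer_freq` column.
#' @param fraction Retained lower fraction; default 0.10.
#' @return The retained subset, original order preserved.
#' @export
decile_filter <- function(records, fraction = 0.10) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  if (is.null(records$seed_heptamer_freq)) {
    stop("records must carry a 'seed_heptamer_freq' column; annotate first",
         call. = FALSE)
  }
  out <- records[nearest_rank_retain(records$seed_heptamer_freq, fraction), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.heptamer_table <- function(x, ...) {
  cat("<heptamer_table>", length(x), "distinct heptamers,",
      sum(x), "total windows",
      if (!is.na(attr(x, "species"))) paste0("(", attr(x, "species"), ", ",
                                             attr(x, "n_genes"), " genes)"),
      "\n")
  invisible(x)
}
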