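# Stage 5: exact complementary-match counting per species and the three-key
# decamer ranking.

# normalise transcriptome-like inputs to a character vector of transcripts
as_transcript_set <- function(x) {
  if (inherits(x, "transcriptome")) return(unname(transcript_seqs(x)))
  if (is.character(x)) return(unname(x))
  stop("expected a transcriptome or a character vector of transcript sequences",
       call. = FALSE)
}

# ... and collections thereof to a named list of such vectors
as_reference_list <- function(x) {
  if (inherits(x, "transcriptome") || is.character(x)) {
    x <- list(x)
    names(x) <- if (inherits(x[[1L]], "transcriptome")) x[[1L]]$species else "ref"
  }
  stopifnot(is.list(x))
  if (is.null(names(x))) {
    names(x) <- vapply(seq_along(x), function(i)
      if (inherits(x[[i]], "transcriptome")) x[[i]]$species else
        paste0("ref", i), character(1))
  }
  lapply(x, as_transcript_set)
}

#' Count exact complementary matches of decamers in a transcriptome
#'
#' A guide decamer engages an mRNA through its reverse complement; the count
#' is the number of occurrences of `revcomp(decamer)` as a substring of any
#' transcript sense sequence, overlapping occurrences included, summed over
#' all transcripts (every isoform counted). For full-length perfect matches
#' this is exactly the number of ungapped 100%-identity alignments of the
#' decamer on the reverse-complement strand.
#'
#' @param decamers data.frame with a `decamer` column, or character vector.
#' @param transcriptome A `transcriptome` or character vector of transcripts.
#' @return Integer vector of counts, one per decamer.
#' @export
#' @examples
#' count_complementary_matches("AAAAAAAAAA", strrep("T", 12))  # 3
count_complementary_matches <- function(decamers, transcriptome) {
  decamers <- as_decamer_frame(decamers)
  txs <- as_transcript_set(transcriptome)
  if (length(txs) == 0L) return(integer(nrow(decamers)))
  check_dna(txs, "transcript")
  pats <- revcomp(decamers$decamer)
  hits <- Biostrings::vcountPDict(
    Biostrings::PDict(Biostrings::DNAStringSet(pats)),
    Biostrings::DNAStringSet(txs))
  as.integer(rowSums(hits))
}

#' Per-species complementary-match counts
#'
#' @param decamers data.frame with a `decamer` column, or character vector.
#' @param transcriptomes Named list of transcriptomes (or transcript vectors).
#' @return Integer matrix, decamers x species.
#' @export
count_matches_by_species <- function(decamers, transcriptomes) {
  decamers <- as_decamer_frame(decamers)
  refs <- as_reference_list(transcriptomes)
  m <- vapply(refs, function(txs) count_complementary_matches(decamers, txs),
              integer(nrow(decamers)))
  if (nrow(decamers) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(refs)))
  m
}

#' Rank decamers by match total, quiescence and human seed frequency
#'
#' Stable ascending sort on three keys: total complementary matches across
#' species, then quiescence score, then seed-heptamer frequency in the primary
#' (human) transcriptome. Residual ties are broken lexicographically by
#' decamer so the ranking is fully deterministic.
#'
#' @param records data.frame with columns `decamer`, `total_matches`,
#'   `quiescence`, `human_seed_freq`.
#' @return `records` reordered, with a `rank` column prepended.
#' @export
rank_decamers <- function(records) {
  stopifnot(is.data.frame(records))
  for (key in c("total_matches", "quiescence", "human_seed_freq")) {
    if (is.null(records[[key]])) {
      stop("missing annotation '", key, "'; run the corresponding stage first",
           call. = FALSE)
    }
    bad <- is.na(records[[key]])
    if (any(bad)) {
      stop("record ", records$decamer[bad][1L], " has NA for key '", key, "'",
           call. = FALSE)
    }
  }
  ord <- order(records$total_matches, records$quiescence,
               records$human_seed_freq, records$decamer, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}
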