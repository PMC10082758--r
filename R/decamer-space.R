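# Stage 1-2: decamer enumeration and the miRNA seed-exclusion filter.

#' Enumerate all candidate 10-mer guide prefixes
#'
#' The first 10 bases of a candidate antisense (guide) strand determine its
#' seed; the cascade starts from the complete space of 4^10 = 1,048,576
#' decamers. Records are returned in lexicographic order (A < C < G < T) with
#' the seed (positions 2-7) pre-extracted.
#'
#' @return data.frame with columns `decamer` and `seed6`, 1,048,576 rows.
#' @export
#' @examples
#' d <- enumerate_decamers()
#' nrow(d)      # 1048576
#' d$decamer[1] # "AAAAAAAAAA"
enumerate_decamers <- function() {
  out <- DNA_BASES
  for (i in 2:10) out <- paste0(rep(out, each = 4L), DNA_BASES)
  data.frame(decamer = out, seed6 = substr(out, 2L, 7L))
}

#' Extract the set of miRNA seeds from mature sequences
#'
#' The seed of a mature miRNA is positions 2-7 of its 5'->3' sequence. Input
#' may be in the RNA alphabet (miRBase convention); U is normalised to T so
#' the set is directly comparable with decamer seeds.
#'
#' @param matures Character vector of mature miRNA sequences, each >= 7 nt.
#' @return Sorted character vector of unique 6-mer seeds (DNA alphabet).
#' @export
#' @examples
#' mirna_seed_set("ACGUACGUACGUACGUACG")  # "CGTACG"
mirna_seed_set <- function(matures) {
  if (length(matures) == 0L) return(character(0))
  matures <- normalize_dna(matures)
  short <- nchar(matures) < 7L
  if (any(short)) {
    id <- if (!is.null(names(matures))) names(matures)[short][1L] else
      paste0("entry ", which(short)[1L])
    stop("mature miRNA shorter than 7 nt: ", id, call. = FALSE)
  }
  check_dna(matures, "mature miRNA")
  sort(unique(substr(matures, 2L, 7L)))
}

#' Remove decamers whose seed matches an endogenous miRNA seed
#'
#' Seed comparison is exact string equality of positions 2-7 after U->T
#' normalisation; retained records keep their original order.
#'
#' @param decamers data.frame from [enumerate_decamers()] (or a character
#'   vector of decamers).
#' @param seeds Character vector of 6-mer seeds, e.g. from [mirna_seed_set()].
#' @return The retained subset of `decamers`.
#' @export
filter_mirna_seeds <- function(decamers, seeds) {
  decamers <- as_decamer_frame(decamers)
  if (length(seeds)) check_dna(seeds, "seed", len = 6L)
  out <- decamers[!(decamers$seed6 %in% seeds), , drop = FALSE]
  rownames(out) <- NULL
  out
}
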