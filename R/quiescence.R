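# Stage 3: quiescence scoring and the lowest-quartile filter.
#
# "Quiescence" is a predicted off-target silencing propensity for a guide
# prefix: lower = fewer predicted seed-mediated engagements with the
# endogenous transcriptome. Any scorer with that orientation can be plugged
# into the pipeline; the surrogate below is the package default.

#' Surrogate quiescence score: seed-complementary gene count
#'
#' Scores each decamer by the number of genes whose 3'UTR contains at least
#' one occurrence of the reverse complement of decamer positions 2-8 (the
#' seed-complementary 7-mer target site). Lower = more quiescent. This is a
#' transparent, documented stand-in for an arbitrary off-target prediction
#' model and defines the scorer contract: `f(decamers, utrs) -> numeric`,
#' deterministic, lower = safer.
#'
#' @param decamers data.frame with a `decamer` column, or character vector.
#' @param utrs Named character vector of per-gene 3'UTR sequences (non-empty).
#' @return Numeric vector of scores, one per decamer.
#' @export
#' @examples
#' score_quiescence_surrogate("TACGTACGTA", c(g1 = "CCCCCGTACGTCCCC"))
score_quiescence_surrogate <- function(decamers, utrs) {
  decamers <- as_decamer_frame(decamers)
  if (length(utrs) == 0L) stop("3'UTR collection is empty", call. = FALSE)
  check_dna(utrs, "3'UTR")
  targets <- revcomp(substr(decamers$decamer, 2L, 8L))
  hits <- Biostrings::vcountPDict(
    Biostrings::PDict(Biostrings::DNAStringSet(targets)),
    Biostrings::DNAStringSet(utrs))
  as.numeric(rowSums(hits > 0L))
}

#' Retain the most quiescent quartile of decamers
#'
#' Tie-inclusive nearest-rank lower-quantile filter on the `quiescence`
#' column (see [nearest_rank_retain()]): with all-distinct scores exactly
#' `ceiling(fraction * n)` records survive; ties at the threshold are all
#' kept, which is how retained fractions above 25% arise.
#'
#' @param records data.frame with a numeric `quiescence` column.
#' @param fraction Retained lower fraction; default 0.25.
#' @return The retained subset, original order preserved.
#' @export
quartile_filter <- function(records, fraction = 0.25) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  if (is.null(records$quiescence)) {
    stop("records must carry a 'quiescence' column; run the scorer first",
         call. = FALSE)
  }
  out <- records[nearest_rank_retain(records$quiescence, fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
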