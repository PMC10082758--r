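# Internal helpers shared across stages.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single bases, no reversal
comp_base <- function(x) chartr("ACGT", "TGCA", x)

# U -> T, upper-case; accepts RNA or DNA input
normalize_dna <- function(x) chartr("U", "T", toupper(x))

check_dna <- function(x, what = "sequence", len = NULL) {
  if (length(x) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(what, " must be non-empty upper-case DNA (A/C/G/T); offending entry: ",
         deparse(substr(x[bad][1L], 1L, 30L)), call. = FALSE)
  }
  if (!is.null(len) && any(nchar(x) != len)) {
    stop(what, " must have length ", len, " nt, got ",
         paste(unique(nchar(x)[nchar(x) != len]), collapse = ","), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

check_range <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < min) {
    stop(what, " must be a non-empty integer range c(lo, hi) with lo >= ", min,
         call. = FALSE)
  }
  as.integer(x)
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

# Accept a data.frame with a `decamer` column or a bare character vector.
as_decamer_frame <- function(x) {
  if (is.character(x)) {
    check_dna(x, "decamer", len = 10L)
    return(data.frame(decamer = x, seed6 = substr(x, 2L, 7L)))
  }
  if (is.data.frame(x) && "decamer" %in% names(x)) {
    if (is.null(x$seed6)) x$seed6 <- substr(x$decamer, 2L, 7L)
    return(x)
  }
  stop("expected a character vector of decamers or a data.frame with a 'decamer' column",
       call. = FALSE)
}

#' Tie-inclusive nearest-rank lower-quantile retention
#'
#' With `n` scores the nearest-rank threshold is the `k`-th smallest score,
#' `k = ceiling(fraction * n)`; every score less than or equal to the threshold
#' is retained. Ties at the threshold are therefore always included, so the
#' retained fraction can exceed `fraction`.
#'
#' @param scores Numeric vector (lower = better).
#' @param fraction Retained lower fraction, in (0, 1].
#' @return Logical vector marking retained entries.
#' @export
#' @examples
#' nearest_rank_retain(c(1, 2, 3, 4), 0.25)  # only the 1
#' nearest_rank_retain(c(5, 5, 5, 5), 0.25)  # all retained through ties
nearest_rank_retain <- function(scores, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  }
  n <- length(scores)
  if (n == 0L) return(logical(0))
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  k <- ceiling(fraction * n)
  threshold <- sort(scores, method = "quick")[k]
  scores <= threshold
}
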