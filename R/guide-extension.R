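# Stage 6: 23-mer extension, position-weighted ungapped alignment scoring,
# worst-aligned selection, final ranking and duplex construction.

#' Position-weighted mismatch penalty scheme
#'
#' Per-guide-position penalties for a mismatch between a 23-mer guide and an
#' antiparallel transcript window: the seed (positions 2-9) dominates
#' microRNA-like off-target recognition and is weighted 2.8; the central
#' cleavage-site positions 10-11 get 1.2; the 3' supplementary region 12-19
#' gets 1.0; position 1 and the 3' terminus 20-23 are not read out by RISC and
#' get 0. The maximum total over a fully mismatched window is 32.8.
#'
#' @return Numeric vector of length 23 (index = guide position, 5'->3').
#' @export
#' @examples
#' sum(penalty_scheme())  # 32.8
penalty_scheme <- function() {
  p <- numeric(23)
  p[2:9] <- 2.8
  p[10:11] <- 1.2
  p[12:19] <- 1.0
  p
}

check_scheme <- function(scheme) {
  if (!is.numeric(scheme) || length(scheme) != 23L || anyNA(scheme) ||
      any(scheme < 0) || any(scheme >= 1000)) {
    stop("penalty scheme must be 23 non-negative finite values", call. = FALSE)
  }
  scheme
}

# integer penalties (scale 1e4) keep mismatch-penalty sums and ties exact
scheme_int <- function(scheme) as.integer(round(check_scheme(scheme) * 1e4))

#' Extend a decamer into random 23-mer guide candidates
#'
#' Appends `n` independently uniform random 13-mers (sampled with
#' replacement; duplicates permitted) to the 10-mer prefix.
#'
#' @param decamer A 10-mer guide prefix.
#' @param n Number of candidates; the cascade default is 10,000.
#' @param rng_seed Integer seed; extension is deterministic given it.
#' @return Character vector of `n` 23-mers sharing the 10-mer prefix.
#' @export
extend_decamer <- function(decamer, n = 10000L, rng_seed = 1L) {
  check_dna(decamer, "decamer", len = 10L)
  n <- check_count(n, "n", min = 1L)
  suffixes <- withr::with_seed(rng_seed, {
    m <- matrix(sample(DNA_BASES, 13L * n, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
  paste0(decamer, suffixes)
}

#' Weighted ungapped penalty of a guide against one transcript window
#'
#' The guide pairs antiparallel with the window: guide position `p` lies
#' opposite window position `24 - p`. The penalty is the sum of `scheme[p]`
#' over all positions where the opposite window base is not the Watson-Crick
#' complement of the guide base. 0 means a perfect (fully complementary)
#' site; larger is safer.
#'
#' @param guide 23-mer guide (antisense) sequence.
#' @param window 23-nt transcript sense subsequence.
#' @param scheme Penalty vector, by default [penalty_scheme()].
#' @return A single numeric penalty in `[0, sum(scheme)]`.
#' @export
#' @examples
#' g <- strrep("A", 23)
#' window_penalty(g, strrep("T", 23))  # 0: perfect complementarity
window_penalty <- function(guide, window, scheme = penalty_scheme()) {
  check_dna(guide, "guide", len = 23L)
  check_dna(window, "window", len = 23L)
  check_scheme(scheme)
  g <- strsplit(guide, "")[[1L]]
  opposite <- rev(strsplit(window, "")[[1L]])   # window position 24 - p
  sum(scheme[g != comp_base(opposite)])
}

#' Alignment profile: best (lowest-penalty) window anywhere in the references
#'
#' For each candidate guide, the profile is the minimum [window_penalty()]
#' over every length-23 window of every transcript in every reference
#' transcriptome - i.e. the single most dangerous potential off-target site.
#' "Most poorly aligned" candidates have the LARGEST profiles. If no
#' transcript offers a length-23 window the profile is `Inf` (no off-target
#' site is possible at all).
#'
#' When all guides share a common 10-mer prefix (the extension stage always
#' produces such batches) a prefix-factored scan is used: per-window prefix
#' penalties are computed once and windows are visited in ascending order of
#' that bound.
#'
#' @param guides Character vector of 23-mer guides.
#' @param transcriptomes A `transcriptome`, a character vector of transcripts,
#'   or a (named) list of either.
#' @param scheme Penalty vector, by default [penalty_scheme()].
#' @return data.frame with columns `antisense`, `profile` (overall minimum),
#'   `n_best` (number of windows attaining it), and one `profile.<species>`
#'   column per reference.
#' @export
alignment_profile <- function(guides, transcriptomes, scheme = penalty_scheme()) {
  check_dna(guides, "guide", len = 23L)
  refs <- as_reference_list(transcriptomes)
  p10 <- scheme_int(scheme)
  shared_prefix <- length(guides) > 1L &&
    length(unique(substr(guides, 1L, 10L))) == 1L
  per <- lapply(refs, function(txs) {
    if (length(txs)) check_dna(txs, "transcript")
    if (length(txs) == 0L) {
      list(profile = rep(Inf, length(guides)),
           n_best = integer(length(guides)))
    } else if (shared_prefix) {
      cpp_profile_scan_prefix(substr(guides[1L], 1L, 10L),
                              substr(guides, 11L, 23L), txs, p10)
    } else {
      cpp_profile_scan(guides, txs, p10)
    }
  })
  pmat <- vapply(per, function(z) z$profile, numeric(length(guides)))
  nmat <- vapply(per, function(z) z$n_best, integer(length(guides)))
  if (length(guides) == 1L) {
    pmat <- matrix(pmat, nrow = 1L)
    nmat <- matrix(nmat, nrow = 1L)
  }
  profile <- do.call(pmin, lapply(seq_along(refs), function(j) pmat[, j]))
  n_best <- as.integer(rowSums(nmat * (pmat == profile)))
  out <- data.frame(antisense = guides, profile = profile, n_best = n_best)
  for (j in seq_along(refs)) out[[paste0("profile.", names(refs)[j])]] <- pmat[, j]
  out
}

#' Select the k most poorly aligned candidates
#'
#' Retains the `k` candidates with the LARGEST alignment profiles (the
#' safest: their best potential off-target site is still heavily mismatched).
#' Ties are broken by fewer windows attaining the minimum, then
#' lexicographically by antisense sequence. Fewer than `k` candidates are
#' returned as-is (re-ordered).
#'
#' @param candidates data.frame from [alignment_profile()] (columns
#'   `antisense`, `profile`, `n_best`).
#' @param k Number to retain; the cascade default is 10.
#' @return The selected rows, best (largest profile) first.
#' @export
select_worst_aligned <- function(candidates, k = 10L) {
  stopifnot(is.data.frame(candidates),
            all(c("antisense", "profile", "n_best") %in% names(candidates)))
  k <- check_count(k, "k", min = 1L)
  ord <- order(-candidates$profile, candidates$n_best, candidates$antisense,
               method = "radix")
  out <- candidates[head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Final ranking of retained guide candidates
#'
#' Descending by alignment profile (most poorly aligned to every reference
#' first), then ascending by the parent decamer's quiescence score, then
#' lexicographically by antisense sequence.
#'
#' @param candidates data.frame with columns `antisense`, `profile`,
#'   `quiescence`.
#' @return `candidates` reordered with a `rank` column prepended.
#' @export
final_rank <- function(candidates) {
  stopifnot(is.data.frame(candidates),
            all(c("antisense", "profile", "quiescence") %in% names(candidates)))
  ord <- order(-candidates$profile, candidates$quiescence, candidates$antisense,
               method = "radix")
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Build an siRNA duplex from a 23-mer antisense strand
#'
#' The duplex convention: a 21-nt sense (passenger) strand equal to the
#' reverse complement of antisense positions 1-21, leaving antisense positions
#' 22-23 as a 2-nt 3' overhang on the guide strand.
#'
#' @param antisense 23-mer antisense (guide) sequence, 5'->3'.
#' @return List of class `sirna_duplex` with elements `antisense` (23 nt) and
#'   `sense` (21 nt).
#' @export
#' @examples
#' make_duplex(strrep("A", 23))$sense  # 21 T's
make_duplex <- function(antisense) {
  check_dna(antisense, "antisense", len = 23L)
  structure(list(antisense = antisense,
                 sense = revcomp(substr(antisense, 1L, 21L))),
            class = "sirna_duplex")
}

#' @export
print.sirna_duplex <- function(x, ...) {
  cat("<sirna_duplex>\n",
      " antisense 5'-", x$antisense, "-3' (23 nt)\n",
      " sense     5'-", x$sense, "-3' (21 nt; 2-nt guide 3' overhang)\n",
      sep = "")
  invisible(x)
}
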