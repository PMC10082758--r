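# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (no Biostrings, no C++): plain loops and substr only.

o_rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

rand_dna <- function(len, n = 1L) {
  vapply(seq_len(n), function(.)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# overlapping occurrences of `pattern` in each of `txts`, summed
o_count_occurrences <- function(pattern, txts) {
  k <- nchar(pattern)
  total <- 0L
  for (s in txts) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1L)) {
      if (substr(s, i, i + k - 1L) == pattern) total <- total + 1L
    }
  }
  total
}

# per-position weighted mismatch penalty, guide antiparallel to window
o_window_penalty <- function(guide, window, scheme) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  g <- strsplit(guide, "")[[1]]
  w <- strsplit(window, "")[[1]]
  tot <- 0
  for (p in 1:23) {
    if (w[24 - p] != comp[[g[p]]]) tot <- tot + scheme[p]
  }
  tot
}

# exhaustive all-window minimum penalty (and how many windows attain it)
o_profile <- function(guide, txts, scheme) {
  best <- Inf
  cnt <- 0L
  for (s in txts) {
    n <- nchar(s)
    if (n < 23L) next
    for (i in 1:(n - 22L)) {
      p <- o_window_penalty(guide, substr(s, i, i + 22L), scheme)
      if (p < best) {
        best <- p
        cnt <- 1L
      } else if (p == best) cnt <- cnt + 1L
    }
  }
  list(profile = best, n_best = cnt)
}

# tie-inclusive nearest-rank lower-quantile retention
o_nearest_rank <- function(scores, fraction) {
  if (length(scores) == 0L) return(logical(0))
  threshold <- sort(scores)[ceiling(fraction * length(scores))]
  scores <= threshold
}

# canonical-site scan: every occurrence of the seed-complementary 6-mer core,
# classified by its flanking bases (one class per core occurrence)
o_scan_sites <- function(guide, utr) {
  core <- o_rc(substr(guide, 2, 7))
  m8 <- chartr("ACGT", "TGCA", substr(guide, 8, 8))
  n <- nchar(utr)
  rows <- list()
  if (n >= 6L) {
    for (j in 1:(n - 5L)) {
      if (substr(utr, j, j + 5L) != core) next
      has_m8 <- j > 1L && substr(utr, j - 1L, j - 1L) == m8
      has_a1 <- j + 6L <= n && substr(utr, j + 6L, j + 6L) == "A"
      row <- if (has_m8 && has_a1) {
        data.frame(start = j - 2L, end = j + 6L, site_class = "8mer")
      } else if (has_m8) {
        data.frame(start = j - 2L, end = j + 5L, site_class = "7mer-m8")
      } else if (has_a1) {
        data.frame(start = j - 1L, end = j + 6L, site_class = "7mer-A1")
      }
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# longest-common-substring length via row-wise dynamic programming
o_lcs_len <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- integer(length(B))
  best <- 0L
  for (ca in A) {
    cur <- ifelse(B == ca, c(0L, prev[-length(prev)]) + 1L, 0L)
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# small shared fixtures
fixture_guide <- function(seed = 11L) {
  withr::with_seed(seed, rand_dna(23))
}
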