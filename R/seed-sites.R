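# Canonical seed-matched site annotation in 3'UTRs and reporter-insert
# construction.

TANDEM_SPACER <- "TAATATTACATAAATAAAA"  # 19-nt spacer between tandem seed sites

#' Canonical target-site sequence for a guide
#'
#' Site patterns on the mRNA sense strand, in the standard canonical-site
#' nomenclature (guide positions are 1-based from the antisense 5' end):
#' * `8mer`: reverse complement of guide positions 2-8, followed by A (8 nt);
#' * `7mer-m8`: reverse complement of guide positions 2-8 (7 nt);
#' * `7mer-A1`: reverse complement of guide positions 2-7, followed by A (7 nt);
#' * `full_23`: reverse complement of the full 23-mer guide (23 nt).
#'
#' @param guide Guide (antisense) sequence; >= 8 nt (23 nt for `full_23`).
#' @param site_type One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"full_23"`.
#' @return The site sequence (DNA, mRNA sense strand).
#' @export
canonical_site <- function(guide,
                           site_type = c("8mer", "7mer-m8", "7mer-A1", "full_23")) {
  site_type <- match.arg(site_type)
  check_dna(guide, "guide")
  if (site_type == "full_23") {
    check_dna(guide, "guide", len = 23L)
    return(revcomp(guide))
  }
  if (nchar(guide) < 8L) stop("guide must be at least 8 nt", call. = FALSE)
  switch(site_type,
         "8mer" = paste0(revcomp(substr(guide, 2L, 8L)), "A"),
         "7mer-m8" = revcomp(substr(guide, 2L, 8L)),
         "7mer-A1" = paste0(revcomp(substr(guide, 2L, 7L)), "A"))
}

#' Find canonical seed-matched sites in a 3'UTR
#'
#' Scans for every occurrence of the guide's seed-complementary core (reverse
#' complement of positions 2-7) and classifies each occurrence by its
#' flanking bases: a match to position 8's complement immediately upstream
#' plus an A immediately downstream makes an 8mer; the m8 match alone a
#' 7mer-m8; the A alone a 7mer-A1. Each core occurrence is therefore
#' reported under exactly one class (precedence 8mer > 7mer-m8 > 7mer-A1),
#' and overlapping occurrences at distinct starts are all reported.
#'
#' @param guide Guide (antisense) sequence, >= 8 nt.
#' @param utr UTR sequence (mRNA sense strand, DNA alphabet).
#' @return data.frame with columns `start`, `end` (0-based, half-open UTR
#'   coordinates), `site_class` and `site_seq`, ordered by `start`.
#' @export
#' @examples
#' g <- "TACGTACGTAGGGGGGGGGGGGG"
#' find_canonical_sites(g, plant_site(strrep("C", 30), g, "8mer", 10))
find_canonical_sites <- function(guide, utr) {
  check_dna(guide, "guide")
  if (nchar(guide) < 8L) stop("guide must be at least 8 nt", call. = FALSE)
  check_dna(utr, "utr")
  core <- revcomp(substr(guide, 2L, 7L))          # 6-mer seed complement
  m8 <- comp_base(substr(guide, 8L, 8L))          # base pairing guide pos 8
  n <- nchar(utr)
  empty <- data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), site_seq = character(0))
  if (n < 6L) return(empty)
  starts <- Biostrings::start(
    Biostrings::matchPattern(core, Biostrings::DNAString(utr)))
  if (length(starts) == 0L) return(empty)
  rows <- lapply(starts, function(j) {
    has_m8 <- j > 1L && substr(utr, j - 1L, j - 1L) == m8
    has_a1 <- j + 6L <= n && substr(utr, j + 6L, j + 6L) == "A"
    if (has_m8 && has_a1) {
      data.frame(start = j - 2L, end = j + 6L, site_class = "8mer")
    } else if (has_m8) {
      data.frame(start = j - 2L, end = j + 5L, site_class = "7mer-m8")
    } else if (has_a1) {
      data.frame(start = j - 1L, end = j + 6L, site_class = "7mer-A1")
    } else {
      NULL
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$site_seq <- substr(rep(utr, nrow(out)), out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Annotate canonical sites across a per-gene UTR collection
#'
#' @param guide Guide (antisense) sequence, >= 8 nt.
#' @param utrs Named character vector of per-gene 3'UTR sequences.
#' @return BED-like data.frame: `gene_id`, `start`, `end` (0-based,
#'   half-open), `site_class`.
#' @export
annotate_utr_sites <- function(guide, utrs) {
  per <- lapply(names(utrs), function(g) {
    s <- find_canonical_sites(guide, utrs[[g]])
    if (nrow(s) == 0L) return(NULL)
    cbind(gene_id = g, s[c("start", "end", "site_class")])
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0L) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), site_class = character(0)))
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Gene-level canonical-site summary
#'
#' Per-gene site counts by class plus a has-site flag, suitable for joining
#' to an external differential-expression table (e.g. for colouring an MA
#' plot by seed-site content).
#'
#' @param guide Guide (antisense) sequence, >= 8 nt.
#' @param utrs Named character vector of per-gene 3'UTR sequences.
#' @return data.frame with columns `gene_id`, `n_8mer`, `n_7mer_m8`,
#'   `n_7mer_a1`, `n_sites`, `has_site`.
#' @export
classify_genes <- function(guide, utrs) {
  rows <- lapply(names(utrs), function(g) {
    s <- find_canonical_sites(guide, utrs[[g]])
    data.frame(gene_id = g,
               n_8mer = sum(s$site_class == "8mer"),
               n_7mer_m8 = sum(s$site_class == "7mer-m8"),
               n_7mer_a1 = sum(s$site_class == "7mer-A1"),
               n_sites = nrow(s))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_8mer = integer(0),
               n_7mer_m8 = integer(0), n_7mer_a1 = integer(0),
               n_sites = integer(0))
  out$has_site <- out$n_sites >= 1L
  out
}

#' Construct a dual-luciferase reporter 3'UTR insert
#'
#' Reporter inserts for validating a designed duplex:
#' * `on_target`: one site fully complementary to the 23-mer antisense strand
#'   (23 nt);
#' * `seed_1x`: one 8-nt site complementary to antisense positions 2-9;
#' * `seed_4x`: four such sites in tandem, separated by three copies of the
#'   19-nt spacer `TAATATTACATAAATAAAA` (89 nt total).
#'
#' Restriction-site flanks are not added by default; pass `flank5`/`flank3`
#' to wrap the insert for a specific cloning context.
#'
#' @param antisense 23-mer antisense (guide) sequence.
#' @param kind One of `"on_target"`, `"seed_1x"`, `"seed_4x"`.
#' @param spacer Spacer between tandem seed sites (19 nt default).
#' @param flank5,flank3 Optional flanking sequences.
#' @return List of class `reporter_insert` with elements `kind`, `site`,
#'   `spacer`, `insert`.
#' @export
#' @examples
#' nchar(build_reporter_insert(strrep("A", 23), "seed_4x")$insert)  # 89
build_reporter_insert <- function(antisense,
                                  kind = c("on_target", "seed_1x", "seed_4x"),
                                  spacer = TANDEM_SPACER,
                                  flank5 = "", flank3 = "") {
  kind <- match.arg(kind)
  check_dna(antisense, "antisense", len = 23L)
  site <- if (kind == "on_target") revcomp(antisense) else
    revcomp(substr(antisense, 2L, 9L))
  insert <- if (kind == "seed_4x") {
    check_dna(spacer, "spacer")
    paste(rep(site, 4L), collapse = spacer)
  } else {
    site
  }
  structure(list(kind = kind, site = site,
                 spacer = if (kind == "seed_4x") spacer else NA_character_,
                 insert = paste0(flank5, insert, flank3)),
            class = "reporter_insert")
}

#' @export
print.reporter_insert <- function(x, ...) {
  cat("<reporter_insert> kind:", x$kind, "|", nchar(x$insert), "nt\n ",
      x$insert, "\n")
  invisible(x)
}
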