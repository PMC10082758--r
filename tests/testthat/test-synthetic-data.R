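test_that("generator is seeded-deterministic and respects counts", {
  p <- synthetic_params(n_genes = 5, isoforms_per_gene = c(1, 3),
                        exon_block_length = c(40, 80), blocks_per_gene = c(2, 4),
                        utr_length = c(30, 60), rng_seed = 42)
  tx1 <- generate_transcriptome(p, species = "sp")
  tx2 <- generate_transcriptome(p, species = "sp")
  expect_identical(tx1, tx2)

  mp <- gene_map(tx1)
  expect_equal(length(tx1$genes), 5)
  expect_true(nrow(mp) >= 5 && nrow(mp) <= 15)
  expect_false(anyDuplicated(mp$transcript_id) > 0)
  # every transcript maps to exactly one gene
  expect_equal(sort(mp$transcript_id), sort(names(transcript_seqs(tx1))))

  # empty case
  tx0 <- generate_transcriptome(synthetic_params(n_genes = 0))
  expect_equal(length(tx0$genes), 0)
  expect_equal(length(transcript_seqs(tx0)), 0)
})

test_that("each gene UTR is a suffix of an isoform and isoforms share blocks", {
  p <- synthetic_params(n_genes = 8, isoforms_per_gene = c(2, 3),
                        exon_block_length = c(30, 60), blocks_per_gene = c(2, 4),
                        utr_length = c(25, 50), rng_seed = 7)
  tx <- generate_transcriptome(p)
  expect_silent(validate_transcriptome(tx))
  utrs <- utr_seqs(tx)
  expect_equal(sort(names(utrs)), sort(names(tx$genes)))
  for (g in names(tx$genes)) {
    expect_true(any(endsWith(tx$genes[[g]], utrs[[g]])))
    iso <- tx$genes[[g]]
    if (length(iso) >= 2) {
      # any isoform pair shares a substring at least as long as the shortest block
      min_block <- min(p$exon_block_length[1], p$utr_length[1])
      for (a in 1:(length(iso) - 1)) {
        for (b in (a + 1):length(iso)) {
          expect_gte(o_lcs_len(iso[[a]], iso[[b]]), min_block)
        }
      }
    }
  }
})

test_that("transcriptome FASTA/TSV round trip is exact", {
  tx <- generate_transcriptome(synthetic_params(
    n_genes = 4, exon_block_length = c(30, 50), utr_length = c(20, 40),
    rng_seed = 3), species = "rt")
  dir <- withr::local_tempdir()
  paths <- write_transcriptome(tx, dir)
  back <- read_transcriptome(paths[["fasta"]], paths[["map"]],
                             utr_fasta = paths[["utr"]], species = "rt")
  expect_identical(back, tx)

  # byte-identical FASTA on regeneration with the same seed
  tx2 <- generate_transcriptome(synthetic_params(
    n_genes = 4, exon_block_length = c(30, 50), utr_length = c(20, 40),
    rng_seed = 3), species = "rt")
  dir2 <- withr::local_tempdir()
  paths2 <- write_transcriptome(tx2, dir2)
  expect_identical(readLines(paths[["fasta"]]), readLines(paths2[["fasta"]]))
})

test_that("miRNA set generation and FASTA round trip behave", {
  expect_identical(generate_mirna_set(0), character(0))
  m <- generate_mirna_set(10, c(19, 24), rng_seed = 9)
  expect_length(m, 10)
  expect_true(all(nchar(m) >= 19 & nchar(m) <= 24))
  expect_true(all(grepl("^[ACGU]+$", m)))
  expect_identical(m, generate_mirna_set(10, c(19, 24), rng_seed = 9))

  path <- withr::local_tempfile(fileext = ".fa")
  write_mirna_fasta(m, path)
  expect_identical(read_mirna_fasta(path), m)
})

test_that("plant_site substitutes the requested canonical site in place", {
  g <- fixture_guide()

  # a C background cannot extend a site to an 8mer (no downstream A)
  planted <- plant_site(strrep("C", 40), g, "7mer-m8", 12)
  expect_equal(nchar(planted), 40)
  found <- find_canonical_sites(g, planted)
  expect_true(any(found$site_class == "7mer-m8" & found$start == 11))

  # full-complementarity site equals the reverse complement of the guide
  planted23 <- plant_site(strrep("A", 40), g, "full_23", 5)
  expect_identical(substr(planted23, 5, 27), o_rc(g))

  # planting into an all-A UTR: brute-force scan finds exactly the planted site
  pat <- canonical_site(g, "7mer-m8")
  planted_a <- plant_site(strrep("A", 40), g, "7mer-m8", 12)
  expect_equal(o_count_occurrences(pat, planted_a), 1L)

  expect_error(plant_site(strrep("A", 10), g, "full_23", 5), "does not fit")
})

test_that("invalid synthetic parameters are rejected", {
  expect_error(synthetic_params(base_composition = c(0.5, 0.5, 0.1, 0.1)),
               "sum")
  expect_error(synthetic_params(isoforms_per_gene = c(3, 1)), "range")
  expect_error(synthetic_params(n_genes = -1), "integer")
})
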