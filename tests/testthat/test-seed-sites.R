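test_that("canonical site patterns follow the standard definitions", {
  g <- fixture_guide()
  expect_identical(canonical_site(g, "8mer"),
                   paste0(o_rc(substr(g, 2, 8)), "A"))
  expect_identical(canonical_site(g, "7mer-m8"), o_rc(substr(g, 2, 8)))
  expect_identical(canonical_site(g, "7mer-A1"),
                   paste0(o_rc(substr(g, 2, 7)), "A"))
  expect_identical(canonical_site(g, "full_23"), o_rc(g))
  expect_error(canonical_site(substr(g, 1, 10), "full_23"), "23")
})

test_that("site classes obey the 8mer > 7mer-m8 > 7mer-A1 precedence", {
  # guide position 8 is A, so the C background can never supply an m8 match
  # (which pairs with T) and silently upgrade a planted 7mer-A1 to an 8mer
  g <- "TACGTACATAGGGGGGGGGGGGG"
  utr <- strrep("C", 60)

  # a planted 8mer is reported once, as 8mer only
  u8 <- plant_site(utr, g, "8mer", 20)
  s8 <- find_canonical_sites(g, u8)
  expect_equal(nrow(s8), 1)
  expect_identical(s8$site_class, "8mer")
  expect_equal(s8$start, 19)
  expect_equal(s8$end - s8$start, 8)

  # removing the downstream A reclassifies the site as 7mer-m8
  u7 <- u8
  substr(u7, 27, 27) <- "C"
  s7 <- find_canonical_sites(g, u7)
  expect_identical(s7$site_class, "7mer-m8")
  expect_equal(s7$start, 19)
  expect_equal(s7$end - s7$start, 7)

  # seed complement + A without the m8 match is a 7mer-A1
  ua <- plant_site(utr, g, "7mer-A1", 20)
  sa <- find_canonical_sites(g, ua)
  expect_identical(sa$site_class, "7mer-A1")
  expect_equal(sa$end - sa$start, 7)
})

test_that("site scanning agrees with the brute-force oracle on random UTRs", {
  withr::with_seed(71, {
    for (i in 1:15) {
      g <- rand_dna(23)
      # AT-rich UTRs raise the chance of real (including overlapping) hits
      utr <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                          prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
      # guarantee some structure: plant one site of each class
      utr <- plant_site(utr, g, "8mer", 10)
      utr <- plant_site(utr, g, "7mer-m8", 50)
      utr <- plant_site(utr, g, "7mer-A1", 90)
      got <- find_canonical_sites(g, utr)
      orc <- o_scan_sites(g, utr)
      expect_identical(got[c("start", "end", "site_class")], orc)
    }
  })
})

test_that("gene classification flags exactly the genes carrying sites", {
  g <- fixture_guide()
  withr::with_seed(72, utrs <- setNames(rand_dna(40, 6), paste0("g", 1:6)))
  base <- classify_genes(g, utrs)
  planted <- utrs
  planted[["g3"]] <- plant_site(planted[["g3"]], g, "8mer", 10)
  cls <- classify_genes(g, planted)
  expect_true(cls$has_site[cls$gene_id == "g3"])
  # flag is definitionally n_sites >= 1
  expect_identical(cls$has_site, cls$n_sites >= 1)
  # planting added exactly one 8mer to g3 relative to background
  expect_equal(cls$n_8mer[cls$gene_id == "g3"],
               base$n_8mer[base$gene_id == "g3"] + 1)

  # no sites anywhere -> all flags false (G/C-only UTRs cannot carry the A)
  gc_only <- setNames(rep(strrep("G", 30), 3), paste0("g", 1:3))
  g_at <- paste0("T", strrep("A", 22))  # seed complement needs T's
  expect_false(any(classify_genes(g_at, gc_only)$has_site))

  bed <- annotate_utr_sites(g, planted)
  expect_true(all(c("gene_id", "start", "end", "site_class") %in% names(bed)))
  expect_equal(sum(bed$gene_id == "g3"), cls$n_sites[cls$gene_id == "g3"])
})

test_that("reporter inserts match the published construction", {
  withr::with_seed(73, antisense <- rand_dna(23))

  on_t <- build_reporter_insert(antisense, "on_target")
  expect_identical(on_t$insert, o_rc(antisense))
  expect_equal(nchar(on_t$insert), 23)

  one <- build_reporter_insert(antisense, "seed_1x")
  expect_identical(one$insert, o_rc(substr(antisense, 2, 9)))
  expect_equal(nchar(one$insert), 8)

  four <- build_reporter_insert(antisense, "seed_4x")
  expect_equal(nchar(four$insert), 4 * 8 + 3 * 19)
  expect_identical(four$spacer, "TAATATTACATAAATAAAA")
  expect_identical(four$insert,
                   paste(rep(one$insert, 4), collapse = "TAATATTACATAAATAAAA"))

  # optional cloning flanks wrap without altering the core insert
  flanked <- build_reporter_insert(antisense, "seed_1x",
                                   flank5 = "CTCGAG", flank3 = "GCGGCCGC")
  expect_identical(flanked$insert, paste0("CTCGAG", one$insert, "GCGGCCGC"))

  expect_error(build_reporter_insert(substr(antisense, 1, 20), "seed_1x"), "23")
})

test_that("an embedded seed_1x insert is re-detected as a seed-matched site", {
  # cross-module loop: build insert -> embed in a UTR -> scan
  withr::with_seed(74, antisense <- rand_dna(23))
  insert <- build_reporter_insert(antisense, "seed_1x")$insert
  utr <- paste0(strrep("C", 20), insert, strrep("C", 20))
  found <- find_canonical_sites(antisense, utr)
  expect_gte(nrow(found), 1)
  expect_true(any(found$site_class %in% c("7mer-m8", "8mer")))
})
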