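test_that("penalty scheme matches the published position weights", {
  s <- penalty_scheme()
  expect_length(s, 23)
  expect_equal(s[2:9], rep(2.8, 8))
  expect_equal(s[10:11], rep(1.2, 2))
  expect_equal(s[12:19], rep(1.0, 8))
  expect_equal(s[c(1, 20:23)], rep(0, 5))
  expect_equal(sum(s), 32.8)
})

test_that("window penalty follows the per-position scheme", {
  withr::with_seed(51, g <- rand_dna(23))
  perfect <- o_rc(g)
  expect_equal(window_penalty(g, perfect), 0)

  flip_opposite <- function(window, p) {
    # corrupt the window base opposite guide position p
    q <- 24 - p
    old <- substr(window, q, q)
    substr(window, q, q) <- setdiff(c("A", "C", "G", "T"), old)[1]
    window
  }
  expect_equal(window_penalty(g, flip_opposite(perfect, 1)), 0)    # pos 1 free
  expect_equal(window_penalty(g, flip_opposite(perfect, 5)), 2.8)  # seed
  expect_equal(window_penalty(g, flip_opposite(perfect, 10)), 1.2)
  expect_equal(window_penalty(g, flip_opposite(perfect, 15)), 1.0)
  expect_equal(window_penalty(g, flip_opposite(perfect, 22)), 0)

  # every position mismatched -> the full 32.8: the reversed guide places the
  # guide's own base opposite every position, and no base is its own complement
  w <- paste(rev(strsplit(g, "")[[1]]), collapse = "")
  expect_equal(window_penalty(g, w), 32.8)

  expect_error(window_penalty(substr(g, 1, 10), perfect), "23")
})

test_that("window penalty equals the brute-force oracle on random pairs", {
  scheme <- penalty_scheme()
  withr::with_seed(52, {
    for (i in 1:200) {
      g <- rand_dna(23)
      w <- rand_dna(23)
      expect_equal(window_penalty(g, w, scheme), o_window_penalty(g, w, scheme))
    }
  })
})

test_that("extension emits seeded random 23-mers sharing the decamer prefix", {
  withr::with_seed(53, d <- rand_dna(10))
  cand <- extend_decamer(d, n = 200, rng_seed = 9)
  expect_length(cand, 200)
  expect_true(all(nchar(cand) == 23))
  expect_true(all(substr(cand, 1, 10) == d))
  expect_true(all(grepl("^[ACGT]+$", substr(cand, 11, 23))))
  expect_identical(cand, extend_decamer(d, n = 200, rng_seed = 9))
  expect_false(identical(cand, extend_decamer(d, n = 200, rng_seed = 10)))
})

test_that("alignment profile equals exhaustive all-window search", {
  scheme <- penalty_scheme()
  withr::with_seed(54, {
    txs <- c(rand_dna(60, n = 3), rand_dna(30, n = 2))
    guides <- rand_dna(23, n = 6)
  })
  got <- alignment_profile(guides, txs, scheme)
  for (i in seq_along(guides)) {
    orc <- o_profile(guides[i], txs, scheme)
    expect_equal(got$profile[i], orc$profile)
    expect_equal(got$n_best[i], orc$n_best)
  }

  # prefix-batch path agrees with the generic path and the oracle
  withr::with_seed(55, shared <- paste0(substr(rand_dna(23), 1, 10),
                                        rand_dna(13, n = 7)))
  batch <- alignment_profile(shared, txs, scheme)        # shared prefix path
  for (i in seq_along(shared)) {
    single <- alignment_profile(shared[i], txs, scheme)  # generic path
    orc <- o_profile(shared[i], txs, scheme)
    expect_equal(batch$profile[i], single$profile)
    expect_equal(batch$profile[i], orc$profile)
    expect_equal(batch$n_best[i], orc$n_best)
  }
})

test_that("profile handles absent windows and added transcripts monotonically", {
  withr::with_seed(56, g <- rand_dna(23))
  # all transcripts shorter than 23 nt -> no window -> +Inf sentinel
  expect_equal(alignment_profile(g, rand_dna(20, n = 3))$profile, Inf)

  # adding transcripts can only lower (or keep) the profile
  withr::with_seed(57, txs <- rand_dna(70, n = 6))
  prev <- Inf
  for (k in 1:6) {
    cur <- alignment_profile(g, txs[1:k])$profile
    expect_lte(cur, prev)
    prev <- cur
  }

  # a planted perfectly complementary site forces the profile to zero
  expect_equal(alignment_profile(g, c(txs, paste0("ACGT", o_rc(g), "AC")))$profile, 0)
})

test_that("per-species profiles combine into the overall minimum", {
  withr::with_seed(58, {
    g <- rand_dna(23)
    a <- rand_dna(50, n = 2)
    b <- c(rand_dna(50), paste0("GG", o_rc(g), "TT"))  # species b carries a perfect site
  })
  res <- alignment_profile(g, list(spA = a, spB = b))
  expect_named(res, c("antisense", "profile", "n_best", "profile.spA", "profile.spB"))
  expect_equal(res$profile.spB, 0)
  expect_equal(res$profile, pmin(res$profile.spA, res$profile.spB))
})

test_that("worst-aligned selection keeps the largest profiles with stated ties", {
  cand <- data.frame(
    antisense = c("C", "A", "B", "D", "E"),
    profile = c(0.0, 2.8, 32.8, 2.8, 2.8),
    n_best = c(1L, 5L, 1L, 2L, 2L))

  # k exceeding n returns everything
  expect_equal(nrow(select_worst_aligned(cand, 10)), 5)

  # max selection
  expect_identical(select_worst_aligned(cand, 1)$antisense, "B")

  # ties: fewer windows attaining the minimum first, then lexicographic
  top3 <- select_worst_aligned(cand, 3)
  expect_identical(top3$antisense, c("B", "D", "E"))

  all_equal <- data.frame(antisense = c("T", "G", "A", "C"),
                          profile = rep(1.2, 4), n_best = rep(1L, 4))
  expect_identical(select_worst_aligned(all_equal, 2)$antisense, c("A", "C"))
})

test_that("planting a perfect site excludes a candidate from selection", {
  # full-loop property: the planted candidate drops to profile 0 and out of
  # the worst-aligned (safest) set
  withr::with_seed(59, {
    d <- rand_dna(10)
    txs <- rand_dna(200, n = 4)
  })
  cand <- extend_decamer(d, n = 12, rng_seed = 3)
  planted_tx <- c(txs, paste0("AA", o_rc(cand[5]), "CC"))
  prof <- alignment_profile(cand, planted_tx)
  expect_equal(prof$profile[5], 0)
  sel <- select_worst_aligned(prof, 6)
  expect_false(cand[5] %in% sel$antisense)
})

test_that("final ranking is profile-descending then quiescence-ascending", {
  cand <- data.frame(
    antisense = c("B", "A", "D", "C"),
    profile = c(5.6, 32.8, 5.6, 5.6),
    quiescence = c(3, 1, 0, 0))
  ranked <- final_rank(cand)
  expect_identical(ranked$antisense, c("A", "C", "D", "B"))
  expect_identical(ranked$rank, 1:4)
  expect_identical(final_rank(cand[1, ])$antisense, "B")
})

test_that("duplex builder emits a 21-nt sense strand with a 2-nt guide overhang", {
  dx <- make_duplex(strrep("A", 23))
  expect_identical(dx$sense, strrep("T", 21))

  withr::with_seed(60, as <- rand_dna(23))
  dx <- make_duplex(as)
  expect_equal(nchar(dx$sense), 21)
  # pairing oracle: sense position q pairs with antisense position 22 - q
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (q in 1:21) {
    expect_identical(substr(dx$sense, q, q),
                     comp[[substr(dx$antisense, 22 - q, 22 - q)]])
  }
  expect_error(make_duplex(substr(as, 1, 21)), "23")
})
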