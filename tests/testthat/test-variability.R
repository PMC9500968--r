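test_that("site variability matches the Shannon entropy of the column", {
  expect_equal(site_variability(rep("A", 13)), 0)
  expect_equal(site_variability(LETTERS[1:13]), log2(13))
  expect_equal(site_variability(rep(c("A", "K"), each = 4)), 1.0)
  # frozen from entropy_oracle(c(3, 2, 1)) = 1.459148
  expect_equal(site_variability(c("A", "A", "A", "K", "K", "W")),
               entropy_oracle(c(3, 2, 1)))
  expect_equal(round(site_variability(c("A", "A", "A", "K", "K", "W")), 4),
               1.4591)
})

test_that("gaps and X are not amino-acid types", {
  expect_equal(site_variability(c("A", "A", "-", "X")), 0)
  expect_true(is.na(site_variability(c("-", "-", "X"))))
  # entropy bounds + permutation symmetry over random columns
  set.seed(5)
  for (i in 1:25) {
    col <- sample(mhcvar:::AA_ALPHABET, sample(2:20, 1), replace = TRUE)
    v <- site_variability(col)
    expect_gte(v, 0)
    expect_lte(v, log2(length(col)) + 1e-12)
    relab <- stats::setNames(sample(mhcvar:::AA_ALPHABET), mhcvar:::AA_ALPHABET)
    expect_equal(site_variability(unname(relab[col])), v)
  }
})

test_that("polymorphic-site calling uses a strict threshold", {
  fx <- make_variability_fixture(12, 25, c(`4` = 2, `10` = 4, `20` = 3),
                                 seed = 2)
  prof <- profile_alignment(fx$alignment)
  # k = 2 gives V = 1.0 exactly: not polymorphic under strict >
  expect_equal(prof$V[prof$site_1based == 4], 1.0)
  expect_false(prof$polymorphic[prof$site_1based == 4])
  expect_true(all(prof$polymorphic[prof$site_1based %in% c(10, 20)]))
  expect_equal(attr(prof, "n_polymorphic"), 2)

  # a domain of constant columns has zero polymorphic sites
  const <- make_variability_fixture(12, 10, seed = 3)
  expect_equal(attr(profile_alignment(const$alignment), "n_polymorphic"), 0)

  # count is monotone non-increasing in the threshold
  counts <- vapply(c(0, 0.5, 1, 1.5, 2, 4), function(th)
    attr(profile_alignment(fx$alignment, threshold = th), "n_polymorphic"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("no-data columns are flagged, not scored", {
  aln <- aligned_sequences(c(a = "A-C", b = "A-C", c = "AXC"))
  prof <- profile_alignment(aln)
  expect_true(is.na(prof$V[2]))
  expect_true(is.na(prof$polymorphic[2]))
  expect_equal(attr(prof, "n_polymorphic"), 0)
})

test_that("pairwise percent differences honour the deletion policy", {
  aln <- aligned_sequences(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA"))
  expect_equal(unname(pairwise_difference_matrix(aln)["a", "b"]), 0)

  aln <- aligned_sequences(c(a = "ACDEFGHIKL", b = "ACDEFGHMNP"))
  expect_equal(unname(pairwise_difference_matrix(aln)["a", "b"]), 30)

  aln <- aligned_sequences(c(a = "AC-DE", b = "ACQDF"))
  m <- pairwise_difference_matrix(aln, deletion = "pairwise")
  expect_equal(unname(m["a", "b"]), 25)          # 1 diff over 4 compared
  expect_equal(attr(m, "n_sites_used")["a", "b"], 4)

  # complete deletion drops the gap column for every pair
  aln3 <- aligned_sequences(c(a = "AC-DE", b = "ACQDE", c = "ACQDF"))
  mc <- pairwise_difference_matrix(aln3, deletion = "complete")
  expect_equal(attr(mc, "n_sites_used"), 4)
  expect_equal(unname(mc["a", "c"]), 25)

  # cross-module consistency: percent == 100 * p-distance
  fx <- make_variability_fixture(8, 40, c(`3` = 4, `11` = 2, `30` = 8),
                                 seed = 8)
  expect_equal(unclass(pairwise_difference_matrix(fx$alignment,
                                                  deletion = "pairwise")),
               100 * unclass(p_distance_matrix(fx$alignment,
                                               deletion = "pairwise")),
               ignore_attr = TRUE)

  expect_error(pairwise_difference_matrix(
    aligned_sequences(c(a = "A--", b = "-A-", c = "AAA"))), "pair a / b")
})

test_that("difference summaries use unique unordered pairs", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- m["b", "a"] <- 10
  m["a", "c"] <- m["c", "a"] <- 20
  m["b", "c"] <- m["c", "b"] <- 30
  s <- summarize_differences(m)
  expect_equal(s$min, 10); expect_equal(s$max, 30); expect_equal(s$mean, 20)
  expect_equal(s$sem, stats::sd(c(10, 20, 30)) / sqrt(3))
  expect_equal(round(s$sem, 4), 5.7735)

  all_eq <- matrix(5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(all_eq) <- 0
  expect_equal(summarize_differences(all_eq)$sem, 0)

  one_pair <- matrix(c(0, 7, 7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(s1 <- summarize_differences(one_pair), "undefined")
  expect_equal(s1$sem, 0)
  expect_equal(s1$mean, 7)
})

test_that("duplicating a sequence changes neither max difference nor M", {
  fx <- make_variability_fixture(6, 30, c(`5` = 3, `21` = 6), seed = 13)
  aln <- fx$alignment
  dup <- aligned_sequences(c(aln$seqs, dup1 = unname(aln$seqs[1])))
  expect_lte(max(pairwise_difference_matrix(dup)),
             max(pairwise_difference_matrix(aln)))
  expect_equal(profile_alignment(dup)$M[-c(5, 21)],
               profile_alignment(aln)$M[-c(5, 21)])
})
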