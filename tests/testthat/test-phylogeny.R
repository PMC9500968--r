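test_that("p-distance removes ambiguous positions per policy", {
  expect_equal(p_distance("ACDE", "ACDE"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AC-DE", "ACQDF"), 0.25)  # 1 diff / 4 compared

  ctx <- aligned_sequences(c(s1 = "AC-DE", s2 = "ACQDE", s3 = "ACQDF"))
  expect_equal(p_distance("AC-DE", "ACQDF", deletion = "complete",
                          context = ctx), 0.25)
  m <- p_distance_matrix(ctx, deletion = "complete")
  expect_equal(unname(m["s1", "s3"]), 0.25)
  expect_equal(attr(m, "n_sites_used"), 4)
  expect_error(p_distance("A-", "-A"), "no comparable")
})

test_that("Poisson correction is -ln(1-p), monotone, undefined at saturation", {
  expect_equal(poisson_distance(0), 0)
  expect_equal(poisson_distance(0.5), -log(0.5))
  expect_equal(round(poisson_distance(0.5), 6), 0.693147)
  expect_error(poisson_distance(1), "saturated")
  p <- seq(0, 0.95, by = 0.05)
  d <- poisson_distance(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("NJ handles 2- and 3-taxon closed forms", {
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(m2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  m3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m3["a", "b"] <- m3["b", "a"] <- 0.4
  m3["a", "c"] <- m3["c", "a"] <- 0.6
  m3["b", "c"] <- m3["c", "b"] <- 0.8
  t3 <- nj_tree(m3)
  pend <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(pend[c("a", "b", "c")], c(a = 0.1, b = 0.3, c = 0.5))
})

test_that("NJ recovers additive trees exactly", {
  for (seed in 1:30) {
    n <- 4 + (seed %% 5)
    ra <- random_additive(n, seed)
    tr <- nj_tree(ra$dm)
    expect_equal(rf_dist(tr, ra$tree), 0)
    expect_equal(stats::cophenetic(tr)[rownames(ra$dm), colnames(ra$dm)],
                 ra$dm, tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6
    ra <- random_additive(n, seed + 100)
    noisy <- ra$dm + matrix(stats::runif(n * n, 0, 0.01), n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    expect_equal(rf_dist(nj_tree(noisy), ape::nj(noisy)), 0)
  }
})

test_that("NJ validates its input and clamps negative branch lengths", {
  m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(m), "symmetric")
  m2 <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(m2), "negative")
  # a strongly non-additive matrix that produces negative NJ estimates
  labs <- letters[1:4]
  m4 <- matrix(c(0, 1, 1, 1,
                 1, 0, 1, 1,
                 1, 1, 0, 1,
                 1, 1, 1, 0.0), 4, dimnames = list(labs, labs))
  m4["a", "b"] <- m4["b", "a"] <- 1.9
  tr <- nj_tree(m4)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are certain for a clean split, reproducible, and order-invariant", {
  aln <- two_pair_alignment(L = 30)
  tr <- bootstrap_support(aln, replicates = 200, seed = 7)
  sup <- suppressWarnings(as.integer(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_equal(sup, 100)  # the {a1,a2} | {b1,b2} split in every replicate
  expect_equal(attr(tr, "n_discarded"), 0)

  # same seed, same supports; different leaf order, same supports
  tr2 <- bootstrap_support(aln, replicates = 200, seed = 7)
  expect_identical(tr$node.label, tr2$node.label)
  perm <- aligned_sequences(aln$seqs[c(3, 1, 4, 2)])
  tr3 <- bootstrap_support(perm, replicates = 200, seed = 7)
  expect_identical(tr$node.label, tr3$node.label)

  sim <- simulate_family(n_lineages = 2, seqs_per_lineage = 4,
                         domain_lengths = c(d = 60), rate_within = 0.1,
                         divergence_between = 0.4, seed = 5)
  trs <- bootstrap_support(sim$alignment, replicates = 100, seed = 11)
  sups <- suppressWarnings(as.integer(trs$node.label))
  sups <- sups[!is.na(sups)]
  expect_true(all(sups >= 0 & sups <= 100))
  expect_error(bootstrap_support(sim$alignment, replicates = 100, seed = 11,
                                 deletion = "complete", domain = "nope"),
               "no such domain")
})

test_that("lineage assignment follows the smallest uniform reference clade", {
  tr <- ape::read.tree(text = paste0(
    "(((q1:0.1,u1:0.1)95:0.2,u2:0.3)90:0.1,(z1:0.1,z2:0.1)99:0.3,q2:0.5);"))
  refs <- c(u1 = "U", u2 = "U", z1 = "Z", z2 = "Z")
  calls <- assign_lineage(tr, refs, c("q1", "q2"))
  expect_equal(calls$lineage[calls$query == "q1"], "U")
  expect_equal(calls$support[calls$query == "q1"], 95)
  # q2's smallest reference-containing side is {z1,z2,q2}: uniform Z
  expect_equal(calls$lineage[calls$query == "q2"], "Z")
  expect_error(assign_lineage(tr, refs, "ghost"), "absent")

  # a query equidistant from two mixed clades has no uniform smallest side
  tr2 <- ape::read.tree(text = "((u1:1,z1:1)90:1,(u2:1,z2:1)80:1,q:1);")
  mixed <- assign_lineage(tr2, refs, "q")
  expect_equal(mixed$lineage, "unassigned")
  expect_true(is.na(mixed$support))
})

test_that("simulated lineages are recovered through the full tree pipeline", {
  sim <- simulate_family(n_lineages = 3, seqs_per_lineage = 4,
                         rate_within = 0.05, divergence_between = 0.5,
                         domain_lengths = c(d = 120), seed = 21)
  tree <- bootstrap_support(sim$alignment, replicates = 100, seed = 4)
  truth <- sim$truth$lineages
  queries <- c("U1", "Z1", "S1")
  refs <- truth[!names(truth) %in% queries]
  calls <- assign_lineage(tree, refs, queries)
  expect_equal(stats::setNames(calls$lineage, calls$query),
               truth[queries], ignore_attr = FALSE)
})
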