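# Independent oracles, kept free of the package's own code paths.

# Shannon entropy by direct summation over a count table
entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# random unrooted tree with exponential branch lengths + its path matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::rexp(k, rate = 5) + 0.05)
  dm <- stats::cophenetic(tr)
  list(tree = tr, dm = dm[sort(rownames(dm)), sort(rownames(dm))])
}

# exhaustive least-squares topology search (feasible to ~6 taxa)
ls_best_topology <- function(dm) {
  labs <- rownames(dm)
  tops <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  ss <- vapply(seq_along(tops), function(i) {
    fit <- phangorn::nnls.tree(dm, tops[[i]], method = "unrooted")
    sum((stats::cophenetic(fit)[labs, labs] - dm)^2)
  }, numeric(1))
  tops[[which.min(ss)]]
}

rf_dist <- function(a, b) phangorn::RF.dist(a, b)
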