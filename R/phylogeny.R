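#' Pairwise p-distance
#'
#' Fraction of compared columns at which two aligned protein sequences
#' differ. Ambiguous positions (gap or `X`) are removed before comparison:
#' under `pairwise` deletion, only those of the pair itself; under
#' `complete` deletion, every column that is ambiguous in any sequence of
#' the context set is removed first, so all pairs share one column set (as
#' in a "final dataset of N positions" reported by standard phylogenetics
#' software).
#'
#' @param a,b Aligned protein sequences (character scalars, equal length).
#' @param deletion `"pairwise"` (default for a lone pair) or `"complete"`.
#' @param context An `aln_set` supplying the column set for complete
#'   deletion; required when `deletion = "complete"`.
#' @return p in `[0, 1]`.
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete"),
                       context = NULL) {
  deletion <- match.arg(deletion)
  if (nchar(a) != nchar(b)) stop_invalid("sequences must be aligned (equal length)")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(av))
  if (deletion == "complete") {
    if (is.null(context)) stop_invalid("complete deletion needs a context alignment")
    m <- aln_matrix(context)
    keep <- colSums(m == "-" | m == "X") == 0
  }
  keep <- keep & !(av %in% c("-", "X")) & !(bv %in% c("-", "X"))
  if (!any(keep)) stop_invalid("no comparable columns for this pair")
  sum(av[keep] != bv[keep]) / sum(keep)
}

#' p-distance matrix for an alignment
#'
#' @inheritParams profile_alignment
#' @param deletion `"complete"` (default for tree building) or
#'   `"pairwise"`.
#' @return Symmetric matrix of p-distances with attributes `units`,
#'   `deletion`, `n_sites_used`.
#' @export
p_distance_matrix <- function(aln, domain = NULL,
                              deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "aln_set"))
  domain <- domain %||% names(aln$domains)[1]
  p <- pdist_matrix(aln_matrix(aln, domain), deletion)
  attr(p, "units") <- "p_distance"
  attr(p, "deletion") <- deletion
  p
}

#' Poisson-corrected protein distance
#'
#' Converts an observed proportion of differing residues into the expected
#' number of amino-acid substitutions per site under a Poisson substitution
#' model: \eqn{d = -\ln(1 - p)}. Undefined at saturation (p >= 1).
#'
#' @param p Observed difference proportion(s) in `[0, 1)`; a scalar,
#'   vector, or matrix (a distance matrix is corrected entry-wise).
#' @return d, same shape as `p`.
#' @examples
#' poisson_distance(0.5)  # 0.6931
#' @export
poisson_distance <- function(p) {
  if (any(p < 0)) stop_invalid("p must be >= 0")
  if (any(p >= 1))
    stop_invalid("saturated pair (p >= 1): Poisson distance undefined")
  d <- -log(1 - p)
  if (is.matrix(p)) {
    attr(d, "units") <- "poisson_distance"
    attr(d, "deletion") <- attr(p, "deletion")
    attr(d, "n_sites_used") <- attr(p, "n_sites_used")
  }
  d
}

#' Neighbor-joining tree
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)},
#' with branch lengths from the standard two-point formulas and the last
#' three clusters joined at a single internal node by the three-point
#' closed form. On an additive matrix the tree's path lengths reproduce the
#' input exactly. Negative branch lengths are clamped to 0; Q ties are
#' broken by the lowest (row, column) index pair; a 2-taxon input yields a
#' single edge split at its midpoint.
#'
#' @param m Symmetric distance matrix with labelled dimnames (e.g. from
#'   [poisson_distance()] of a [p_distance_matrix()]).
#' @return Unrooted `phylo` tree (basal trifurcation for >= 3 taxa).
#' @export
nj_tree <- function(m) {
  m <- unclass(as.matrix(m))
  n <- nrow(m)
  if (n < 2) stop_invalid("need >= 2 taxa")
  if (is.null(rownames(m))) stop_invalid("distance matrix must be labelled")
  if (any(!is.finite(m))) stop_invalid("non-finite distance entries")
  if (any(m < 0)) stop_invalid("negative distance entries")
  if (max(abs(m - t(m))) > 1e-12) stop_invalid("distance matrix not symmetric")
  labels <- rownames(m)

  fmt <- function(x) sprintf("%.15g", max(x, 0))
  reps <- labels  # newick fragment per active cluster
  D <- m
  while (length(reps) > 3) {
    nn <- length(reps)
    R <- rowSums(D)
    Q <- (nn - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
      if (Q[i, j] < best) { best <- Q[i, j]; bi <- i; bj <- j }
    }
    dij <- D[bi, bj]
    li <- dij / 2 + (R[bi] - R[bj]) / (2 * (nn - 2))
    lj <- dij - li
    newrep <- paste0("(", reps[bi], ":", fmt(li), ",", reps[bj], ":", fmt(lj), ")")
    dnew <- (D[bi, -c(bi, bj)] + D[bj, -c(bi, bj)] - dij) / 2
    D <- D[-c(bi, bj), -c(bi, bj), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    reps <- c(reps[-c(bi, bj)], newrep)
  }
  txt <- if (length(reps) == 2) {
    h <- D[1, 2] / 2
    paste0("(", reps[1], ":", fmt(h), ",", reps[2], ":", fmt(h), ");")
  } else {
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    paste0("(", reps[1], ":", fmt(la), ",", reps[2], ":", fmt(lb),
           ",", reps[3], ":", fmt(lc), ");")
  }
  ape::read.tree(text = txt)
}

#' Felsenstein bootstrap support for the NJ tree
#'
#' Builds the Poisson-corrected NJ tree of the alignment, then resamples
#' alignment columns with replacement (`replicates` pseudo-alignments of
#' the original length), recomputes the distance matrix and NJ tree for
#' each, and annotates every internal edge of the original tree with the
#' percent of replicate trees containing the same bipartition (rounded to
#' the nearest integer). Complete deletion, when selected, is applied
#' after resampling, per replicate. A replicate with a saturated pair
#' (p >= 1) or an incomparable pair is discarded and counted; if more than
#' 10% of replicates are discarded the run aborts.
#'
#' @inheritParams p_distance_matrix
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed; required, so runs are reproducible.
#' @return The original NJ `phylo` tree with `node.label` holding integer
#'   supports ("" at the basal node); the number of discarded replicates is
#'   in `attr(, "n_discarded")`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed,
                              domain = NULL,
                              deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "aln_set"))
  if (missing(seed)) stop_invalid("seed is required for bootstrap_support")
  if (length(aln$seqs) < 4)
    stop_invalid("bootstrap support needs >= 4 sequences")
  domain <- domain %||% names(aln$domains)[1]
  mat <- aln_matrix(aln, domain)
  # canonical row order, so supports are invariant to input leaf order
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  L <- ncol(mat)

  dist_of <- function(m) poisson_distance(pdist_matrix(m, deletion))
  tree <- nj_tree(dist_of(mat))

  orig <- bipartitions(tree)
  counts <- stats::setNames(integer(length(orig$keys)), orig$keys)
  n_discard <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_keys <- tryCatch(bipartitions(nj_tree(dist_of(mat[, cols, drop = FALSE])))$keys,
                           mhcvar_error = function(e) NULL)
      if (is.null(rep_keys)) { n_discard <- n_discard + 1L; next }
      hit <- orig$keys %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (n_discard > 0.1 * replicates)
    stop2(sprintf("bootstrap aborted: %d of %d replicates discarded (saturated pairs)",
                  n_discard, replicates))
  used <- replicates - n_discard
  support <- round(100 * counts / used)
  ntip <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  labs[orig$node - ntip] <- as.character(as.integer(support))
  tree$node.label <- labs
  attr(tree, "n_discarded") <- n_discard
  tree
}

# Internal edges of an unrooted phylo as normalized bipartition keys.
# Key = sorted labels of the side NOT containing the first sorted tip,
# so the key is orientation-free. Nodes vector gives, per key, the
# internal node whose tip set is that split (for support annotation).
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  tipsets <- node_tipsets(tree)
  root <- ntip + 1L
  anchor <- sort(tree$tip.label)[1]
  nodes <- setdiff(seq_len(tree$Nnode) + ntip, root)
  keys <- character(0); knodes <- integer(0)
  for (v in nodes) {
    side <- tipsets[[v]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    knodes <- c(knodes, v)
  }
  list(keys = keys, node = knodes)
}

# tip labels under each node (tips: themselves), by postorder accumulation
node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Assign query sequences to reference lineages
#'
#' Given a (bootstrap-annotated) tree whose reference leaves carry lineage
#' labels (the teleost MHC-I lineages U, Z, S, L, P, H in the shipped
#' analyses), each query is assigned by its smallest surrounding clade:
#' among all bipartition sides containing the query and at least one
#' reference leaf, take the smallest; if all its references share one
#' lineage the query is assigned that lineage together with the side's
#' bootstrap support, otherwise it is `"unassigned"`.
#'
#' @param tree A `phylo`, typically from [bootstrap_support()].
#' @param reference_lineages Named character vector: reference leaf id ->
#'   lineage label.
#' @param queries Character vector of query leaf ids.
#' @return Data.frame with `query`, `lineage`, `support` (NA when the
#'   defining side is a trivial split without an internal-edge support).
#' @export
assign_lineage <- function(tree, reference_lineages, queries) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing_q <- setdiff(queries, tips)
  if (length(missing_q))
    stop_invalid("query leaf absent from tree: ", paste(missing_q, collapse = ", "))
  refs <- names(reference_lineages)
  if (!all(refs %in% tips))
    stop_invalid("reference leaf absent from tree: ",
                 paste(setdiff(refs, tips), collapse = ", "))
  if (length(unique(reference_lineages)) < 2)
    stop_invalid("need >= 2 lineages among references")

  ntip <- length(tips)
  tipsets <- node_tipsets(tree)
  root <- ntip + 1L
  # every bipartition side with its support: for each non-root node, the
  # node's tip set and its complement (support = node label of that node)
  sides <- list(); supports <- numeric(0)
  get_sup <- function(v) {
    if (v <= ntip || is.null(tree$node.label)) return(NA_real_)
    lab <- tree$node.label[v - ntip]
    if (is.na(lab) || lab == "") NA_real_ else as.numeric(lab)
  }
  for (v in setdiff(seq_along(tipsets), root)) {
    s <- tipsets[[v]]
    sides <- c(sides, list(s), list(setdiff(tips, s)))
    supports <- c(supports, get_sup(v), get_sup(v))
  }
  do.call(rbind, lapply(queries, function(q) {
    cand <- which(vapply(sides, function(s) q %in% s && any(refs %in% s),
                         logical(1)))
    ord <- cand[order(lengths(sides)[cand], -ifelse(is.na(supports[cand]), -1,
                                                    supports[cand]))]
    s <- sides[[ord[1]]]
    lin <- unique(reference_lineages[intersect(refs, s)])
    data.frame(query = q,
               lineage = if (length(lin) == 1) unname(lin) else "unassigned",
               support = if (length(lin) == 1) supports[ord[1]] else NA_real_)
  }))
}
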