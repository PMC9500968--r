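#' Alignment fixture with exactly known per-site variability
#'
#' Builds a gap-free protein alignment in which every unspecified column is
#' constant (V = 0) and each specified column carries exactly `k` distinct
#' residue types at equal frequency, so its true variability is
#' \eqn{V = \log_2 k} exactly. Useful for validating [profile_alignment()]
#' end to end.
#'
#' @param n_seqs Number of sequences; every `k` must divide it (otherwise
#'   exact equifrequency is impossible and an error is raised).
#' @param L Alignment length.
#' @param site_spec Named integer vector: names are 1-based column indices,
#'   values the number `k` of equifrequent residue types (2..20). A `k`
#'   equal to `n_seqs` yields an all-distinct column, e.g. V = log2(13) =
#'   3.70 for 13 sequences.
#' @param seed Integer seed; the fixture is deterministic given it.
#' @return List with `alignment` (an `aln_set`, ids `seq01`, `seq02`, ...)
#'   and `truth` (data.frame `column_1based`, `k`, `V_true`).
#' @examples
#' fx <- make_variability_fixture(12, 30, c(`5` = 4, `9` = 2), seed = 1)
#' fx$truth
#' @export
make_variability_fixture <- function(n_seqs, L, site_spec = integer(0),
                                     seed = 1L) {
  cols <- as.integer(names(site_spec))
  ks <- as.integer(site_spec)
  if (length(ks) && (any(is.na(cols)) || any(cols < 1) || any(cols > L)))
    stop_invalid("site_spec names must be 1-based columns within 1..", L)
  if (any(ks > 20) || any(ks > n_seqs) || any(ks < 1))
    stop_invalid("k must be in 1..min(20, n_seqs)")
  bad <- ks[n_seqs %% ks != 0]
  if (length(bad))
    stop_invalid("k = ", bad[1], " does not divide n_seqs = ", n_seqs,
                 ": exact equifrequency impossible")
  with_seed(seed, {
    m <- matrix(sample(AA_ALPHABET, L, replace = TRUE),
                nrow = n_seqs, ncol = L, byrow = TRUE)
    for (t in seq_along(cols)) {
      types <- sample(AA_ALPHABET, ks[t])
      m[, cols[t]] <- sample(rep(types, each = n_seqs / ks[t]))
    }
    seqs <- stats::setNames(apply(m, 1, paste, collapse = ""),
                            sprintf("seq%02d", seq_len(n_seqs)))
    list(alignment = aligned_sequences(seqs),
         truth = data.frame(column_1based = cols, k = ks, V_true = log2(ks)))
  })
}

#' Simulate a lineage-structured MHC-like protein family
#'
#' Emulates the shape of an MHC class I alpha1/alpha2 sequence study:
#' several lineages (labelled after the teleost MHC-I lineages U, Z, S, L,
#' P, H) diverge from a common ancestor, and sequences within each lineage
#' evolve along a random coalescent-shaped tree under a Poisson
#' substitution process (events per site Poisson-distributed with the
#' branch length as mean; each event replaces the residue uniformly with
#' one of the other 19). Designated anchor columns are never mutated,
#' mirroring the conserved peptide-binding anchor residues. The output is
#' gap-free and deterministic given the seed.
#'
#' Each lineage root sits at distance `divergence_between / 2` from the
#' common ancestor, so two lineage roots are separated by an expected
#' `divergence_between` substitutions per site; within-lineage coalescent
#' trees are rescaled so the root-to-tip height equals `rate_within`.
#'
#' @param n_lineages Number of lineages (1..6).
#' @param seqs_per_lineage Sequences per lineage.
#' @param domain_lengths Named lengths of the concatenated domains; default
#'   `c(alpha1 = 87, alpha2 = 93)`, the study-scale domain sizes.
#' @param rate_within Expected root-to-tip substitutions per site within a
#'   lineage.
#' @param divergence_between Expected substitutions per site separating two
#'   lineage roots.
#' @param anchor_columns Named character vector: names are 1-based columns,
#'   values the fixed residue (e.g. `c(`7` = "Y", `84` = "R")`). `NULL`
#'   for none.
#' @param seed Integer seed.
#' @return List with `alignment` (an `aln_set` with the domain
#'   annotations), and `truth`: `tree` (the realized `phylo` with branch
#'   lengths), `lineages` (named vector id -> lineage label), and
#'   `anchor_columns`.
#' @export
simulate_family <- function(n_lineages = 3L, seqs_per_lineage = 4L,
                            domain_lengths = c(alpha1 = 87L, alpha2 = 93L),
                            rate_within = 0.05, divergence_between = 0.5,
                            anchor_columns = NULL, seed = 1L) {
  if (rate_within < 0 || divergence_between < 0)
    stop_invalid("rates must be >= 0")
  if (n_lineages < 1 || n_lineages > 6)
    stop_invalid("n_lineages must be 1..6 (lineage labels U, Z, S, L, P, H)")
  L <- sum(domain_lengths)
  anchor_idx <- integer(0)
  if (!is.null(anchor_columns)) {
    anchor_idx <- as.integer(names(anchor_columns))
    if (any(is.na(anchor_idx)) || any(anchor_idx < 1) || any(anchor_idx > L))
      stop_invalid("anchor columns must be 1-based within 1..", L)
  }
  lineage_labels <- c("U", "Z", "S", "L", "P", "H")[seq_len(n_lineages)]

  mutate_seq <- function(ch, t) {
    free <- setdiff(seq_along(ch), anchor_idx)
    nmut <- stats::rpois(length(free), t)
    for (w in which(nmut > 0)) {
      i <- free[w]
      for (rep in seq_len(nmut[w]))
        ch[i] <- sample(setdiff(AA_ALPHABET, ch[i]), 1)
    }
    ch
  }

  with_seed(seed, {
    ancestor <- sample(AA_ALPHABET, L, replace = TRUE)
    if (length(anchor_idx))
      ancestor[anchor_idx] <- toupper(unname(anchor_columns))
    seqs <- character(0)
    lineages <- character(0)
    sub_newicks <- character(n_lineages)
    for (g in seq_len(n_lineages)) {
      lab <- lineage_labels[g]
      ids <- sprintf("%s%d", lab, seq_len(seqs_per_lineage))
      root_seq <- mutate_seq(ancestor, divergence_between / 2)
      if (seqs_per_lineage == 1) {
        seqs[ids] <- paste(mutate_seq(root_seq, rate_within), collapse = "")
        sub_newicks[g] <- sprintf("%s:%.10f", ids, rate_within)
      } else {
        sub <- ape::rcoal(seqs_per_lineage, tip.label = ids)
        depth <- max(ape::node.depth.edgelength(sub))
        sub$edge.length <- sub$edge.length * (rate_within / depth)
        # evolve down the lineage tree from its root
        ntip <- seqs_per_lineage
        node_seq <- vector("list", ntip + sub$Nnode)
        node_seq[[ntip + 1L]] <- root_seq
        pre <- ape::reorder.phylo(sub, "cladewise")
        for (e in seq_len(nrow(pre$edge))) {
          p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
          node_seq[[ch]] <- mutate_seq(node_seq[[p]], pre$edge.length[e])
        }
        for (i in seq_len(ntip))
          seqs[sub$tip.label[i]] <- paste(node_seq[[i]], collapse = "")
        sub_newicks[g] <- sub(";$", "", ape::write.tree(sub))
      }
    }
    lineages <- stats::setNames(rep(lineage_labels, each = seqs_per_lineage),
                                names(seqs))
    true_tree <- ape::read.tree(text = paste0(
      "(", paste(sprintf("%s:%.10f", sub_newicks, divergence_between / 2),
                 collapse = ","), ");"))
    starts <- cumsum(c(0L, utils::head(domain_lengths, -1)))
    domains <- stats::setNames(
      lapply(seq_along(domain_lengths),
             function(i) c(starts[i], starts[i] + domain_lengths[i])),
      names(domain_lengths))
    list(alignment = aligned_sequences(seqs, domains = domains),
         truth = list(tree = true_tree, lineages = lineages,
                      anchor_columns = anchor_columns))
  })
}
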