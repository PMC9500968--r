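#' Per-site Shannon-entropy variability
#'
#' The variability metric V of an alignment column is the Shannon entropy
#' of its amino-acid composition, \eqn{V = -\sum_{i=1}^{M} P_i \log_2 P_i},
#' where \eqn{P_i} is the fraction of residues of amino-acid type i and M
#' the number of types observed at that column. Gaps and the ambiguity
#' character `X` are not amino-acid types and are excluded from the counts.
#'
#' V ranges from 0 (a fully conserved column, one type) up to
#' \eqn{\log_2 \min(20, n)} for n counted residues; with 13 sequences all
#' distinct, V = log2(13) = 3.70.
#'
#' @param column Character vector of single residues at one column.
#' @return V in bits, or `NA_real_` when no residue remains after excluding
#'   gaps and `X` ("no data" column — V is undefined there, not 0).
#' @examples
#' site_variability(rep("A", 13))              # 0
#' site_variability(c("A","A","A","A","K","K","K","K"))  # 1 bit
#' @export
site_variability <- function(column) {
  if (length(column) == 0) stop_invalid("empty column")
  res <- column[!column %in% c("-", "X")]
  if (length(res) == 0) return(NA_real_)
  p <- table(res) / length(res)
  -sum(p * log2(p)) + 0  # + 0 avoids IEEE negative zero for pure columns
}

#' Profile an alignment domain: V per site and polymorphic-site calls
#'
#' Computes V at every column of a domain and flags highly polymorphic
#' sites, those with V strictly greater than `threshold` (default 1 bit).
#' Columns with no usable residue (all gap/`X`) carry `V = NA` and are
#' excluded from the polymorphic count.
#'
#' @param aln An `aln_set`.
#' @param domain Domain name; defaults to the first domain.
#' @param threshold Polymorphic-site threshold in bits; strict inequality.
#' @param ref_map Optional [build_reference_map()] result used to annotate
#'   sites with reference (HLA-A2 style) numbering.
#' @return A data.frame with one row per domain column: `site_1based`
#'   (1-based within the domain), `column_1based` (1-based in the full
#'   alignment), optional `ref_position`, `n_used`, `M`, `V`, `V_2dp`,
#'   `polymorphic`. The polymorphic-site count is in
#'   `attr(, "n_polymorphic")`.
#' @export
profile_alignment <- function(aln, domain = NULL, threshold = 1.0,
                              ref_map = NULL) {
  stopifnot(inherits(aln, "aln_set"))
  domain <- domain %||% names(aln$domains)[1]
  d <- get_domain(aln, domain)
  m <- aln_matrix(aln, domain)
  cols <- seq_len(ncol(m))
  V <- vapply(cols, function(j) site_variability(m[, j]), numeric(1))
  n_used <- vapply(cols, function(j) sum(!m[, j] %in% c("-", "X")), integer(1))
  M <- vapply(cols, function(j) {
    r <- m[, j]; length(unique(r[!r %in% c("-", "X")]))
  }, integer(1))
  poly <- ifelse(is.na(V), NA, V > threshold)
  out <- data.frame(site_1based = cols,
                    column_1based = d[1] + cols,
                    n_used = n_used, M = M,
                    V = V, V_2dp = round(V, 2),
                    polymorphic = poly)
  if (!is.null(ref_map)) {
    idx <- match(out$column_1based - 1L, ref_map$column)
    out$ref_position <- ref_map$ref_position[idx]
    out <- out[, c("site_1based", "column_1based", "ref_position",
                   "n_used", "M", "V", "V_2dp", "polymorphic")]
  }
  attr(out, "n_polymorphic") <- sum(poly, na.rm = TRUE)
  attr(out, "domain") <- domain
  attr(out, "threshold") <- threshold
  out
}

#' Pairwise percent-difference matrix
#'
#' For every unordered pair of sequences, the percent of compared columns
#' at which the residues differ. Columns containing a gap or `X` are
#' excluded: under `pairwise` deletion only from the pair being compared,
#' under `complete` deletion from the whole set (one shared column set).
#'
#' @inheritParams profile_alignment
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix in percent (0-100), zero diagonal, with
#'   attributes `units = "percent_difference"`, `deletion`, and
#'   `n_sites_used` (a single integer under complete deletion; a per-pair
#'   matrix under pairwise deletion).
#' @export
pairwise_difference_matrix <- function(aln, domain = NULL,
                                       deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "aln_set"))
  if (length(aln$seqs) < 2) stop_invalid("need at least 2 sequences")
  domain <- domain %||% names(aln$domains)[1]
  pd <- pdist_matrix(aln_matrix(aln, domain), deletion)
  m <- 100 * pd
  attr(m, "units") <- "percent_difference"
  attr(m, "deletion") <- deletion
  attr(m, "n_sites_used") <- attr(pd, "n_sites_used")
  m
}

#' Summary statistics of a pairwise difference matrix
#'
#' Minimum, maximum, mean and standard error of the mean over the
#' \eqn{n(n-1)/2} unique off-diagonal values. The s.e.m. uses the sample
#' standard deviation (n-1 denominator) divided by the square root of the
#' number of unique pairs. With a single pair the s.e.m. is undefined and
#' reported as 0 with a warning.
#'
#' @param m Symmetric matrix as returned by [pairwise_difference_matrix()].
#' @return List with `min`, `max`, `mean`, `sem`, `n_pairs`.
#' @export
summarize_differences <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2) stop_invalid("need a matrix over >= 2 labels")
  vals <- m[upper.tri(m)]
  sem <- if (length(vals) < 2) {
    warning("single pair: s.e.m. undefined, reported as 0")
    0
  } else {
    stats::sd(vals) / sqrt(length(vals))
  }
  list(min = min(vals), max = max(vals), mean = mean(vals), sem = sem,
       n_pairs = length(vals))
}

# Shared p-distance engine on a character matrix (rows = sequences).
# Returns fractions in [0,1]; errors if a pair has no comparable column.
pdist_matrix <- function(m, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- nrow(m)
  ids <- rownames(m)
  bad <- m == "-" | m == "X"
  if (deletion == "complete") {
    keep <- colSums(bad) == 0
    if (!any(keep)) stop_invalid("no columns left after complete deletion")
    m <- m[, keep, drop = FALSE]
    bad <- bad[, keep, drop = FALSE]
  }
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  nsites <- matrix(if (deletion == "complete") ncol(m) else 0L, n, n,
                   dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cmpk <- !(bad[i, ] | bad[j, ])
      nc <- sum(cmpk)
      if (nc == 0)
        stop_invalid("no comparable columns for pair ", ids[i], " / ", ids[j])
      pij <- sum(m[i, cmpk] != m[j, cmpk]) / nc
      p[i, j] <- p[j, i] <- pij
      nsites[i, j] <- nsites[j, i] <- nc
    }
  }
  attr(p, "n_sites_used") <- if (deletion == "complete") ncol(m) else nsites
  p
}
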