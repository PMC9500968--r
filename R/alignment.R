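#' Aligned amino-acid sequence set
#'
#' Container for a protein multiple sequence alignment: named, equal-length,
#' gapped amino-acid sequences plus optional named domain intervals (for MHC
#' class I work, typically the alpha1 and alpha2 peptide-binding domains).
#'
#' Domain intervals are stored 0-based half-open, e.g. `alpha1 = c(0, 87)`,
#' `alpha2 = c(87, 180)`; user-facing reports use 1-based inclusive
#' coordinates.
#'
#' @param seqs Named character vector of aligned protein sequences (equal
#'   length; gap character allowed). Case-insensitive input; stored
#'   upper-case.
#' @param domains Named list of integer pairs `c(start, end)`, 0-based
#'   half-open column intervals. `NULL` means a single implicit domain
#'   spanning the whole alignment, named `"full"`.
#' @param gap_char Gap character, `"-"`.
#' @return An object of class `aln_set`: a list with elements `seqs`,
#'   `L` (alignment length), `domains` and `gap_char`.
#' @examples
#' aln <- aligned_sequences(c(s1 = "ACDEF", s2 = "ACDQF"),
#'                          domains = list(d1 = c(0, 2), d2 = c(2, 5)))
#' aln$L
#' @export
aligned_sequences <- function(seqs, domains = NULL, gap_char = "-") {
  if (length(seqs) < 1 || is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_invalid("alignment needs at least one named sequence")
  if (anyDuplicated(names(seqs)))
    stop_invalid("duplicate sequence id(s): ",
                 paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    off <- lens != stats::median(lens)
    stop_invalid("ragged alignment; offending id(s): ",
                 paste(sprintf("%s (%d)", names(seqs)[off], lens[off]), collapse = ", "))
  }
  L <- lens[[1]]
  if (L == 0) stop_invalid("zero-length alignment")
  validate_alphabet(seqs, PROTEIN_CHARS)
  if (is.null(domains)) domains <- list(full = c(0L, L))
  if (is.null(names(domains)) || any(!nzchar(names(domains))))
    stop_invalid("domains must be named")
  domains <- lapply(domains, function(d) as.integer(d))
  for (nm in names(domains)) {
    d <- domains[[nm]]
    if (length(d) != 2 || d[1] < 0 || d[2] > L || d[1] >= d[2])
      stop_invalid("domain '", nm, "' [", d[1], ",", d[2],
                   ") out of bounds for alignment of length ", L)
  }
  # disjointness
  cov <- integer(L)
  for (d in domains) cov[(d[1] + 1):d[2]] <- cov[(d[1] + 1):d[2]] + 1L
  if (any(cov > 1)) stop_invalid("domain intervals overlap")
  structure(list(seqs = seqs, L = L, domains = domains, gap_char = gap_char),
            class = "aln_set")
}

validate_alphabet <- function(seqs, allowed) {
  for (id in names(seqs)) {
    ch <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad))
      stop_invalid("illegal character '", ch[bad[1]], "' in record '", id,
                   "' at position ", bad[1])
  }
  invisible(TRUE)
}

#' @export
print.aln_set <- function(x, ...) {
  cat(sprintf("Aligned set: %d sequences x %d columns\n", length(x$seqs), x$L))
  for (nm in names(x$domains)) {
    d <- x$domains[[nm]]
    cat(sprintf("  domain %-10s columns %d..%d (1-based), %d aa\n",
                nm, d[1] + 1, d[2], d[2] - d[1]))
  }
  invisible(x)
}

# character matrix view (rows = sequences, columns = alignment columns)
aln_matrix <- function(aln, domain = NULL) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  if (!is.null(domain)) {
    d <- get_domain(aln, domain)
    m <- m[, (d[1] + 1):d[2], drop = FALSE]
  }
  m
}

get_domain <- function(aln, domain) {
  if (!domain %in% names(aln$domains))
    stop_invalid("no such domain '", domain, "'; available: ",
                 paste(names(aln$domains), collapse = ", "))
  aln$domains[[domain]]
}
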