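#' Read sequences from a FASTA file
#'
#' Reads a plain or aligned FASTA file into a named character vector,
#' validating ids and alphabet. Protein records may contain the 20 standard
#' residues plus `X` (ambiguous), `-` (gap) and `*` (stop); nucleotide
#' records may contain `ACGTN`. Input case is ignored; sequences are stored
#' upper-case.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_invalid("not valid FASTA: ", path,
                                                   " (", conditionMessage(e), ")"))
  if (length(set) == 0) stop_invalid("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))  # id = first whitespace-delimited token
  if (any(!nzchar(ids))) stop_invalid("empty sequence id in ", path)
  if (anyDuplicated(ids))
    stop_invalid("duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs))) stop_invalid("empty sequence for id '", ids[!nzchar(seqs)][1], "'")
  names(seqs) <- ids
  allowed <- if (moltype == "protein") PROTEIN_CHARS else NT_CHARS
  validate_alphabet(seqs, allowed)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an aligned FASTA file into an [aligned_sequences()] set
#'
#' @inheritParams read_fasta
#' @param domains Named list of 0-based half-open column intervals (see
#'   [aligned_sequences()]); `NULL` for a single whole-alignment domain.
#' @return An `aln_set`.
#' @export
read_alignment <- function(path, domains = NULL) {
  aligned_sequences(read_fasta(path, "protein"), domains = domains)
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code, codons read 5'->3' from the frame offset. Trailing
#' 1-2 nt are dropped; stop codons are emitted as `*` (as EMBOSS Transeq
#' does) and codons containing `N` as `X`.
#'
#' @param nt A nucleotide sequence (character scalar over `ACGTN`; name, if
#'   any, is preserved).
#' @param frame Frame offset, 0, 1 or 2.
#' @return Protein sequence of length `floor((nchar(nt) - frame) / 3)`.
#' @examples
#' translate_cds("ATGGGCTAA")        # "MG*"
#' translate_cds("AATGGGC", frame = 1)  # "MG"
#' @export
translate_cds <- function(nt, frame = 0L) {
  stopifnot(length(nt) == 1)
  if (!frame %in% 0:2) stop_invalid("frame must be 0, 1 or 2")
  s <- toupper(nt)
  validate_alphabet(stats::setNames(s, names(nt) %||% "seq"), NT_CHARS)
  s <- substring(s, frame + 1)
  n_codons <- nchar(s) %/% 3
  if (n_codons < 1) stop_invalid("sequence too short to translate in frame ", frame)
  s <- substring(s, 1, 3 * n_codons)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  stats::setNames(aa, names(nt))
}

#' Write a tree to Newick
#'
#' Serializes an `ape::phylo` tree to Newick with branch lengths printed to
#' 6 decimal places and any internal-node labels (e.g. integer bootstrap
#' supports, see [bootstrap_support()]) written as internal node labels.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  txt <- deparse_newick(tree, digits_fmt = "%.6f")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_invalid("cannot write to ", path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file. Internal node labels (bootstrap
#'   supports) are kept as `node.label`.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  ape::read.tree(path)
}

# Recursive Newick writer; digits_fmt controls branch-length formatting.
# ape::write.tree prints significant digits, whereas the report format
# fixes 6 decimal places, so this is done by hand.
deparse_newick <- function(tree, digits_fmt = "%.6f") {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- ntip + 1L
  node_label <- function(v) {
    if (is.null(tree$node.label)) return("")
    lab <- tree$node.label[v - ntip]
    if (is.na(lab) || identical(lab, "")) "" else as.character(lab)
  }
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    parts <- vapply(children[[as.character(v)]], function(e) {
      child <- tree$edge[e, 2]
      len <- if (is.null(tree$edge.length)) "" else
        sprintf(paste0(":", digits_fmt), tree$edge.length[e])
      paste0(rec(child), len)
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", node_label(v))
  }
  paste0(rec(root), ";")
}
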