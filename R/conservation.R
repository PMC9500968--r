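#' Residue conservation schemes
#'
#' A residue scheme lists reference-numbered positions (1-based, HLA-A2
#' mature-protein numbering in the shipped schemes), the residue(s) allowed
#' at each, and a category. Categories: `anchor` (the peptide-terminus
#' anchor octet at positions 7, 59, 84, 143, 146, 147, 159, 171),
#' `pre_class_I_II` (residues predating the class I/II split) and
#' `classical_common` (residues common to classical MHC-I). The latter two
#' sets are supplied as data (TSV) since their full membership is a
#' figure-level annotation, not an enumerable rule.
#'
#' @param ref_position Integer vector of 1-based reference positions.
#' @param allowed Character vector, one entry per position; alternatives
#'   separated by `/`, e.g. `"Y/R"`.
#' @param category Character vector of categories (recycled if scalar).
#' @param name Scheme name.
#' @return A data.frame of class `residue_scheme` with columns
#'   `ref_position`, `allowed` (display string) and `category`; the parsed
#'   allowed-sets are in `attr(, "allowed_sets")`.
#' @export
residue_scheme <- function(ref_position, allowed, category = "anchor",
                           name = "custom") {
  ref_position <- as.integer(ref_position)
  if (anyDuplicated(ref_position))
    stop_invalid("duplicate ref_position in scheme")
  if (any(ref_position < 1)) stop_invalid("ref_position must be >= 1")
  category <- rep_len(category, length(ref_position))
  sets <- strsplit(toupper(allowed), "/", fixed = TRUE)
  if (any(lengths(sets) == 0)) stop_invalid("empty allowed set in scheme")
  out <- data.frame(ref_position = ref_position,
                    allowed = toupper(allowed),
                    category = category)
  attr(out, "allowed_sets") <- sets
  attr(out, "name") <- name
  class(out) <- c("residue_scheme", "data.frame")
  out
}

#' Built-in peptide-anchor octet schemes
#'
#' The eight residues anchoring the peptide N- and C-termini in the MHC-I
#' groove, in HLA-A2 numbering: Y7, Y59, 84, T143, K146, W147, Y159, Y171.
#' The mammalian set has Y at 84 (octet YYYYYTKW); in teleost fish and
#' sharks position 84 is R instead, so the fish scheme allows R there and
#' is otherwise identical.
#'
#' @param set `"fish"` or `"mammal"`.
#' @return A [residue_scheme()].
#' @examples
#' anchor_scheme("fish")
#' @export
anchor_scheme <- function(set = c("fish", "mammal")) {
  set <- match.arg(set)
  pos <- c(7L, 59L, 84L, 143L, 146L, 147L, 159L, 171L)
  allowed <- c("Y", "Y", if (set == "fish") "R" else "Y", "T", "K", "W", "Y", "Y")
  residue_scheme(pos, allowed, "anchor", name = paste0("anchor_", set))
}

#' Read / write a residue scheme as TSV
#'
#' TSV columns: `ref_position`, `allowed` (e.g. `"Y"` or `"Y/R"`),
#' `category`.
#'
#' @param path Path to a TSV file.
#' @return A [residue_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref_position", "allowed", "category")
  if (!all(need %in% names(df)))
    stop_invalid("scheme TSV must have columns: ", paste(need, collapse = ", "))
  residue_scheme(df$ref_position, df$allowed, df$category,
                 name = basename(path))
}

#' @rdname read_scheme
#' @param scheme A [residue_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme)[c("ref_position", "allowed", "category")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map alignment columns to reference numbering
#'
#' Derives a column-to-reference-position correspondence from a designated
#' reference row: its k-th non-gap residue maps to
#' `start_position + k - 1`; columns where the reference has a gap are
#' unmapped. Figure-style MHC reports number positions on the mature
#' HLA-A2 protein, so `start_position` is the HLA-A2 position of the
#' reference row's first residue.
#'
#' @param aln An `aln_set`.
#' @param ref_id Id of the reference row.
#' @param start_position 1-based reference position of the first non-gap
#'   reference residue.
#' @return Data.frame of class `ref_map` with columns `column` (0-based
#'   alignment column) and `ref_position`; unmapped columns are listed in
#'   `attr(, "unmapped")`.
#' @export
build_reference_map <- function(aln, ref_id, start_position = 1L) {
  stopifnot(inherits(aln, "aln_set"))
  if (start_position < 1) stop_invalid("start_position must be >= 1")
  if (!ref_id %in% names(aln$seqs))
    stop_invalid("reference id '", ref_id, "' not in alignment")
  ch <- strsplit(aln$seqs[[ref_id]], "", fixed = TRUE)[[1]]
  nongap <- which(ch != aln$gap_char)
  out <- data.frame(column = nongap - 1L,
                    ref_position = start_position + seq_along(nongap) - 1L)
  attr(out, "unmapped") <- setdiff(seq_along(ch), nongap) - 1L
  attr(out, "ref_id") <- ref_id
  class(out) <- c("ref_map", "data.frame")
  out
}

#' Audit conservation of scheme residues across an alignment
#'
#' For every sequence and scheme entry, reports the observed residue at the
#' mapped column and whether it matches the allowed set. A gap at a scheme
#' position is a non-match reported with status `"gap"`; scheme positions
#' not covered by the reference map are reported `"unmappable"` rather than
#' silently dropped.
#'
#' @param aln An `aln_set`.
#' @param map A [build_reference_map()] result.
#' @param scheme A [residue_scheme()].
#' @return List of class `conservation_report`:
#'   \describe{
#'     \item{per_site}{data.frame seq_id x scheme entry with `observed`,
#'       `status` (match/mismatch/gap/unmappable), `match`.}
#'     \item{per_seq}{per sequence: anchor positions matched out of the
#'       anchor entries (e.g. 8/8 for the built-in octet).}
#'     \item{n_substitutions}{total non-matches across sequences at
#'       non-anchor category positions (gap counts as a substitution).}
#'   }
#' @export
check_residues <- function(aln, map, scheme) {
  stopifnot(inherits(aln, "aln_set"), inherits(map, "ref_map"),
            inherits(scheme, "residue_scheme"))
  sets <- attr(scheme, "allowed_sets")
  col_of <- map$column[match(scheme$ref_position, map$ref_position)]
  mat <- aln_matrix(aln)
  rows <- vector("list", length(aln$seqs) * nrow(scheme))
  k <- 0
  for (sid in names(aln$seqs)) {
    for (e in seq_len(nrow(scheme))) {
      k <- k + 1
      if (is.na(col_of[e])) {
        obs <- NA_character_; status <- "unmappable"
      } else {
        obs <- mat[sid, col_of[e] + 1L]
        status <- if (obs == aln$gap_char) "gap"
                  else if (obs %in% sets[[e]]) "match" else "mismatch"
      }
      rows[[k]] <- data.frame(seq_id = sid,
                              ref_position = scheme$ref_position[e],
                              category = scheme$category[e],
                              allowed = scheme$allowed[e],
                              observed = obs,
                              status = status,
                              match = identical(status, "match"))
    }
  }
  per_site <- do.call(rbind, rows)
  anchors <- per_site$category == "anchor"
  per_seq <- do.call(rbind, lapply(names(aln$seqs), function(sid) {
    sel <- per_site$seq_id == sid & anchors
    data.frame(seq_id = sid,
               n_anchor = sum(sel),
               n_anchor_matched = sum(per_site$match[sel]))
  }))
  n_sub <- sum(!per_site$match[!anchors & per_site$status != "unmappable"])
  structure(list(per_site = per_site, per_seq = per_seq,
                 n_substitutions = n_sub,
                 scheme = attr(scheme, "name")),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("Conservation report (scheme:", x$scheme, ")\n")
  print(x$per_seq, row.names = FALSE)
  cat("Non-anchor substitutions:", x$n_substitutions, "\n")
  invisible(x)
}
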