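# Small fixture builders shared across test files.

write_temp_fasta <- function(seqs, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

# two identical pairs, the pairs differing at 40% of columns: every
# bootstrap replicate supports the {a1,a2} | {b1,b2} split (the chance of
# resampling no differing column is 0.6^L), and no pair saturates
two_pair_alignment <- function(L = 30, seed = 42) {
  set.seed(seed)
  aa <- mhcvar:::AA_ALPHABET
  s1 <- sample(aa, L, replace = TRUE)
  s2 <- s1
  diff_cols <- sample(L, ceiling(0.4 * L))
  s2[diff_cols] <- vapply(s1[diff_cols],
                          function(x) sample(setdiff(aa, x), 1), character(1))
  aligned_sequences(c(a1 = paste(s1, collapse = ""),
                      a2 = paste(s1, collapse = ""),
                      b1 = paste(s2, collapse = ""),
                      b2 = paste(s2, collapse = "")))
}
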