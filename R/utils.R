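# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
PROTEIN_CHARS <- c(AA_ALPHABET, "X", "-", "*")
NT_CHARS <- c("A", "C", "G", "T", "N")

stop2 <- function(..., class = "mhcvar_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_invalid <- function(...) {
  stop2(..., class = c("mhcvar_validation_error", "mhcvar_error"))
}

# Run code under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
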