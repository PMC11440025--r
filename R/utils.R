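# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so seeded internals never perturb user-level streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a deterministic child seed from a base seed and a stream index,
# kept inside the 32-bit integer range
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103L + index * 7919L) %% .Machine$integer.max)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = "NA")
  invisible(path)
}
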