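# Shared helpers.

# Half-up rounding for presentation percentages (R's round() is half-even;
# published tables use half-up, e.g. 57.89 -> 57.9).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; all randomness in the package flows through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a decorrelated child seed (keeps results of separate seeded stages
# independent of one another while remaining a pure function of the seed).
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 69069 + 12345 * stream) %% 2147483647)
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  trimws(out)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
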