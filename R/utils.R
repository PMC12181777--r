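# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# "A1" -> list(row = 1L, col = 1L); errors carry the offending address
parseWellAddress <- function(address) {
  if (length(address) != 1L || !is.character(address) ||
      !grepl("^[A-Z][0-9]+$", address))
    stop("invalid well address '", address, "'", call. = FALSE)
  list(row = match(substr(address, 1, 1), LETTERS),
       col = as.integer(sub("^[A-Z]", "", address)))
}

# row/col (1-based) -> "A1"
wellAddress <- function(row, col) paste0(LETTERS[row], col)

# all addresses of a labware, A1 -> down then right (column-major)
labwareAddresses <- function(lw) {
  as.vector(outer(LETTERS[seq_len(lw@rows)], seq_len(lw@cols), paste0))
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
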