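# Internal helpers shared across modules.

# Canonical entity-name form: case-folded, trimmed, internal whitespace
# collapsed. All name matching in the package goes through this.
normalizeEntityName <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; stays well inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647L)
}

# Delimiter auto-detection for the text readers: tab wins over comma.
detectDelim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

stopIfNot01 <- function(m, what, tol = 1e-9) {
  if (any(m < -tol) || any(m > 1 + tol))
    stop(sprintf("%s has entries outside [0, 1]", what))
  invisible(NULL)
}
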