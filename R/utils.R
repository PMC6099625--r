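# Internal helpers shared across modules.

# Evaluate expr under a given RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a distinct sub-seed (< 2^31) from a base seed and a stream index.
subSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

# Collapse whitespace runs to single spaces and trim.
squish <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

# Monotonic-ish elapsed-time stamp in seconds.
nowSeconds <- function() unname(proc.time()["elapsed"])

# Parse a flat key=value text file ('#' comments, blank lines allowed).
readKeyValue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("malformed key=value line: ", dQuote(lines[bad][1L], FALSE),
         call. = FALSE)
  stats::setNames(lapply(kv, `[[`, 3L), trimws(vapply(kv, `[[`, "", 2L)))
}
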