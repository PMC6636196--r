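#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames runif
#' @importFrom utils head tail write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' A single global seed fans out to per-stage seeds so that toggling one stage
#' does not perturb the random stream of another. The derivation hashes the
#' stage name onto the 31-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## Reverse-complement for plain character strings (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## Runs of N of at least `min_run` in a DNA string: data.frame(start, end),
## 1-based closed.
n_runs <- function(dna, min_run = 10L) {
  m <- gregexpr(sprintf("N{%d,}", min_run), dna)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), end = integer()))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L)
}

stop_codons <- c("TAA", "TAG", "TGA")

## Translate a DNA string (multiple of 3 not required; trailing 1-2 nt are
## dropped). N-containing codons become X.
translate_str <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, 3L * n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[mhciscan] ", ...)
}
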