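# Internal helpers shared across modules.

#' @useDynLib durmiR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of ACGTN sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA sequences (uniform ACGT).
random_dna <- function(n, len) {
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Normalize sequences: uppercase, RNA U -> T.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
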