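#' Generate a random DNA string
#'
#' Uniform i.i.d. bases over A/C/G/T. Used by the synthetic locus generator;
#' at the scales used here (kb--hundreds of kb) random sequence is effectively
#' repeat-free, which is what makes k-mer anchoring unambiguous.
#'
#' @param n Sequence length in bp.
#' @return A single uppercase DNA string.
#' @export
random_dna <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x A DNA string (A/C/G/T/N).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package calls do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 1-based inclusive interval width
iv_width <- function(start, end) end - start + 1L

assert_dna <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0) {
    stop(sprintf("%s contains non-nucleotide character '%s' at position %d",
                 what, substr(x, bad, bad), bad), call. = FALSE)
  }
  invisible(x)
}
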