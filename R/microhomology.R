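#' Junction microhomology between two sequence starts
#'
#' Length of the longest common prefix of two junction-start sequences, in
#' bp, capped at `max_k`. This is the quantity implicated in
#' microhomology-mediated repair at a breakpoint: a short stretch of perfect
#' identity between the beginnings of the two sequences joined there (here,
#' the start of the MGE and the start of the truncated repeat type).
#' Symmetric in its arguments; 0 when the first bases already differ.
#'
#' @param seq_a,seq_b Nonempty DNA strings.
#' @param max_k Cap on the reported length; at most the shorter length.
#' @return Integer microhomology length.
#' @export
junction_microhomology <- function(seq_a, seq_b,
                                   max_k = min(nchar(seq_a), nchar(seq_b))) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0,
            max_k <= min(nchar(seq_a), nchar(seq_b)))
  a <- utf8ToInt(substr(seq_a, 1L, max_k))
  b <- utf8ToInt(substr(seq_b, 1L, max_k))
  diff <- which(a != b)
  if (length(diff) == 0) return(as.integer(max_k))
  diff[1] - 1L
}

#' Count gene occurrences in an assembly
#'
#' Number of non-overlapping exact occurrences of a gene body on either
#' strand of an assembly. Sites found on both strands (palindromic probes)
#' are counted once, and overlapping sites are greedily deduplicated
#' left-to-right.
#'
#' @param assembly DNA string to search.
#' @param gene_sequence Probe sequence (>= 100 bp so matches are specific).
#' @return Integer count.
#' @export
count_gene_occurrences <- function(assembly, gene_sequence) {
  if (nchar(gene_sequence) < 100)
    stop("gene_sequence must be >= 100 bp for specific matching")
  subj <- Biostrings::DNAString(assembly)
  len <- nchar(gene_sequence)
  f <- BiocGenerics::start(
    Biostrings::matchPattern(Biostrings::DNAString(gene_sequence), subj))
  r <- BiocGenerics::start(
    Biostrings::matchPattern(Biostrings::DNAString(revcomp(gene_sequence)), subj))
  sites <- sort(unique(c(f, r)))
  if (length(sites) == 0) return(0L)
  kept <- sites[1]
  last_end <- sites[1] + len - 1L
  for (s in sites[-1]) {
    if (s > last_end) {
      kept <- c(kept, s)
      last_end <- s + len - 1L
    }
  }
  length(kept)
}
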