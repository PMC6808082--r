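#' Layout parameters for a single-copy locus template
#'
#' Describes the contig length and gene placement used by
#' [build_susceptible_locus()]. The `"kochia"` profile reproduces the EPSPS
#' contig annotation verbatim (399,779 bp, 13 genes, EPSPS at
#' 91,663--97,214). The `"mini"` profile is the same layout scaled down
#' 20-fold for fast simulation work; all downstream operations are
#' scale-free, so results on the mini profile exercise the same code paths.
#'
#' @param profile `"kochia"` (full scale) or `"mini"` (1/20 scale).
#' @param genes Optional replacement gene table (as from
#'   [read_gene_table()]); may have zero rows.
#' @param contig_length Optional contig length override.
#' @param allow_overlap List of length-2 character vectors naming gene pairs
#'   that are permitted to overlap (the annotation contains one such pair).
#' @return A list with elements `contig_id`, `contig_length`, `genes`,
#'   `epsps_gene_id`, `scale`, `allow_overlap`.
#' @export
locus_layout <- function(profile = c("kochia", "mini"), genes = NULL,
                         contig_length = NULL,
                         allow_overlap = list(c("KS_00461", "KS_00462"))) {
  profile <- match.arg(profile)
  scale <- if (profile == "mini") 20L else 1L
  if (is.null(genes)) genes <- kochia_gene_table()
  if (is.null(contig_length)) contig_length <- 399779L
  if (scale > 1L && nrow(genes) > 0) {
    genes$start <- as.integer(round(genes$start / scale))
    genes$end <- as.integer(round(genes$end / scale))
    genes$length <- genes$end - genes$start
  }
  contig_length <- as.integer(round(contig_length / scale))
  list(contig_id = paste0("epsps_contig_", profile),
       contig_length = contig_length,
       genes = genes,
       epsps_gene_id = "KS_00460",
       scale = scale,
       allow_overlap = allow_overlap)
}

#' Build a single-copy (susceptible) locus template
#'
#' Generates a random DNA contig carrying the configured gene layout. The
#' sequence is uniform random DNA, so gene bodies are locally unique and
#' anchoring of derived fragments back onto the template is unambiguous.
#'
#' @param layout Layout from [locus_layout()].
#' @param seed Integer seed; the same seed yields a byte-identical sequence.
#' @return A `LocusTemplate`: list with `contig_id`, `sequence`, `genes`,
#'   `epsps_gene_id`, `scale`.
#' @export
build_susceptible_locus <- function(layout = locus_layout(), seed = 1L) {
  genes <- layout$genes
  L <- layout$contig_length
  if (nrow(genes) > 0) {
    if (any(genes$start < 1L) || any(genes$end > L))
      stop("gene interval outside contig bounds")
    if (any(genes$start >= genes$end)) stop("gene with start >= end")
    ov <- which(outer(genes$start, genes$end, "<=") &
                outer(genes$end, genes$start, ">="), arr.ind = TRUE)
    ov <- ov[ov[, 1] < ov[, 2], , drop = FALSE]
    if (nrow(ov) > 0) {
      allowed <- vapply(seq_len(nrow(ov)), function(i) {
        pair <- sort(genes$gene_id[ov[i, ]])
        any(vapply(layout$allow_overlap,
                   function(p) identical(sort(p), pair), logical(1)))
      }, logical(1))
      if (!all(allowed)) {
        bad <- ov[!allowed, , drop = FALSE][1, ]
        stop(sprintf("genes %s and %s overlap and are not an allowed pair",
                     genes$gene_id[bad[1]], genes$gene_id[bad[2]]))
      }
    }
  }
  sequence <- with_seed(seed, random_dna(L))
  structure(list(contig_id = layout$contig_id,
                 sequence = sequence,
                 genes = genes,
                 epsps_gene_id = layout$epsps_gene_id,
                 scale = layout$scale),
            class = "LocusTemplate")
}

#' @export
print.LocusTemplate <- function(x, ...) {
  cat(sprintf("<LocusTemplate> %s: %s bp, %d genes (EPSPS: %s)\n",
              x$contig_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes), x$epsps_gene_id))
  invisible(x)
}

#' Gene sequence from a locus template
#'
#' Extracts the gene-body sequence (reverse-complemented for reverse-strand
#' genes) from a template.
#'
#' @param template A `LocusTemplate`.
#' @param gene_id Gene identifier; defaults to the template's EPSPS gene.
#' @return A DNA string.
#' @export
gene_sequence <- function(template, gene_id = template$epsps_gene_id) {
  g <- template$genes[template$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("gene not found: ", gene_id)
  s <- substr(template$sequence, g$start, g$end)
  if (g$orientation == "reverse") s <- revcomp(s)
  s
}
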