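#' Read a gene table in the contig-annotation layout
#'
#' Reads a TSV with columns `Gene`, `Beginning`, `Ending`, `Orientation` and
#' optionally `Length`, `Description`, `Part_of_CNV`, `DE`, `P_Value`.
#' Coordinates are 1-based inclusive positions on the contig. When a `Length`
#' column is present it is checked against the table's own convention,
#' `Length = Ending - Beginning` (no +1); rows violating it trigger a warning
#' naming the gene. This convention is deliberate: it is how the source
#' annotation reports gene lengths (e.g. the EPSPS gene model at
#' 91,663--97,214 is reported as 5,551 bp).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `gene_id`, `start`, `end`, `orientation`
#'   (`"forward"`/`"reverse"`), `length` (end - start) and, when present in
#'   the file, `description`, `part_of_cnv`, `log2_de`, `fdr_p`.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  req <- c("Gene", "Beginning", "Ending", "Orientation")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("gene table is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    return(data.frame(gene_id = character(), start = integer(), end = integer(),
                      orientation = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  for (col in c("Beginning", "Ending")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) stop("non-numeric coordinate in column ", col)
    tab[[col]] <- as.integer(v)
  }
  out <- data.frame(
    gene_id = as.character(tab$Gene),
    start = tab$Beginning,
    end = tab$Ending,
    orientation = tolower(as.character(tab$Orientation)),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("gene with start >= end in table")
  out$length <- out$end - out$start
  if ("Length" %in% names(tab)) {
    decl <- suppressWarnings(as.integer(tab$Length))
    bad <- which(!is.na(decl) & decl != out$length)
    if (length(bad) > 0) {
      warning("declared Length != Ending - Beginning for row(s): ",
              paste(out$gene_id[bad], collapse = ", "))
    }
  }
  if ("Description" %in% names(tab)) out$description <- as.character(tab$Description)
  if ("Part_of_CNV" %in% names(tab)) out$part_of_cnv <- as.character(tab$Part_of_CNV)
  if ("DE" %in% names(tab)) out$log2_de <- as.numeric(tab$DE)
  if ("P_Value" %in% names(tab)) out$fdr_p <- as.numeric(tab$P_Value)
  out
}

#' Gene annotation of the kochia EPSPS contig
#'
#' The 13 genes in and flanking the EPSPS copy-number variant on the
#' 399,779 bp susceptible-genome contig, with their log2 differential
#' expression (resistant vs susceptible) and FDR-adjusted p-values.
#' Shipped with the package as a plain TSV.
#'
#' @return A data.frame as returned by [read_gene_table()].
#' @export
kochia_gene_table <- function() {
  read_gene_table(system.file("extdata", "table1_genes.tsv",
                              package = "tandemloc", mustWork = TRUE))
}
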