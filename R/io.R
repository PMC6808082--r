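#' Read a FASTA file
#'
#' Wraps `Biostrings::readDNAStringSet` with strict validation: duplicate
#' record ids are an error, sequences are normalized to uppercase, and any
#' character outside A/C/G/T/N is an error naming the offending position.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) assert_dna(seqs[i], paste0("record '", ids[i], "'"))
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param records Named character vector (or named list) of DNA sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path` invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- unlist(as.list(records))
  if (is.null(names(records)) || any(names(records) == ""))
    stop("records must be named")
  set <- Biostrings::DNAStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' BED uses 0-based half-open intervals; these functions convert to and
#' from the package's 1-based inclusive convention at the boundary, and the
#' conversion round-trips exactly.
#'
#' @param path File path.
#' @return `read_bed`: data.frame `chrom`, `start`, `end`, `name` with
#'   1-based inclusive coordinates.
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED needs at least 3 columns")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (any(tab$start < 0) || any(tab$end < 0)) stop("negative BED coordinate")
  out <- data.frame(chrom = as.character(tab$chrom),
                    start = as.integer(tab$start) + 1L,
                    end = as.integer(tab$end),
                    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("BED interval with start >= end after conversion")
  out
}

#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional `name`.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$start < 1) || any(intervals$end < intervals$start))
    stop("invalid interval for BED output")
  out <- data.frame(chrom = intervals$chrom,
                    start = as.integer(intervals$start) - 1L,
                    end = as.integer(intervals$end))
  if ("name" %in% names(intervals)) out$name <- intervals$name
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a minimal GFF3 (1-based inclusive)
#'
#' @param path File path.
#' @return `read_gff3`: data.frame `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase`, `attributes`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(), attributes = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.delim(text = lines, header = FALSE,
                           stringsAsFactors = FALSE)
  names(tab) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(tab$start < 1) || any(tab$start > tab$end))
    stop("invalid GFF3 interval")
  tab
}

#' @param features data.frame as returned by `read_gff3`.
#' @rdname read_gff3
#' @export
write_gff3 <- function(features, path) {
  if (any(features$start < 1) || any(features$start > features$end))
    stop("invalid interval for GFF3 output")
  features <- features[order(features$seqid, features$start, features$end), ,
                       drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(features, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a simulated truth channel as GFF3
#'
#' Writes the repeat units (`repeat_unit` features with a `unit_type`
#' attribute), MGE insertions (`mobile_element`) and the CNV region
#' (`CNV_region`, on template coordinates) of a simulated resistant locus.
#'
#' @param truth A `SimulatedGenomeTruth`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_truth_gff3 <- function(truth, path) {
  units <- truth$unit_intervals
  mges <- truth$mge_intervals
  feats <- rbind(
    data.frame(seqid = "resistant", source = "tandemloc",
               type = "repeat_unit", start = units$start, end = units$end,
               score = ".",
               strand = ifelse(units$orientation == "forward", "+", "-"),
               phase = ".",
               attributes = sprintf("unit_type=%s", units$unit_type),
               stringsAsFactors = FALSE),
    data.frame(seqid = "resistant", source = "tandemloc",
               type = "mobile_element", start = mges$start, end = mges$end,
               score = ".", strand = "+", phase = ".",
               attributes = "name=MGE", stringsAsFactors = FALSE),
    data.frame(seqid = truth$template$contig_id, source = "tandemloc",
               type = "CNV_region", start = truth$cnv_interval[1],
               end = truth$cnv_interval[2], score = ".", strand = "+",
               phase = ".", attributes = "name=EPSPS_CNV",
               stringsAsFactors = FALSE))
  write_gff3(feats, path)
}

#' Read / write a Ct table TSV
#'
#' Columns `sample`, `replicate` (optional), `marker`, `ct`, with `NA` as
#' the no-amplification sentinel.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot(all(c("sample", "marker", "ct") %in% names(tab)))
  tab$ct <- as.numeric(tab$ct)
  tab
}

#' @param ct_table data.frame with `sample`, `replicate`, `marker`, `ct`.
#' @rdname read_ct_table
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write read placements as headerless TSV
#'
#' Columns: fragment id, start (1-based), length, strand.
#'
#' @param path File path.
#' @param source_length Source length to attach to the `ReadSet`.
#' @return `read_placements`: a `ReadSet`.
#' @export
read_placements <- function(path, source_length) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("fragment_id", "start", "length", "strand")
  tab$start <- as.integer(tab$start)
  tab$length <- as.integer(tab$length)
  structure(list(reads = tab, source_length = as.integer(source_length),
                 seed = NA_integer_), class = "ReadSet")
}

#' @param readset A `ReadSet`.
#' @rdname read_placements
#' @export
write_placements <- function(readset, path) {
  r <- readset$reads[order(readset$reads$start,
                           readset$reads$fragment_id), , drop = FALSE]
  utils::write.table(r[, c("fragment_id", "start", "length", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
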