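#' Simulate uniform short-read placements
#'
#' Places `round(coverage * L / read_length)` fixed-length reads with starts
#' uniform on `[1, L - read_length + 1]` and random strands. Placements only
#' (no sequencing-error model); sequences can be materialized with
#' [read_sequences()].
#'
#' @param sequence Source DNA string (or its length as a single number).
#' @param coverage Nominal fold coverage (> 0).
#' @param read_length Read length in bp (< source length).
#' @param seed Integer seed; placements are reproducible.
#' @return A `ReadSet`: list with `reads` (data.frame `fragment_id`, `start`,
#'   `length`, `strand`), `source_length`, `seed`.
#' @export
simulate_short_reads <- function(sequence, coverage, read_length, seed = 1L) {
  L <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  if (!is.numeric(coverage) || coverage <= 0) stop("coverage must be > 0")
  if (read_length <= 0) stop("read_length must be positive")
  if (read_length >= L) stop("read_length must be smaller than the source")
  n <- round(coverage * L / read_length)
  reads <- with_seed(seed, data.frame(
    fragment_id = sprintf("r%07d", seq_len(n)),
    start = sample.int(L - read_length + 1L, n, replace = TRUE),
    length = as.integer(read_length),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE))
  structure(list(reads = reads, source_length = L, seed = seed),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("<ReadSet> %d reads on a %s bp source\n", nrow(x$reads),
              format(x$source_length, big.mark = ",")))
  invisible(x)
}

#' Materialize read sequences from placements
#'
#' @param readset A `ReadSet`.
#' @param sequence The source DNA string the reads were placed on.
#' @param error_rate Optional uniform substitution rate per base (default 0).
#' @param seed Seed for substitution placement.
#' @return Character vector of read sequences, named by fragment id; minus
#'   strand reads are reverse-complemented.
#' @export
read_sequences <- function(readset, sequence, error_rate = 0, seed = 1L) {
  r <- readset$reads
  seqs <- substring(sequence, r$start, r$start + r$length - 1L)
  neg <- r$strand == "-"
  if (any(neg)) seqs[neg] <- vapply(seqs[neg], revcomp, character(1))
  if (error_rate > 0) {
    seqs <- with_seed(seed, vapply(seqs, function(s) {
      hit <- which(runif(nchar(s)) < error_rate)
      for (i in hit) {
        substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, i, i)), 1L)
      }
      s
    }, character(1), USE.NAMES = FALSE))
  }
  setNames(seqs, r$fragment_id)
}

#' Simulate BAC-like long fragments
#'
#' Draws `n` fragments with sizes uniform in `size_range` and positions
#' uniform along the source, carrying their true source interval for the
#' truth channel.
#'
#' @param sequence Source DNA string.
#' @param size_range Length-2 vector `(min, max)` in bp; max must not exceed
#'   the source length.
#' @param n Number of fragments.
#' @param seed Integer seed.
#' @return data.frame with `fragment_id`, `start`, `end`, `size`, `sequence`.
#' @export
simulate_long_fragments <- function(sequence, size_range, n, seed = 1L) {
  L <- nchar(sequence)
  if (length(size_range) != 2L || size_range[1] > size_range[2] ||
      size_range[1] < 1)
    stop("size_range must be (min, max) with 1 <= min <= max")
  if (size_range[2] > L) stop("size_range max exceeds source length")
  if (n == 0) {
    return(data.frame(fragment_id = character(), start = integer(),
                      end = integer(), size = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    sizes <- sample(seq.int(size_range[1], size_range[2]), n, replace = TRUE)
    starts <- vapply(sizes, function(s) sample.int(L - s + 1L, 1L), integer(1))
    data.frame(fragment_id = sprintf("bac%02d", seq_len(n)),
               start = starts, end = starts + sizes - 1L, size = sizes,
               sequence = substring(sequence, starts, starts + sizes - 1L),
               stringsAsFactors = FALSE)
  })
}

#' Per-base depth from read placements
#'
#' `depth[i]` counts the reads overlapping base `i`; consequently
#' `sum(depth)` equals the summed read lengths.
#'
#' @param reads A `ReadSet` or a data.frame with `start` and `length`.
#' @param contig_length Length of the contig the placements refer to.
#' @param contig_id Contig name for the profile.
#' @return A `DepthProfile`: list with `contig_id`, `depth` (numeric vector),
#'   `window` (1 for per-base).
#' @export
depth_from_placements <- function(reads, contig_length, contig_id = "contig") {
  r <- if (inherits(reads, "ReadSet")) reads$reads else reads
  L <- as.integer(contig_length)
  d <- numeric(L + 1L)
  if (nrow(r) > 0) {
    ends <- r$start + r$length - 1L
    bad <- which(r$start < 1L | ends > L)
    if (length(bad) > 0) {
      id <- if ("fragment_id" %in% names(r)) r$fragment_id[bad[1]] else bad[1]
      stop("read placement out of contig bounds: ", id)
    }
    inc <- tabulate(r$start, nbins = L)
    dec <- tabulate(ends + 1L, nbins = L + 1L)
    d <- cumsum(inc - dec[seq_len(L)])
  } else {
    d <- numeric(L)
  }
  structure(list(contig_id = contig_id, depth = as.numeric(d), window = 1L),
            class = "DepthProfile")
}

#' Project resistant-haplotype read placements onto template coordinates
#'
#' Stand-in for re-aligning resistant reads to the single-copy reference:
#' each read is assigned to the truth segment containing its midpoint and
#' mapped through that segment's affine (orientation-aware) transform. Reads
#' whose midpoint falls in an MGE have no template image and are dropped;
#' reads straddling a segment boundary are mapped via their midpoint segment
#' and clipped to the template.
#'
#' @param readset `ReadSet` simulated on the resistant sequence.
#' @param truth The `SimulatedGenomeTruth` the reads were simulated from.
#' @return A `ReadSet` on template coordinates.
#' @export
project_reads_to_template <- function(readset, truth) {
  r <- readset$reads
  segs <- truth$segments
  L <- nchar(truth$template$sequence)
  mid <- r$start + (r$length - 1L) %/% 2L
  seg_idx <- findInterval(mid, segs$start)
  keep <- segs$kind[seg_idx] != "mge"
  r <- r[keep, , drop = FALSE]
  seg_idx <- seg_idx[keep]
  fwd <- segs$orientation[seg_idx] == "forward"
  new_start <- integer(nrow(r))
  new_start[fwd] <- segs$template_start[seg_idx[fwd]] +
    (r$start[fwd] - segs$start[seg_idx[fwd]])
  rend <- r$start + r$length - 1L
  new_start[!fwd] <- segs$template_start[seg_idx[!fwd]] +
    (segs$end[seg_idx[!fwd]] - rend[!fwd])
  new_end <- new_start + r$length - 1L
  cl_start <- pmax(new_start, 1L)
  cl_end <- pmin(new_end, L)
  ok <- cl_end >= cl_start
  out <- data.frame(fragment_id = r$fragment_id[ok], start = cl_start[ok],
                    length = cl_end[ok] - cl_start[ok] + 1L,
                    strand = r$strand[ok], stringsAsFactors = FALSE)
  structure(list(reads = out, source_length = L, seed = readset$seed),
            class = "ReadSet")
}
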