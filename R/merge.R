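#' Greedily merge long fragments by suffix--prefix overlap
#'
#' Overlap-layout merging of BAC-scale fragments into the largest contiguous
#' sequence possible: repeatedly merge the pair with the longest
#' suffix--prefix overlap (either orientation) meeting the length and
#' identity thresholds, with a deterministic lexicographic tie-break, until
#' no qualifying overlap remains. Overlap identity is Hamming identity over
#' the overlap (no indel alignment; the default simulations are
#' error-free), and overlap candidates are located by an exact match of the
#' incoming fragment's leading `seed_k`-mer. A fragment fully contained in
#' another is absorbed.
#'
#' @param fragments Named character vector (or named list) of fragment
#'   sequences; names are fragment ids and must be unique.
#' @param min_overlap Minimum qualifying overlap, bp.
#' @param min_identity Minimum Hamming identity over the overlap.
#' @param seed_k Exact seed length used to locate candidate overlaps.
#' @return A `MetaAssembly`: list with `sequence` (largest contig),
#'   `contigs` (list of `sequence` + `members` data.frames with `id`,
#'   `offset` (0-based), `length`, `orientation`), `junctions` (data.frame
#'   `left`, `right`, `overlap`, `identity`).
#' @export
merge_fragments <- function(fragments, min_overlap = 1000L,
                            min_identity = 0.99, seed_k = 31L) {
  fragments <- unlist(as.list(fragments))
  ids <- names(fragments)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("fragments must have unique non-empty ids")
  contigs <- lapply(ids, function(id) {
    list(id = id, sequence = unname(fragments[[id]]),
         members = data.frame(id = id, offset = 0L,
                              length = nchar(fragments[[id]]),
                              orientation = "forward",
                              stringsAsFactors = FALSE))
  })
  names(contigs) <- ids
  junctions <- data.frame(left = character(), right = character(),
                          overlap = integer(), identity = numeric(),
                          stringsAsFactors = FALSE)

  repeat {
    n <- length(contigs)
    if (n < 2) break
    best <- NULL
    cids <- sort(names(contigs))
    for (a in cids) for (b in cids) {
      if (a == b) next
      for (flip in c(FALSE, TRUE)) {
        ov <- best_suffix_prefix(contigs[[a]]$sequence,
                                 if (flip) revcomp(contigs[[b]]$sequence)
                                 else contigs[[b]]$sequence,
                                 min_overlap, min_identity, seed_k)
        if (is.null(ov)) next
        cand <- list(a = a, b = b, flip = flip, overlap = ov$overlap,
                     identity = ov$identity, contained = ov$contained,
                     overlap_at = ov$overlap_at)
        if (is.null(best) || cand$overlap > best$overlap ||
            (cand$overlap == best$overlap &&
             paste(cand$a, cand$b) < paste(best$a, best$b)))
          best <- cand
      }
    }
    if (is.null(best)) break
    A <- contigs[[best$a]]
    B <- contigs[[best$b]]
    if (best$flip) B <- flip_contig(B)
    if (best$contained) {
      merged <- list(id = A$id, sequence = A$sequence, members = NULL)
      off <- best$overlap_at - 1L
    } else {
      merged <- list(id = A$id, sequence = paste0(
        A$sequence, substr(B$sequence, best$overlap + 1L, nchar(B$sequence))),
        members = NULL)
      off <- nchar(A$sequence) - best$overlap
    }
    Bm <- B$members
    Bm$offset <- Bm$offset + off
    merged$members <- rbind(A$members, Bm)
    junctions <- rbind(junctions, data.frame(
      left = best$a, right = best$b, overlap = best$overlap,
      identity = best$identity, stringsAsFactors = FALSE))
    contigs[[best$b]] <- NULL
    contigs[[best$a]] <- merged
  }

  lens <- vapply(contigs, function(ct) nchar(ct$sequence), integer(1))
  contigs <- contigs[order(-lens, names(contigs))]
  structure(list(sequence = contigs[[1]]$sequence,
                 contigs = unname(contigs), junctions = junctions),
            class = "MetaAssembly")
}

#' @export
print.MetaAssembly <- function(x, ...) {
  cat(sprintf("<MetaAssembly> %d contig(s), largest %s bp, %d member fragment(s)\n",
              length(x$contigs), format(nchar(x$sequence), big.mark = ","),
              nrow(x$contigs[[1]]$members)))
  invisible(x)
}

# Longest suffix(a)--prefix(b) overlap >= min_overlap at >= min_identity,
# located by exact match of b's first seed_k bases within a. Containment of
# b in a is reported with overlap = nchar(b).
best_suffix_prefix <- function(a, b, min_overlap, min_identity, seed_k) {
  la <- nchar(a)
  lb <- nchar(b)
  if (lb < seed_k || la < min_overlap) return(NULL)
  seed <- Biostrings::DNAString(substr(b, 1L, seed_k))
  hits <- Biostrings::matchPattern(seed, Biostrings::DNAString(a))
  if (length(hits) == 0) return(NULL)
  best <- NULL
  for (p in sort(BiocGenerics::start(hits))) {
    l <- la - p + 1L
    if (p + lb - 1L <= la) {
      # b contained in a
      idn <- hamming_identity(substr(a, p, p + lb - 1L), b)
      if (idn >= min_identity &&
          (is.null(best) || lb > best$overlap))
        best <- list(overlap = lb, identity = idn, contained = TRUE,
                     overlap_at = p)
      next
    }
    if (l < min_overlap || l > lb) next
    idn <- hamming_identity(substr(a, p, la), substr(b, 1L, l))
    if (idn >= min_identity && (is.null(best) || l > best$overlap))
      best <- list(overlap = l, identity = idn, contained = FALSE,
                   overlap_at = p)
  }
  best
}

hamming_identity <- function(x, y) {
  stopifnot(nchar(x) == nchar(y))
  if (nchar(x) == 0) return(1)
  xb <- utf8ToInt(x)
  yb <- utf8ToInt(y)
  mean(xb == yb)
}

flip_contig <- function(ct) {
  L <- nchar(ct$sequence)
  m <- ct$members
  m$offset <- L - m$offset - m$length
  m$orientation <- ifelse(m$orientation == "forward", "inverted", "forward")
  list(id = ct$id, sequence = revcomp(ct$sequence), members = m)
}

#' Check a meta-assembly's member invariant
#'
#' Every member fragment must match the assembled sequence at its recorded
#' offset (reverse-complemented for inverted members) at the given identity.
#'
#' @param meta A `MetaAssembly`.
#' @param fragments The original named fragment sequences.
#' @param min_identity Required Hamming identity.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_meta_assembly <- function(meta, fragments, min_identity = 0.99) {
  for (ct in meta$contigs) {
    for (i in seq_len(nrow(ct$members))) {
      m <- ct$members[i, ]
      piece <- substr(ct$sequence, m$offset + 1L, m$offset + m$length)
      frag <- fragments[[m$id]]
      if (m$orientation == "inverted") frag <- revcomp(frag)
      if (hamming_identity(piece, frag) < min_identity)
        stop("member ", m$id, " does not match its contig at offset ", m$offset)
    }
  }
  invisible(TRUE)
}
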