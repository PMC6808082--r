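#' Segment anchored blocks into typed repeat-unit calls
#'
#' Interprets a fragment's alignment blocks against the repeat-region
#' grammar: all unit templates share one downstream endpoint
#' (`shared_end`), so each pass of the reference coordinate through the
#' repeat region and back upstream is one unit. Blocks are clipped to the
#' repeat region; consecutive clipped blocks that continue monotonically in
#' the same orientation (small holes from non-unique k-mers) are merged;
#' every return-to-upstream starts a new unit. Each unit call is typed by
#' the nearest unit template with matching orientation whose endpoints agree
#' within `tol` of the template length; calls that fit no template (e.g.
#' units cut by the fragment end) are labeled `"partial"`, never
#' force-typed. Unanchored gaps between blocks are emitted as insertion
#' calls.
#'
#' @param blocks Alignment blocks from [anchor_fragment()].
#' @param unit_templates data.frame from [unit_template_table()].
#' @param shared_end Shared downstream endpoint (reference position).
#' @param tol Typing tolerance as a fraction of template length (default
#'   0.02).
#' @param min_insertion Minimum unanchored gap reported as an insertion, bp.
#' @param merge_gap Largest hole (bp, both coordinates) merged within a
#'   unit.
#' @param fragment_length Fragment length if known; used to flag calls
#'   touching the fragment ends as partial.
#' @param min_call Minimum reference span (bp) for a unit call; shorter
#'   groups are junction slivers (single coincidentally matching bases at an
#'   insertion boundary) and are discarded.
#' @return List with `units` (data.frame `frag_start`, `frag_end`,
#'   `unit_type`, `orientation`, `ref_start`, `ref_end`) and `insertions`
#'   (data.frame `frag_start`, `frag_end`, `length`).
#' @export
segment_units <- function(blocks, unit_templates, shared_end, tol = 0.02,
                          min_insertion = 100L, merge_gap = 1000L,
                          fragment_length = NULL, min_call = 50L) {
  empty_units <- data.frame(frag_start = integer(), frag_end = integer(),
                            unit_type = character(), orientation = character(),
                            ref_start = integer(), ref_end = integer(),
                            stringsAsFactors = FALSE)
  empty_ins <- data.frame(frag_start = integer(), frag_end = integer(),
                          length = integer(), stringsAsFactors = FALSE)
  if (nrow(blocks) == 0) return(list(units = empty_units, insertions = empty_ins))
  blocks <- blocks[order(blocks$frag_start), , drop = FALSE]
  if (nrow(blocks) > 1 &&
      any(blocks$frag_start[-1] <= blocks$frag_end[-nrow(blocks)]))
    stop("alignment blocks overlap on the fragment (anchoring bug)")

  # unanchored gaps between consecutive blocks
  insertions <- empty_ins
  if (nrow(blocks) > 1) {
    gs <- blocks$frag_end[-nrow(blocks)] + 1L
    ge <- blocks$frag_start[-1] - 1L
    keep <- (ge - gs + 1L) >= min_insertion
    insertions <- data.frame(frag_start = gs[keep], frag_end = ge[keep],
                             length = ge[keep] - gs[keep] + 1L,
                             stringsAsFactors = FALSE)
  }

  region_start <- min(unit_templates$ref_start)
  clipped <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    cs <- max(b$ref_start, region_start)
    ce <- min(b$ref_end, shared_end)
    if (cs > ce) return(NULL)
    if (b$orientation == "forward") {
      b$frag_start <- b$frag_start + (cs - b$ref_start)
      b$frag_end <- b$frag_end - (b$ref_end - ce)
    } else {
      b$frag_start <- b$frag_start + (b$ref_end - ce)
      b$frag_end <- b$frag_end - (cs - b$ref_start)
    }
    b$ref_start <- cs
    b$ref_end <- ce
    b
  })
  clipped <- do.call(rbind, clipped)
  if (is.null(clipped) || nrow(clipped) == 0)
    return(list(units = empty_units, insertions = insertions))

  # group clipped blocks into unit passes
  grp <- integer(nrow(clipped))
  g <- 1L
  grp[1] <- g
  if (nrow(clipped) > 1) {
    for (i in 2:nrow(clipped)) {
      prev <- clipped[i - 1L, ]
      cur <- clipped[i, ]
      continues <- prev$orientation == cur$orientation &&
        if (cur$orientation == "forward") {
          cur$ref_start > prev$ref_end &&
            cur$ref_start - prev$ref_end <= merge_gap &&
            cur$frag_start - prev$frag_end <= merge_gap
        } else {
          cur$ref_end < prev$ref_start &&
            prev$ref_start - cur$ref_end <= merge_gap &&
            cur$frag_start - prev$frag_end <= merge_gap
        }
      if (!continues) g <- g + 1L
      grp[i] <- g
    }
  }

  frag_len <- if (is.null(fragment_length)) max(blocks$frag_end) else fragment_length
  edge_tol <- 50L
  end_tol <- tol * min(unit_templates$length)
  units <- lapply(split(clipped, grp), function(bl) {
    call <- data.frame(frag_start = min(bl$frag_start),
                       frag_end = max(bl$frag_end),
                       ref_start = min(bl$ref_start),
                       ref_end = max(bl$ref_end),
                       orientation = bl$orientation[1],
                       stringsAsFactors = FALSE)
    if (call$ref_end - call$ref_start + 1L < min_call) return(NULL)
    cand <- unit_templates[unit_templates$orientation == call$orientation, ,
                           drop = FALSE]
    fits <- abs(call$ref_start - cand$ref_start) <= tol * cand$length &
      abs(call$ref_end - cand$ref_end) <= tol * cand$length
    cand <- cand[fits, , drop = FALSE]
    if (nrow(cand) > 0) {
      call_len <- call$ref_end - call$ref_start + 1L
      call$unit_type <- cand$unit_type[which.min(abs(call_len - cand$length))]
    } else {
      # cut by the fragment end, or an incomplete pass through the region:
      # partial when it at least reaches the shared endpoint or a fragment
      # edge; otherwise it is a flank overhang into the region and no call
      at_edge <- call$frag_start <= edge_tol ||
        call$frag_end >= frag_len - edge_tol
      reaches_end <- abs(call$ref_end - shared_end) <= end_tol
      if (!at_edge && !reaches_end) return(NULL)
      call$unit_type <- "partial"
    }
    call[, c("frag_start", "frag_end", "unit_type", "orientation",
             "ref_start", "ref_end")]
  })
  units <- do.call(rbind, units)
  if (is.null(units)) units <- empty_units
  rownames(units) <- NULL
  list(units = units, insertions = insertions)
}

#' Is an unanchored insertion novel to the reference?
#'
#' Re-anchors the insertion sequence to the reference: the insertion is
#' `novel` iff anchored blocks cover less than `coverage_threshold` of it
#' (default 20%), `known` otherwise (e.g. a transposed copy of reference
#' sequence). A zero-length gap yields no call (`NULL`).
#'
#' @param insertion_seq The unanchored gap's sequence.
#' @param reference Reference DNA string.
#' @param k Seed length for re-anchoring.
#' @param coverage_threshold Anchored fraction below which the insertion is
#'   called novel.
#' @return List `status` (`"novel"`/`"known"`), `length`,
#'   `anchored_fraction`; `NULL` for an empty sequence.
#' @export
detect_novel_insertion <- function(insertion_seq, reference, k = 21L,
                                   coverage_threshold = 0.2) {
  len <- nchar(insertion_seq)
  if (len == 0) return(NULL)
  blocks <- anchor_fragment(insertion_seq, reference, k = k)
  covered <- if (nrow(blocks) == 0) 0L else {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(blocks$frag_start, blocks$frag_end))))
  }
  frac <- covered / len
  list(status = if (frac < coverage_threshold) "novel" else "known",
       length = len, anchored_fraction = frac)
}
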