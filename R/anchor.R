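#' Anchor a fragment to a reference by unique k-mer seeds
#'
#' Finds maximal chains of collinear, reference-unique k-mer matches between
#' a fragment and a single-copy reference, on both strands. Seeds on the
#' same (anti)diagonal are merged into a block when the gap between
#' consecutive seeds is at most `max_gap`; with `max_gap = 0` blocks are
#' exactly the unique maximal exact matches. Orientation comes from the
#' matching strand. Because the matching is exact and gap-free, block
#' identity is 1 by construction.
#'
#' @param fragment DNA string to anchor.
#' @param reference Reference DNA string (indexed by unique k-mers over both
#'   strands; k-mers occurring more than once anywhere, including
#'   palindromic ones, never seed).
#' @param k Seed length (>= 11).
#' @param max_gap Largest hole (in seed start positions) bridged within one
#'   block.
#' @return data.frame of alignment blocks sorted by fragment position:
#'   `frag_start`, `frag_end`, `ref_start`, `ref_end`, `orientation`
#'   (`"forward"`/`"inverted"`), `identity`, `n_seeds`. Zero rows when the
#'   fragment is shorter than `k` or nothing anchors.
#' @export
anchor_fragment <- function(fragment, reference, k = 21L, max_gap = 100L) {
  stopifnot(k >= 11L)
  empty <- data.frame(frag_start = integer(), frag_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      orientation = character(), identity = numeric(),
                      n_seeds = integer(), stringsAsFactors = FALSE)
  if (nchar(fragment) < k) return(empty)
  L <- nchar(reference)
  ref_f <- all_kmers(reference, k)
  ref_r <- all_kmers(revcomp(reference), k)
  comb <- c(ref_f, ref_r)
  unique_kmer <- !(duplicated(comb) | duplicated(comb, fromLast = TRUE))
  fq <- all_kmers(fragment, k)
  idx <- match(fq, comb)
  ok <- !is.na(idx) & unique_kmer[ifelse(is.na(idx), 1L, idx)]
  if (!any(ok)) return(empty)
  i <- which(ok)                      # fragment seed starts
  idx <- idx[ok]
  nf <- length(ref_f)
  fwd <- idx <= nf

  blocks <- list()
  if (any(fwd)) {
    fi <- i[fwd]
    rp <- idx[fwd]                    # plus-strand start
    diag <- rp - fi
    for (d in unique(diag)) {
      ii <- sort(fi[diag == d])
      cut <- c(0L, which(diff(ii) > max_gap + 1L), length(ii))
      for (b in seq_len(length(cut) - 1L)) {
        run <- ii[(cut[b] + 1L):cut[b + 1L]]
        blocks[[length(blocks) + 1L]] <- data.frame(
          frag_start = run[1], frag_end = run[length(run)] + k - 1L,
          ref_start = run[1] + d, ref_end = run[length(run)] + k - 1L + d,
          orientation = "forward", identity = 1, n_seeds = length(run),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (any(!fwd)) {
    fi <- i[!fwd]
    j <- idx[!fwd] - nf               # start within revcomp(reference)
    p <- L - j - k + 2L               # plus-strand start of the matched k-mer
    anti <- p + fi
    for (a in unique(anti)) {
      ii <- sort(fi[anti == a])
      cut <- c(0L, which(diff(ii) > max_gap + 1L), length(ii))
      for (b in seq_len(length(cut) - 1L)) {
        run <- ii[(cut[b] + 1L):cut[b + 1L]]
        lo <- run[1]
        hi <- run[length(run)]
        blocks[[length(blocks) + 1L]] <- data.frame(
          frag_start = lo, frag_end = hi + k - 1L,
          ref_start = a - hi, ref_end = a - lo + k - 1L,
          orientation = "inverted", identity = 1, n_seeds = length(run),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$frag_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
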