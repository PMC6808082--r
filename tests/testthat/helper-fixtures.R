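# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

mini_template <- function() {
  memo("mini_template",
       function() build_susceptible_locus(locus_layout("mini"), seed = 101))
}

mini_sizes <- function() repeat_unit_sizes("mini")

# six-repeat resistant locus on the mini template
mini_truth6 <- function() {
  memo("mini_truth6", function() {
    build_resistant_locus(mini_template(),
                          default_six_repeat_spec(sizes = mini_sizes()),
                          seed = 102)
  })
}

# resistant locus of n full units (mini scale)
mini_truth_full <- function(n = 6) {
  memo(paste0("mini_truth_full_", n), function() {
    spec <- repeat_array_spec(rep("full", n), sizes = mini_sizes())
    build_resistant_locus(mini_template(), spec, seed = 103)
  })
}

# --- brute-force maximal exact match oracle (both strands) ----------------
# Enumerates, by diagonal run-length scanning, every maximal exact match of
# length >= k between fragment and reference. Independent of the k-mer
# seed-and-chain implementation.
oracle_blocks <- function(fragment, reference, k) {
  fw <- oracle_one_strand(fragment, reference, k)
  if (nrow(fw) > 0) fw$orientation <- "forward"
  L <- nchar(reference)
  rv <- oracle_one_strand(fragment, revcomp(reference), k)
  if (nrow(rv) > 0) {
    rv$orientation <- "inverted"
    # map revcomp-reference coordinates back to plus strand
    rs <- L - rv$ref_end + 1L
    re <- L - rv$ref_start + 1L
    rv$ref_start <- rs
    rv$ref_end <- re
  }
  out <- rbind(fw, rv)
  out[order(out$frag_start, out$ref_start, out$orientation), , drop = FALSE]
}

oracle_one_strand <- function(fragment, reference, k) {
  f <- strsplit(fragment, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  nf <- length(f)
  nr <- length(r)
  rows <- list()
  for (d in (1L - nf):(nr - 1L)) {
    i1 <- max(1L, 1L - d)
    i2 <- min(nf, nr - d)
    if (i2 - i1 + 1L < k) next
    idx <- i1:i2
    eq <- f[idx] == r[idx + d]
    runs <- rle(eq)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values & runs$lengths >= k)) {
      fs <- idx[starts[j]]
      fe <- idx[ends[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        frag_start = fs, frag_end = fe, ref_start = fs + d, ref_end = fe + d,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(frag_start = integer(), frag_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# random reference whose k-mers are all unique across both strands, so the
# oracle's maximal-match set coincides with unique-anchor blocks
unique_kmer_reference <- function(n, k) {
  repeat {
    ref <- random_dna(n)
    comb <- c(all_kmers_test(ref, k), all_kmers_test(revcomp(ref), k))
    if (!anyDuplicated(comb)) return(ref)
  }
}

all_kmers_test <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

# Compose a fragment from reference segments (with orientations) joined by
# novel spacers, recording truth blocks. Junction bases are chosen so that
# no exact match extends across a junction by coincidence.
compose_fragment <- function(reference, segments, spacer_lengths) {
  L <- nchar(reference)
  pieces <- character(0)
  truth <- list()
  pos <- 1L
  pick_base <- function(forbidden) {
    setdiff(c("A", "C", "G", "T"), forbidden)[1]
  }
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    piece <- substr(reference, sg$start, sg$end)
    if (sg$orientation == "inverted") piece <- revcomp(piece)
    sp_len <- spacer_lengths[i]
    spacer <- random_dna(sp_len)
    # base right before this segment must not extend the match upstream
    forb_prev <- if (sg$orientation == "forward") {
      if (sg$start > 1) substr(reference, sg$start - 1L, sg$start - 1L) else ""
    } else {
      if (sg$end < L) revcomp(substr(reference, sg$end + 1L, sg$end + 1L)) else ""
    }
    substr(spacer, sp_len, sp_len) <- pick_base(forb_prev)
    pieces <- c(pieces, spacer)
    pos <- pos + sp_len
    truth[[length(truth) + 1L]] <- data.frame(
      frag_start = pos, frag_end = pos + nchar(piece) - 1L,
      ref_start = sg$start, ref_end = sg$end, orientation = sg$orientation,
      stringsAsFactors = FALSE)
    pieces <- c(pieces, piece)
    pos <- pos + nchar(piece)
  }
  # trailing spacer; first base must not extend the last segment downstream
  sg <- segments[[length(segments)]]
  forb_next <- if (sg$orientation == "forward") {
    if (sg$end < L) substr(reference, sg$end + 1L, sg$end + 1L) else ""
  } else {
    if (sg$start > 1) revcomp(substr(reference, sg$start - 1L, sg$start - 1L)) else ""
  }
  tail_spacer <- random_dna(spacer_lengths[length(spacer_lengths)])
  substr(tail_spacer, 1L, 1L) <- pick_base(forb_next)
  pieces <- c(pieces, tail_spacer)
  # also fix each internal spacer's first base against the preceding segment
  frag <- paste(pieces, collapse = "")
  truth_df <- do.call(rbind, truth)
  # re-fix: base immediately after each segment must not extend it
  for (i in seq_len(nrow(truth_df))) {
    fe <- truth_df$frag_end[i]
    if (fe >= nchar(frag)) next
    sg <- segments[[i]]
    forb <- if (sg$orientation == "forward") {
      if (sg$end < L) substr(reference, sg$end + 1L, sg$end + 1L) else ""
    } else {
      if (sg$start > 1) revcomp(substr(reference, sg$start - 1L, sg$start - 1L)) else ""
    }
    if (substr(frag, fe + 1L, fe + 1L) == forb)
      substr(frag, fe + 1L, fe + 1L) <- pick_base(forb)
  }
  list(sequence = frag, truth = truth_df)
}
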