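#' Comparative-Ct relative copy number
#'
#' Copy number relative to two single-copy reference genes:
#' `2^DeltaCt` with `DeltaCt = (Ct(ALS) + Ct(CPS))/2 - Ct(marker)`.
#' Vectorized over markers. An absent (NA) marker Ct means no amplification
#' and yields an NA copy call (distinct from 0 copies); an absent reference
#' Ct is an error, since the references must amplify.
#'
#' @param ct_marker Marker Ct value(s), in cycles; NA for no amplification.
#' @param ct_als,ct_cps Reference Ct values (positive, non-NA).
#' @return Numeric copy number(s); NA where the marker did not amplify.
#' @export
relative_copy_number <- function(ct_marker, ct_als, ct_cps) {
  if (anyNA(ct_als) || anyNA(ct_cps))
    stop("reference Ct is missing: ALS and CPS must amplify")
  if (any(ct_als <= 0) || any(ct_cps <= 0))
    stop("reference Ct values must be positive")
  if (any(!is.na(ct_marker) & ct_marker <= 0))
    stop("marker Ct values must be positive when present")
  2^((ct_als + ct_cps) / 2 - ct_marker)
}

#' Quantify a Ct table against the ALS/CPS references
#'
#' Computes per-replicate copy calls for every non-reference marker, never
#' silently averaging Cts across replicates; use [summarize_copy_calls()]
#' for per-line mean +/- sd.
#'
#' @param ct_table data.frame with `sample`, `replicate`, `marker`, `ct`
#'   (NA = no amplification), e.g. from [simulate_qpcr()] or
#'   [read_ct_table()].
#' @param ref_markers Names of the two reference markers.
#' @return data.frame `sample`, `replicate`, `marker`, `ct`, `copies`.
#' @export
quantify_ct_table <- function(ct_table, ref_markers = c("ALS", "CPS")) {
  stopifnot(all(c("sample", "marker", "ct") %in% names(ct_table)))
  if (!"replicate" %in% names(ct_table)) ct_table$replicate <- 1L
  key <- interaction(ct_table$sample, ct_table$replicate, drop = TRUE)
  out <- lapply(split(ct_table, key), function(g) {
    refs <- vapply(ref_markers,
                   function(m) {
                     ct <- g$ct[g$marker == m]
                     if (length(ct) != 1L)
                       stop("expected exactly one ", m, " Ct per sample/replicate")
                     ct
                   }, numeric(1))
    tgt <- g[!g$marker %in% ref_markers, , drop = FALSE]
    tgt$copies <- relative_copy_number(tgt$ct, refs[1], refs[2])
    tgt
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample, out$replicate, out$marker), ]
}

#' Per-sample copy-call summaries
#'
#' @param calls Output of [quantify_ct_table()].
#' @return data.frame `sample`, `marker`, `n`, `mean_copies`, `sd_copies`,
#'   `n_no_amplification`.
#' @export
summarize_copy_calls <- function(calls) {
  key <- interaction(calls$sample, calls$marker, drop = TRUE)
  out <- lapply(split(calls, key), function(g) {
    data.frame(sample = g$sample[1], marker = g$marker[1],
               n = sum(!is.na(g$copies)),
               mean_copies = mean(g$copies, na.rm = TRUE),
               sd_copies = stats::sd(g$copies, na.rm = TRUE),
               n_no_amplification = sum(is.na(g$copies)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample, out$marker), ]
}

#' Define a qPCR marker
#'
#' @param name Marker name.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param expected_amplicon Length-2 vector `(min, max)` amplicon size in bp,
#'   within (0, 1000).
#' @return A `MarkerDef` list.
#' @export
marker_def <- function(name, forward, reverse, expected_amplicon = c(100, 200)) {
  stopifnot(nchar(forward) > 0, nchar(reverse) > 0,
            length(expected_amplicon) == 2L,
            expected_amplicon[1] > 0, expected_amplicon[2] < 1000,
            expected_amplicon[1] <= expected_amplicon[2])
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse),
                 expected_amplicon = as.integer(expected_amplicon)),
            class = "MarkerDef")
}

#' Would a marker amplify on a template?
#'
#' In-silico PCR with exact matching: the marker amplifies iff the forward
#' primer matches a site and the reverse complement of the reverse primer
#' matches downstream of it within the expected amplicon range (correct
#' relative orientation). Both template strands are examined, so presence is
#' strand-symmetric. Junction markers amplify only when the two sequences
#' they span are joined, which is how repeat-junction and boundary markers
#' discriminate resistant from susceptible templates.
#'
#' @param marker A `MarkerDef`.
#' @param template DNA string.
#' @return List: `present` (logical), `start`, `end` (amplicon interval on
#'   the given template, NA when absent), `strand`.
#' @export
marker_amplifies <- function(marker, template) {
  stopifnot(nchar(template) > 0)
  hit <- amplicon_on_strand(marker, template)
  if (!is.null(hit))
    return(list(present = TRUE, start = hit[1], end = hit[2], strand = "+"))
  L <- nchar(template)
  hit <- amplicon_on_strand(marker, revcomp(template))
  if (!is.null(hit)) {
    return(list(present = TRUE, start = L - hit[2] + 1L, end = L - hit[1] + 1L,
                strand = "-"))
  }
  list(present = FALSE, start = NA_integer_, end = NA_integer_,
       strand = NA_character_)
}

amplicon_on_strand <- function(marker, template) {
  subj <- Biostrings::DNAString(template)
  f <- Biostrings::matchPattern(Biostrings::DNAString(marker$forward), subj)
  if (length(f) == 0) return(NULL)
  rrc <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(marker$reverse)), subj)
  if (length(rrc) == 0) return(NULL)
  fs <- BiocGenerics::start(f)
  re <- BiocGenerics::end(rrc)
  for (s in fs) {
    len <- re - s + 1L
    ok <- which(len >= marker$expected_amplicon[1] &
                len <= marker$expected_amplicon[2])
    if (length(ok) > 0) return(c(s, re[ok[1]]))
  }
  NULL
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2 * (A + T) + 4 * (G + C)` in degrees C. A simple, deterministic
#' rule appropriate for short (~20 bp) primers.
#'
#' @param primer Primer sequence.
#' @return Tm in degrees Celsius.
#' @export
wallace_tm <- function(primer) {
  b <- strsplit(toupper(primer), "")[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

#' GC content of a sequence
#' @param x DNA string.
#' @return Fraction of G+C bases.
#' @export
gc_content <- function(x) {
  b <- strsplit(toupper(x), "")[[1]]
  sum(b %in% c("G", "C")) / length(b)
}

#' Validate a primer pair against design constraints
#'
#' Checks each primer's melting temperature (Wallace rule), GC content and
#' length, plus the expected amplicon size, against the supplied ranges;
#' every violated constraint is reported, not just the first. Defaults are
#' the design rules used for the locus markers: Tm 51--56 C, GC 40--50%,
#' length 20--24 bp, amplicon 100--200 bp.
#'
#' @param marker A `MarkerDef`.
#' @param tm_range,gc_range,len_range,amplicon_range Closed ranges for each
#'   constraint (GC as fractions).
#' @return List: `pass` (logical), `reasons` (character vector of violated
#'   constraints, empty on pass).
#' @export
validate_primer_pair <- function(marker, tm_range = c(51, 56),
                                 gc_range = c(0.40, 0.50),
                                 len_range = c(20, 24),
                                 amplicon_range = c(100, 200)) {
  reasons <- character(0)
  for (side in c("forward", "reverse")) {
    p <- marker[[side]]
    if (grepl("[^ACGT]", p)) {
      reasons <- c(reasons, sprintf("%s primer contains non-ACGT characters", side))
      next
    }
    n <- nchar(p)
    if (n < len_range[1] || n > len_range[2])
      reasons <- c(reasons, sprintf("%s primer length %d outside [%d, %d]",
                                    side, n, len_range[1], len_range[2]))
    tm <- wallace_tm(p)
    if (tm < tm_range[1] || tm > tm_range[2])
      reasons <- c(reasons, sprintf("%s primer Tm %.0f outside [%.0f, %.0f]",
                                    side, tm, tm_range[1], tm_range[2]))
    gc <- gc_content(p)
    if (gc < gc_range[1] || gc > gc_range[2])
      reasons <- c(reasons, sprintf("%s primer GC %.2f outside [%.2f, %.2f]",
                                    side, gc, gc_range[1], gc_range[2]))
  }
  amp <- marker$expected_amplicon
  if (amp[1] < amplicon_range[1] || amp[2] > amplicon_range[2])
    reasons <- c(reasons, sprintf("amplicon range [%d, %d] outside [%d, %d]",
                                  amp[1], amp[2], amplicon_range[1],
                                  amplicon_range[2]))
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Repeat-associated copies after background subtraction
#'
#' The element internal to the repeat structure also exists elsewhere in the
#' genome; subtracting that background from the total yields the
#' repeat-associated count. Scalars subtract directly (clipped at 0 with a
#' warning if the background exceeds the total). Length-2 ranges are
#' combined under two conventions, both reported: naive interval arithmetic
#' `[lo_t - hi_b, hi_t - lo_b]`, and same-rank pairing
#' `[lo_t - lo_b, hi_t - hi_b]`.
#'
#' @param total Total copies: scalar or `(lo, hi)` range.
#' @param background Background copies: scalar or `(lo, hi)` range.
#' @return Scalar when both inputs are scalars; otherwise a data.frame with
#'   `convention`, `low`, `high`.
#' @export
infer_repeat_associated_copies <- function(total, background) {
  if (any(background < 0) || any(total < 0)) stop("copies must be >= 0")
  if (length(total) == 1L && length(background) == 1L) {
    if (total < background) {
      warning("total below background; clipping at 0")
      return(0)
    }
    return(total - background)
  }
  total <- range(total)
  background <- range(background)
  out <- data.frame(
    convention = c("naive", "same_rank"),
    low = pmax(0, c(total[1] - background[2], total[1] - background[1])),
    high = pmax(0, c(total[2] - background[1], total[2] - background[2])),
    stringsAsFactors = FALSE)
  if (any(out$high < out$low)) warning("range subtraction produced an empty interval")
  out
}
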