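#' Define a read-counting unit with mask intervals
#'
#' A named interval on a reference together with repeat-mask intervals that
#' are excluded from counting (masking guards the depth signal against
#' mapping inflation in repetitive sequence).
#'
#' @param name Unit name, e.g. `"upstream_flank"`, `"full_repeat"`,
#'   `"shared_repeat_core"`, `"mge"`.
#' @param start,end 1-based inclusive interval on the reference.
#' @param mask Optional data.frame of mask intervals (`start`, `end`),
#'   clipped to the unit; the unmasked length must stay positive.
#' @return A `UnitDefinition` list.
#' @export
unit_definition <- function(name, start, end, mask = NULL) {
  stopifnot(start >= 1, end >= start)
  if (is.null(mask)) {
    mask <- data.frame(start = integer(), end = integer())
  } else {
    mask$start <- pmax(as.integer(mask$start), as.integer(start))
    mask$end <- pmin(as.integer(mask$end), as.integer(end))
    mask <- mask[mask$end >= mask$start, , drop = FALSE]
    if (nrow(mask) > 0) {
      ir <- IRanges::reduce(IRanges::IRanges(mask$start, mask$end))
      mask <- data.frame(start = BiocGenerics::start(ir),
                         end = BiocGenerics::end(ir))
    }
  }
  masked <- sum(iv_width(mask$start, mask$end))
  unmasked <- iv_width(start, end) - masked
  if (unmasked <= 0) stop("unit '", name, "' has no unmasked length")
  structure(list(name = name, start = as.integer(start), end = as.integer(end),
                 mask = mask, unmasked_length = as.integer(unmasked)),
            class = "UnitDefinition")
}

#' Flank-normalized per-unit copy number from read counts
#'
#' For each unit, counts the reads assigned to it (a read counts for every
#' unit covering at least half of the read, provided the read midpoint is
#' unmasked), converts to reads per unmasked kb, and normalizes by the mean
#' rate of the two single-copy flanking units. The flank-normalized rate is
#' the estimated copy number; the flanks themselves come out at ~1 by
#' construction.
#'
#' @param reads A `ReadSet` or data.frame with `start` and `length`, placed
#'   on the same reference as the units.
#' @param units List of [unit_definition()] objects.
#' @param flank_units Names of the two single-copy flank units.
#' @return data.frame with one row per unit: `unit`, `start`, `end`,
#'   `unmasked_length`, `reads_mapped`, `reads_per_unmasked_kb`,
#'   `normalized_copies`.
#' @export
estimate_unit_copy_number <- function(reads, units,
                                      flank_units = c("upstream_flank",
                                                      "downstream_flank")) {
  r <- if (inherits(reads, "ReadSet")) reads$reads else reads
  names(units) <- vapply(units, `[[`, character(1), "name")
  miss <- setdiff(flank_units, names(units))
  if (length(miss) > 0)
    stop("flank unit(s) not in unit list: ", paste(miss, collapse = ", "))
  rstart <- r$start
  rend <- r$start + r$length - 1L
  rmid <- r$start + (r$length - 1L) %/% 2L
  rows <- lapply(units, function(u) {
    olap <- pmin(rend, u$end) - pmax(rstart, u$start) + 1L
    assigned <- olap >= r$length / 2
    if (nrow(u$mask) > 0 && any(assigned)) {
      masked_mid <- rep(FALSE, length(rmid))
      for (j in seq_len(nrow(u$mask))) {
        masked_mid <- masked_mid |
          (rmid >= u$mask$start[j] & rmid <= u$mask$end[j])
      }
      assigned <- assigned & !masked_mid
    }
    cnt <- sum(assigned)
    data.frame(unit = u$name, start = u$start, end = u$end,
               unmasked_length = u$unmasked_length, reads_mapped = cnt,
               reads_per_unmasked_kb = cnt / (u$unmasked_length / 1000),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  flank_rates <- out$reads_per_unmasked_kb[match(flank_units, out$unit)]
  baseline <- mean(flank_rates)
  if (baseline == 0)
    stop("zero reads on both flanks: copy-number baseline undefined")
  out$normalized_copies <- out$reads_per_unmasked_kb / baseline
  out
}

#' Deconvolve full vs truncated repeat copies
#'
#' The shared repeat core aggregates reads from every repeat type, so its
#' flank-normalized estimate is the total array copy number, while the
#' full-repeat-only region counts just the full-length units. Solving the
#' resulting 2x2 linear system gives per-type counts: full = full-only
#' estimate; truncated-or-other = shared estimate minus full-only estimate.
#'
#' @param full_only_copies Normalized copies of the region private to the
#'   full-length repeat.
#' @param shared_copies Normalized copies of the region shared by all repeat
#'   types.
#' @return Named numeric vector `c(full = ..., truncated = ...)`; a negative
#'   truncated count is clipped at 0 with a warning.
#' @export
deconvolve_repeat_copies <- function(full_only_copies, shared_copies) {
  trunc <- shared_copies - full_only_copies
  if (trunc < 0) {
    warning("shared estimate below full-only estimate; clipping at 0")
    trunc <- 0
  }
  c(full = full_only_copies, truncated = trunc)
}

#' Standard unit set for a simulated resistant locus
#'
#' Convenience constructor of the four counting units used for copy-number
#' estimation on template coordinates: the two single-copy flanks, the
#' full-repeat span, and the shared repeat core (the truncated-repeat span,
#' whose reads come from every repeat type).
#'
#' @param template A `LocusTemplate`.
#' @param sizes Size profile; defaults to the template's scale.
#' @return Named list of `UnitDefinition`s: `upstream_flank`, `full_repeat`,
#'   `shared_repeat_core`, `downstream_flank`.
#' @export
template_unit_set <- function(template, sizes = NULL) {
  tab <- unit_template_table(template, sizes)
  rownames(tab) <- tab$unit_type
  full <- tab["full", ]
  trunc <- tab["truncated", ]
  L <- nchar(template$sequence)
  list(
    upstream_flank = unit_definition("upstream_flank", 1L, full$ref_start - 1L),
    full_repeat = unit_definition("full_repeat", full$ref_start, full$ref_end),
    shared_repeat_core = unit_definition("shared_repeat_core",
                                         trunc$ref_start, trunc$ref_end),
    downstream_flank = unit_definition("downstream_flank",
                                       full$ref_end + 1L, L)
  )
}
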