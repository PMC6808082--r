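#' Repeat-unit size profile
#'
#' Default sizes of the five observed repeat-unit types and of the mobile
#' genetic element (MGE) spacer, in bp. The full and inverted-full units are
#' 56.1 kb, the truncated unit 32.7 kb, the minimal inverted unit 18.2 kb,
#' the forward variant 33.1 kb, and the MGE 16,037 bp. The `"mini"` profile
#' divides everything by 20 to match [locus_layout()]'s mini template.
#'
#' @param profile `"kochia"` or `"mini"`.
#' @return A list with `units` (named integer vector by unit type),
#'   `orientations` (named character vector), `mge` (MGE length).
#' @export
repeat_unit_sizes <- function(profile = c("kochia", "mini")) {
  profile <- match.arg(profile)
  scale <- if (profile == "mini") 20L else 1L
  units <- c(full = 56100L, truncated = 32700L, inverted_full = 56100L,
             inverted_minimal = 18200L, forward_variant = 33100L)
  list(units = as.integer(round(units / scale)) |> setNames(names(units)),
       orientations = c(full = "forward", truncated = "forward",
                        inverted_full = "inverted",
                        inverted_minimal = "inverted",
                        forward_variant = "forward"),
       mge = as.integer(round(16037L / scale)))
}

#' Specify a resistant repeat array
#'
#' An ordered list of repeat units, each optionally preceded by an MGE
#' spacer, with an optional MGE at the outer downstream boundary so the
#' element flanks the whole array on both sides. All units share one
#' downstream endpoint on the template (directly after the EPSPS gene); the
#' upstream start varies by unit type.
#'
#' @param units Character vector of unit types in array order, from
#'   `c("full", "truncated", "inverted_full", "inverted_minimal",
#'   "forward_variant")`.
#' @param mge_before Logical vector (recycled) saying whether an MGE spacer
#'   precedes each unit.
#' @param flanking_mge If `TRUE`, an MGE also closes the array downstream so
#'   that with `mge_before` everywhere the MGE count is unit count + 1 (one
#'   MGE associated with each repeat plus the outer boundary).
#' @param sizes Size profile from [repeat_unit_sizes()].
#' @param mge_sequence Optional explicit MGE sequence; by default one is
#'   generated by [build_resistant_locus()].
#' @param microhomology Number of leading MGE bases copied from the template
#'   at the truncated-repeat start so that the MGE start and the 32.7-kb
#'   repeat start share a short stretch of perfect identity (default 7 bp,
#'   the microhomology implicated in the truncation mechanism). 0 disables.
#' @return A `RepeatArraySpec` object.
#' @export
repeat_array_spec <- function(units, mge_before = TRUE, flanking_mge = TRUE,
                              sizes = repeat_unit_sizes(), mge_sequence = NULL,
                              microhomology = 7L) {
  known <- names(sizes$units)
  if (!all(units %in% known))
    stop("unknown unit type(s): ", paste(setdiff(units, known), collapse = ", "))
  mge_before <- rep_len(as.logical(mge_before), length(units))
  structure(list(units = as.character(units), mge_before = mge_before,
                 flanking_mge = isTRUE(flanking_mge), sizes = sizes,
                 mge_sequence = mge_sequence,
                 microhomology = as.integer(microhomology)),
            class = "RepeatArraySpec")
}

#' The six-repeat array observed in the resistant line
#'
#' Two full 56.1-kb units plus one of each other type, every unit preceded
#' by an MGE and the array flanked by MGEs on both sides -- the composition
#' reconstructed from the BAC meta-assembly (six EPSPS copies, seven MGEs).
#' The within-array order of the rarer types is a modeling choice.
#'
#' @inheritParams repeat_array_spec
#' @return A `RepeatArraySpec`.
#' @export
default_six_repeat_spec <- function(sizes = repeat_unit_sizes()) {
  repeat_array_spec(c("full", "truncated", "full", "inverted_full",
                      "inverted_minimal", "forward_variant"),
                    mge_before = TRUE, flanking_mge = TRUE, sizes = sizes)
}

# Table of per-type template reference spans: every unit ends at shared_end.
# Exported because unit typing in segment_units() consumes it.

#' Reference spans of the repeat-unit templates
#'
#' Computes, for each unit type, the template interval it copies:
#' `[shared_end - size + 1, shared_end]`, where `shared_end` is the common
#' downstream endpoint directly after the EPSPS gene.
#'
#' @param template A `LocusTemplate`.
#' @param sizes Size profile from [repeat_unit_sizes()]; defaults to the
#'   profile matching the template scale.
#' @return data.frame with `unit_type`, `ref_start`, `ref_end`,
#'   `orientation`, `length`.
#' @export
unit_template_table <- function(template, sizes = NULL) {
  if (is.null(sizes))
    sizes <- repeat_unit_sizes(if (template$scale > 1L) "mini" else "kochia")
  shared_end <- shared_downstream_end(template)
  data.frame(unit_type = names(sizes$units),
             ref_start = shared_end - as.integer(sizes$units) + 1L,
             ref_end = shared_end,
             orientation = unname(sizes$orientations[names(sizes$units)]),
             length = as.integer(sizes$units),
             stringsAsFactors = FALSE)
}

#' Shared downstream endpoint of all repeat units
#'
#' All repeat units end at the same template base, directly after the EPSPS
#' gene: its annotated end coordinate.
#'
#' @param template A `LocusTemplate`.
#' @return Template position (1-based).
#' @export
shared_downstream_end <- function(template) {
  g <- template$genes[template$genes$gene_id == template$epsps_gene_id, ]
  if (nrow(g) != 1L) stop("template has no EPSPS gene record")
  g$end
}

# Generate an MGE sequence foreign to the template: random DNA none of whose
# k-mers occurs in the template, with an optional microhomology prefix copied
# from the truncated-repeat start.
generate_mge_sequence <- function(template, length, microhomology = 7L,
                                  trunc_start = NULL, k = 21L) {
  tkmers <- all_kmers(template$sequence, k)
  tkmers <- unique(c(tkmers, all_kmers(revcomp(template$sequence), k)))
  for (try in 1:20) {
    s <- random_dna(length)
    if (microhomology > 0 && !is.null(trunc_start)) {
      mh <- substr(template$sequence, trunc_start, trunc_start + microhomology - 1L)
      nxt <- substr(template$sequence, trunc_start + microhomology,
                    trunc_start + microhomology)
      s <- paste0(mh, substr(s, microhomology + 1L, length))
      # force divergence right after the shared stretch
      if (substr(s, microhomology + 1L, microhomology + 1L) == nxt) {
        alt <- setdiff(c("A", "C", "G", "T"), nxt)[1]
        substr(s, microhomology + 1L, microhomology + 1L) <- alt
      }
    }
    if (!any(all_kmers(s, k) %in% tkmers)) return(s)
  }
  stop("failed to generate an MGE sequence absent from the template")
}

all_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

#' Build a resistant locus with known truth
#'
#' Constructs the resistant haplotype `upstream flank + [MGE? + unit] x n +
#' MGE? + downstream flank` from a single-copy template and a repeat-array
#' specification, recording every segment in a truth channel for downstream
#' tests. Inverted units are reverse-complemented copies of their template
#' span. The MGE sequence is generated to share no k-mer with the template
#' (or validated for that property when supplied), so unanchored gaps in an
#' alignment of the resistant locus to the template are exactly the MGE
#' insertions.
#'
#' @param template A `LocusTemplate`.
#' @param spec A `RepeatArraySpec`.
#' @param seed Integer seed for MGE sequence generation.
#' @param k k-mer size used to enforce MGE foreignness.
#' @return A `SimulatedGenomeTruth`: list with `resistant_sequence`,
#'   `segments` (every flank/MGE/unit with resistant and template
#'   coordinates), `unit_intervals`, `mge_intervals`, `cnv_interval`
#'   (template coordinates), `per_unit_copy_truth`, `mge_sequence`,
#'   `shared_end`, `template`, `spec`.
#' @export
build_resistant_locus <- function(template, spec, seed = 1L, k = 21L) {
  stopifnot(inherits(template, "LocusTemplate"), inherits(spec, "RepeatArraySpec"))
  sizes <- spec$sizes
  shared_end <- shared_downstream_end(template)
  tmpl_tab <- unit_template_table(template, sizes)
  rownames(tmpl_tab) <- tmpl_tab$unit_type
  starts <- tmpl_tab[spec$units, "ref_start"]
  if (any(starts < 2L))
    stop("unit extends past template bounds (upstream start < 2)")
  if (shared_end >= nchar(template$sequence))
    stop("no downstream flank left after the shared endpoint")

  mge <- spec$mge_sequence
  trunc_start <- tmpl_tab["truncated", "ref_start"]
  if (is.null(mge)) {
    mge <- with_seed(seed, generate_mge_sequence(template, sizes$mge,
                                                 spec$microhomology,
                                                 trunc_start, k))
  } else {
    assert_dna(mge, "mge_sequence")
    shared <- intersect(all_kmers(mge, k),
                        c(all_kmers(template$sequence, k),
                          all_kmers(revcomp(template$sequence), k)))
    if (length(shared) > 0)
      stop("mge_sequence shares a ", k, "-mer with the template")
  }
  mge_len <- nchar(mge)

  n <- length(spec$units)
  first_start <- starts[1]
  segs <- list()
  pieces <- character(0)
  pos <- 1L
  add_seg <- function(kind, seqpiece, t_start = NA_integer_, t_end = NA_integer_,
                      orientation = "forward", unit_type = NA_character_) {
    w <- nchar(seqpiece)
    segs[[length(segs) + 1L]] <<- data.frame(
      kind = kind, start = pos, end = pos + w - 1L,
      template_start = t_start, template_end = t_end,
      orientation = orientation, unit_type = unit_type,
      stringsAsFactors = FALSE)
    pieces[length(pieces) + 1L] <<- seqpiece
    pos <<- pos + w
  }

  add_seg("flank", substr(template$sequence, 1L, first_start - 1L),
          1L, first_start - 1L)
  for (i in seq_len(n)) {
    if (spec$mge_before[i]) add_seg("mge", mge)
    ut <- spec$units[i]
    ori <- tmpl_tab[ut, "orientation"]
    useq <- substr(template$sequence, starts[i], shared_end)
    if (ori == "inverted") useq <- revcomp(useq)
    add_seg("unit", useq, starts[i], shared_end, ori, ut)
  }
  if (spec$flanking_mge) add_seg("mge", mge)
  add_seg("flank", substr(template$sequence, shared_end + 1L,
                          nchar(template$sequence)),
          shared_end + 1L, nchar(template$sequence))

  segments <- do.call(rbind, segs)
  resistant <- paste(pieces, collapse = "")
  units <- segments[segments$kind == "unit", , drop = FALSE]
  mges <- segments[segments$kind == "mge", , drop = FALSE]
  structure(list(
    resistant_sequence = resistant,
    segments = segments,
    unit_intervals = units[, c("start", "end", "unit_type", "orientation",
                               "template_start", "template_end")],
    mge_intervals = mges[, c("start", "end")],
    cnv_interval = c(min(starts), shared_end),
    per_unit_copy_truth = table(spec$units),
    mge_sequence = mge,
    shared_end = shared_end,
    template = template,
    spec = spec), class = "SimulatedGenomeTruth")
}

#' @export
print.SimulatedGenomeTruth <- function(x, ...) {
  cat(sprintf(paste0("<SimulatedGenomeTruth> %s bp resistant haplotype, ",
                     "%d repeat units, %d MGE copies\n"),
              format(nchar(x$resistant_sequence), big.mark = ","),
              nrow(x$unit_intervals), nrow(x$mge_intervals)))
  print(x$per_unit_copy_truth)
  invisible(x)
}
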