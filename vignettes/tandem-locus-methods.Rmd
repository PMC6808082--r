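---
title: "Methods: simulating and dissecting a tandemly duplicated EPSPS locus"
author: "tandemloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and dissecting a tandemly duplicated EPSPS locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemloc)
```

## The biological system and what the package computes

Glyphosate kills plants by inhibiting EPSPS
(5-enolpyruvylshikimate-3-phosphate synthase). In kochia (*Bassia
scoparia*), resistant populations carry extra copies of the *EPSPS* gene
arranged head-to-tail at a single locus, separated by a ~16 kb mobile
genetic element (MGE). The locus has a characteristic grammar: several
repeat-unit types of different upstream extents — a full 56.1 kb unit, a
truncated 32.7 kb unit, an 18.2 kb and a 33.1 kb variant, plus full-length
inversions — that all share one downstream endpoint directly after *EPSPS*,
each unit preceded by an MGE copy.

`tandemloc` implements the complete computational workflow for
characterizing such a locus, and a synthetic-data generator that produces
loci of known structure so that every inference step can be validated
against truth:

1. **Synthetic locus generation** — a single-copy template contig with the
   annotated 13-gene layout, resistant haplotypes assembled from
   configurable repeat arrays, uniform short reads, BAC-scale long
   fragments, and qPCR Ct tables.
2. **CNV inference from read depth** — boundary detection from a coverage
   profile and masked, flank-normalized per-unit copy-number estimation.
3. **qPCR quantification** — the comparative-Ct method with two single-copy
   reference genes, junction-marker presence logic, primer-design
   constraint validation, and background subtraction for elements that also
   occur outside the array.
4. **Repeat-structure reconstruction** — anchoring long fragments to the
   single-copy reference with unique k-mer seeds, segmenting anchored
   blocks into typed, oriented unit calls, detecting novel insertions,
   merging fragments by overlap, and measuring junction microhomology.
5. **Array evolution** — a Wright–Fisher-style simulator of the
   unequal-crossing-over model with microhomology-mediated truncation and
   copy-number selection.

## Coordinates and the gene-length convention

All internal coordinates are 1-based inclusive, the R/Bioconductor
convention (IRanges), converted only at the BED boundary (BED stays 0-based
half-open; the conversion is exact and round-trips). One quirk is honored
deliberately at the gene-table boundary: the source annotation reports gene
*Length* as `Ending − Beginning` without the +1 (e.g. the *EPSPS* gene
model at 91,663–97,214 is listed as 5,551 bp). `read_gene_table()` checks
declared lengths against that convention and warns on violations rather
than "fixing" them.

## The synthetic locus generator

`build_susceptible_locus()` draws a uniform random DNA contig (399,779 bp
at full scale) and places the gene layout on it. Random sequence at these
scales is effectively repeat-free, which makes unique k-mer anchoring
well-posed — deliberately idealized: real flanks contain transposons and
low-complexity sequence, which is why real pipelines mask repeats (see
below).

`build_resistant_locus()` assembles
`upstream flank + [MGE + unit] × n + MGE + downstream flank`. Unit types
take their upstream extents from `repeat_unit_sizes()` (56,100 / 32,700 /
56,100 inverted / 18,200 inverted / 33,100 bp; MGE 16,037 bp), all ending
at the shared downstream endpoint, the base at the end of the *EPSPS* gene
model. Inverted units are reverse-complemented template copies. Two
generator properties matter for validation:

* the MGE sequence is generated to share no 21-mer with the template (and a
  supplied MGE sequence is checked for that property), so unanchored
  alignment gaps are exactly the MGE insertions; and
* the first 7 bp of the MGE are copied from the template at the start of
  the truncated repeat (with the 8th base forced to differ), embedding the
  junction microhomology that the truncation mechanism implies, so
  `junction_microhomology()` measures 7 bp on simulated data just as it
  would on real junction sequences.

The MGE placement follows the observed architecture: one copy before each
unit and one closing the array downstream, so an array of *n* units carries
*n* + 1 MGEs. Whether internal junctions carry one or two MGE copies is not
observable from the data the model is built on; the generator defaults to a
single internal spacer (`mge_before`), with the flag per unit.

A `"mini"` profile scales every length by 1/20 (template 19,989 bp, full
unit 2,805 bp, MGE 802 bp). All inference is scale-free, so the mini
profile exercises identical code paths at a fraction of the cost; the
replicated recovery experiments below use it.

Reads are placements only: `simulate_short_reads()` places
`round(coverage × L / read_length)` fixed-length reads uniformly; no
sequencing-error, quality, GC-bias or duplicate model is included (an
optional uniform substitution rate exists in `read_sequences()` for
materialized sequences). Consequently, passing recovery tests demonstrate
the statistical behavior of the estimators under sampling noise, not
robustness to platform artifacts.

`project_reads_to_template()` stands in for re-aligning resistant-plant
reads to the single-copy reference: each read maps through the truth
segment containing its midpoint; MGE reads (absent from the reference) are
dropped. This is an idealized aligner — no mismapping, no multi-mapping —
which again biases the tests toward measuring estimator behavior rather
than aligner behavior.

`simulate_qpcr()` writes `Ct = c0 − log_E(copies) + N(0, σ)` with the two
reference genes ALS and CPS at one copy, `E ∈ (1, 2]` the per-cycle
amplification factor (default 2, perfect doubling), and records 0-copy
markers as `NA` ("no amplification"), which is semantically distinct from a
low copy number throughout the package.

## CNV inference

**Boundary detection.** The published boundaries were called manually where
coverage increased sharply. `detect_cnv_boundaries()` operationalizes that:
window medians (default 500 bp), a flank baseline estimated as the median
of window medians outside candidate windows and iterated to a fixed point,
candidate runs at `fold_threshold` (default 2) over baseline, spans below
`min_span` discarded, and each boundary refined to the largest single-base
depth step within one window of the run edge. On a noise-free step profile
the refinement is exact; with real read sampling the depth ramps over one
read length at the boundary, so refined positions scatter within the ramp —
the recovery criterion is therefore "within one window". Both the median
and the maximum elevation over baseline are reported (`fold_median`,
`fold_max`), since "fold change" of a staircase-shaped region is ambiguous.
`min_span` defaults to 5 kb at full scale; mini-profile analyses use 1 kb,
scaled like everything else.

**Copy number.** `estimate_unit_copy_number()` counts reads per unit
(a read counts for every unit covering ≥ 50% of it), divides by unmasked
unit length, and normalizes by the mean rate of the two single-copy flanks.
Masking uses a midpoint rule: a read whose midpoint falls in a mask
interval is not counted, so piling reads into masked intervals leaves rates
invariant (tested). The flanks come out at ≈ 1 by construction and exactly
1 when their two rates are equal. On a mixed array the full-repeat unit
measures the *average* copy number across its span (a staircase over the
unit-type extents), while the shared repeat core — the truncated-unit span,
contained in every type — measures the total array copy number;
`deconvolve_repeat_copies()` solves the resulting 2×2 system into
full-length vs shorter-type counts.

**Gene classification.** `genes_in_interval()` uses strict containment
(straddling genes are outside). `classify_expression_response()` labels a
*supplied* differential-expression table (no re-fitting, no re-adjustment):
over/under iff the FDR-adjusted p is strictly below α (default 0.05) with a
strict sign rule on log2 fold change; missing p-values become
`not_evaluable` and are excluded from counts.

## qPCR quantification

Copy number is `2^ΔCt` with `ΔCt = (Ct(ALS) + Ct(CPS))/2 − Ct(marker)`.
Replicates are never averaged at the Ct level: per-replicate calls are
produced and `summarize_copy_calls()` gives mean ± sd afterwards.

Primer validation checks length, GC, melting temperature and amplicon
range, reporting *all* violations. Tm uses the Wallace rule
`2(A+T) + 4(G+C)`, chosen for determinism; it is a crude rule, and under it
the published joint constraints (Tm 51–56 °C, GC 40–50%, length 20–24 bp)
admit only boundary solutions such as a 20-mer with 8 G/C (Tm = 56). A
nearest-neighbor Tm would widen the feasible set; the rule is pluggable in
the sense that `wallace_tm()` is exported and small.

`marker_amplifies()` is exact in-silico PCR (forward site plus downstream
reverse-complement site within the expected amplicon range, both strands),
which is how junction markers discriminate resistant from susceptible
templates. `infer_repeat_associated_copies()` subtracts the background
copies of the MGE (it exists elsewhere in the genome) from the total; for
ranges, naive interval arithmetic (`[lo_t − hi_b, hi_t − lo_b]`) and
same-rank pairing (`[lo_t − lo_b, hi_t − hi_b]`) give different intervals
(for totals 14–18 and background 4–5: 9–14 vs 10–13), and both are
reported rather than picking one.

## Repeat-structure reconstruction

**Anchoring.** `anchor_fragment()` seeds with k-mers (default k = 21) that
are unique across both reference strands and chains seeds on the same
(anti)diagonal, bridging holes up to `max_gap`. With `max_gap = 0` the
blocks are exactly the unique maximal exact matches, which is what the
brute-force oracle in the test suite enumerates (by diagonal run-length
scanning at small scale, and by construction-truth at 20 kb scale). Exact,
gap-free matching is appropriate because the default simulations are
error-free; noisy long reads would need a gapped aligner, which is out of
scope.

**Segmentation.** All unit templates share the downstream endpoint, so a
fragment's pass through the repeat region that returns upstream marks a
unit boundary. Blocks are clipped to the repeat region, merged across
small same-diagonal holes, and each pass is typed by the nearest template
with matching orientation within ±2% of template length; calls fitting no
template are labeled `partial` (typically units cut by fragment ends),
never force-typed. Two numerical details:

* *Junction slivers.* A single base at an insertion junction can
  coincidentally match the reference and extend an anchor block by 1–2 bp
  into the MGE; clipped groups shorter than `min_call` (50 bp) are
  discarded as such slivers rather than reported as units.
* *Microhomology absorption.* Because the MGE starts with the same 7 bp as
  the truncated repeat, the anchor preceding an MGE can legitimately extend
  up to 7 bp into it, so measured insertion gaps can be short by up to the
  microhomology length. This is the same repeat-vs-MGE size-attribution
  ambiguity seen in real junction data; the exact MGE length is recovered
  by `detect_novel_insertion()` on the insertion sequence itself, which
  also classifies it novel when anchored coverage is below 20%.

**Merging.** `merge_fragments()` is greedy overlap-layout: repeatedly merge
the pair with the longest suffix–prefix overlap (either orientation,
containment absorbed) meeting `min_overlap` (default 1 kb) and
`min_identity` (default 0.99, Hamming identity over the overlap — no indel
alignment, consistent with error-free simulations), with a lexicographic
tie-break for determinism. An important limitation is intrinsic to the
locus, not the implementation: every repeat type is a suffix (or reverse
complement) of the full unit, so two fragments can share a repeat-induced
false overlap as long as `MGE + full unit + MGE` (≈ 88 kb at full scale) at
identity 1. Blind overlap merging is therefore only determined when true
overlaps exceed the longest repeated stretch — which holds for the
mini-profile experiments in this package (8 kb true vs 4.4 kb repeated) and
cannot hold for BAC-scale fragments of the full-size locus; reconstructing
the real locus correspondingly required fragment end positions and manual
curation. The validated invariants are: members match the assembly at
their offsets, total length never exceeds the summed member lengths, and
re-merging the output changes nothing.

## Array evolution

The model: tandem arrays misalign at homologous MGE boundaries, shifted by
`offset` units (geometric, p = 0.7, so mostly single-unit slips), and an
unequal crossover produces one gamete with `n_a + offset` and one with
`n_b − offset` units — total count conserved exactly, including the
initiating event (1 + 1 → 2 + 0, one duplicated gamete and one null).
Microhomology-mediated truncation converts a full unit into the truncated
type without changing the count. `simulate_generations()` runs a constant-
size population from single-unit MGE-flanked homologs with fitness-weighted
parent sampling, per-meiosis event rates, and inviability of zygotes null
on both homologs.

Rates are free parameters (the mechanism, not the rates, is what the data
support); defaults are deliberately modest: crossover 0.01/meiosis,
truncation 0.001/meiosis. Selection is user-supplied; `step_selection()`
models herbicide pressure as a fitness step in total copy number.

One subtlety is worth stating precisely: with flat fitness, *gamete
formation* is conservative in expectation (each crossover's two products
are kept with equal probability), but the *population* mean still creeps
upward because removing inviable null/null zygotes truncates the low-copy
tail — about +0.2 copies over 10 generations at population 20 and crossover
rate 0.05. The test suite asserts conservation where it holds exactly (one
generation from a homogeneous population, and exact per-event
conservation) and bounds the pruning drift separately. Under copy-number
selection the mean rises sustainedly; the packaged experiment (population
30, 50 generations, crossover 0.05, step selection at 3 copies) rises in
≥ 95% of seeded runs.

## Problem sizes used in the packaged experiments

The replicated experiments run on the mini profile: copy-number and
boundary recovery use a 6-unit array at 50× coverage over 20 seeds (the
estimator's sampling error there is ≈ 2%, against a ±10% acceptance band);
structure recovery covers all five unit types; crossover conservation is
checked over 10,000 random events; the full-scale locus (399,779 bp
template, ~708 kb resistant haplotype) is built once to measure the MGE
length (16,037 bp), the 7 bp junction microhomology, and the six *EPSPS*
repeats. These sizes are the package's validation design; all are
parameters the user can raise.

## Known limitations

* No sequencing-error calibration, quality simulation, or PCR-duplicate
  model; no GC-bias correction in depth analysis.
* No gapped alignment: anchoring and overlap identity are exact/Hamming,
  suited to the simulator's error-free output.
* The read-projection stand-in for alignment cannot mismap; real
  repeat-masked alignment noise is not emulated.
* Copy estimates carry no confidence intervals beyond the binomial
  reasoning used in tests.
* Blind overlap merging cannot resolve repeat-induced ambiguity at
  full scale (discussed above).
* The evolution module is unit-level only: no sequence evolution, no
  linkage, no recombination map; inversions are represented as unit
  orientations but no inversion-generating event is enabled by default.
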