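# tandemloc

Simulation and inference for tandemly duplicated herbicide-resistance
loci.

Glyphosate-resistant kochia carries extra copies of the *EPSPS* gene
(5-enolpyruvylshikimate-3-phosphate synthase, the herbicide's target)
arranged head-to-tail at one locus, each repeat unit paired with a ~16 kb
mobile genetic element (MGE). The repeat units come in several types —
full 56.1 kb, truncated 32.7 kb, inversions, smaller variants — that all
share one downstream endpoint directly after *EPSPS*. `tandemloc` is for
researchers dissecting such loci: it implements the complete analysis
workflow and a synthetic-data generator with a truth channel so every
inference step is testable without access to the original sequencing data.

The core quantities and models:

* **Read-depth copy number.** For a counting unit *u* with unmasked length
  *L(u)* and *r(u)* assigned reads, the flank-normalized copy number is

  `copies(u) = [r(u)/L(u)] / mean( r(f)/L(f) : f in {upstream, downstream flank} )`

  with reads assigned to units covering ≥ 50% of them and a midpoint rule
  for repeat masks. CNV boundaries are called from windowed depth medians
  against an iteratively re-estimated flank baseline, then refined to the
  maximal depth step.

* **Comparative-Ct qPCR.** `copies = 2^ΔCt`,
  `ΔCt = (Ct(ALS) + Ct(CPS))/2 − Ct(marker)`, with the two single-copy
  reference genes ALS and CPS, per-replicate calls, "no amplification"
  kept distinct from zero copies, and background subtraction for markers
  (like the MGE) that also occur outside the array.

* **Repeat-structure reconstruction.** Long fragments are anchored to the
  single-copy reference by unique k-mer seed chains (both strands),
  segmented into typed, oriented repeat-unit calls using the shared
  downstream endpoint, with unanchored gaps reported as insertions and
  classified novel/known; fragments merge greedily by longest
  suffix–prefix overlap; junction microhomology is the longest common
  prefix of the two sequences meeting at a breakpoint.

* **Array evolution.** Unequal crossing over between MGE-misaligned
  homologs (products of `n_a + offset` and `n_b − offset` units; total
  conserved exactly), microhomology-mediated truncation of full units, and
  Wright–Fisher population dynamics with copy-number selection and
  lethality of the null/null genotype.

## Worked example

Build a scaled ("mini", 1/20) susceptible template and a six-repeat
resistant haplotype, then run the depth and structure analyses:

```r
library(tandemloc)

template <- build_susceptible_locus(locus_layout("mini"), seed = 1)
truth <- build_resistant_locus(template,
          default_six_repeat_spec(sizes = repeat_unit_sizes("mini")), seed = 2)
truth
#> <SimulatedGenomeTruth> 35,413 bp resistant haplotype, 6 repeat units, 7 MGE copies

reads <- simulate_short_reads(truth$resistant_sequence, coverage = 50,
                              read_length = 100, seed = 3)
on_template <- project_reads_to_template(reads, truth)
depth <- depth_from_placements(on_template, nchar(template$sequence))
detect_cnv_boundaries(depth, window = 500, fold_threshold = 2, min_span = 1000)
#>   start  end fold_median fold_max baseline
#> 1  2063 4606        4.76     6.76       50
```

The call spans the true CNV interval (2,057–4,861 on the template; both
boundaries land within one window of truth) and reports the elevation over
the flank baseline both as a median (4.8×: the region is a staircase of
unit types) and a maximum (6.8×, near the 6 stacked *EPSPS* copies).

```r
estimate_unit_copy_number(on_template, template_unit_set(template))
#>                 unit start   end unmasked_length reads_mapped reads_per_unmasked_kb normalized_copies
#> 1     upstream_flank     1  2056            2056          995                   484             0.982
#> 2        full_repeat  2057  4861            2805         6287                  2241             4.549
#> 3 shared_repeat_core  3227  4861            1635         4595                  2810             5.704
#> 4   downstream_flank  4862 19989           15128         7586                   501             1.018
```

The flanks normalize to ≈ 1; the shared repeat core (contained in every
repeat type) measures the total array copy number (5.7, truth staircase
mean ≈ 5.6), while the full-repeat span averages over the unit-type
staircase (4.5). Structure calls recover the array grammar exactly:

```r
blocks <- anchor_fragment(truth$resistant_sequence, template$sequence, k = 21)
segment_units(blocks, unit_template_table(template),
              shared_downstream_end(template),
              fragment_length = nchar(truth$resistant_sequence))$units
#>   frag_start frag_end        unit_type orientation ref_start ref_end
#> 1       2859     5663             full     forward      2057    4861
#> 2       6466     8100        truncated     forward      3227    4861
#> 3       8903    11707             full     forward      2057    4861
#> 4      12510    15314    inverted_full    inverted      2057    4861
#> 5      16117    17026 inverted_minimal    inverted      3952    4861
#> 6      17829    19483  forward_variant     forward      3207    4861
```

And the qPCR arm round-trips simulated copy numbers:

```r
ct <- simulate_qpcr(c(epsps = 6, junction_56 = 5), noise_sd = 0.15,
                    seed = 4, replicates = 3)
summarize_copy_calls(quantify_ct_table(ct))
#>    sample      marker n mean_copies sd_copies n_no_amplification
#> 1 sample1       epsps 3        6.65     1.191                  0
#> 2 sample1 junction_56 3        5.48     0.754                  0
```

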