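test_that("exact substrings anchor as single blocks of the right strand", {
  set.seed(31)
  ref <- random_dna(5000)
  frag <- substr(ref, 1001, 3000)
  bl <- anchor_fragment(frag, ref, k = 21)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$frag_start, 1L)
  expect_equal(bl$frag_end, 2000L)
  expect_equal(c(bl$ref_start, bl$ref_end), c(1001L, 3000L))
  expect_equal(bl$orientation, "forward")

  blr <- anchor_fragment(revcomp(frag), ref, k = 21)
  expect_equal(nrow(blr), 1L)
  expect_equal(c(blr$ref_start, blr$ref_end), c(1001L, 3000L))
  expect_equal(blr$orientation, "inverted")

  expect_equal(nrow(anchor_fragment("ACGTACGT", ref, k = 21)), 0L)
})

test_that("anchoring matches the brute-force maximal-match oracle", {
  set.seed(32)
  k <- 11
  ref <- unique_kmer_reference(400, k)
  for (case in 1:50) {
    n_seg <- sample(1:3, 1)
    segs <- lapply(seq_len(n_seg), function(i) {
      len <- sample(20:80, 1)
      s <- sample.int(400 - len, 1)
      list(start = s, end = s + len - 1L,
           orientation = sample(c("forward", "inverted"), 1))
    })
    comp <- compose_fragment(ref, segs, spacer_lengths = sample(10:40, n_seg))
    got <- anchor_fragment(comp$sequence, ref, k = k, max_gap = 0)
    want <- oracle_blocks(comp$sequence, ref, k)
    got <- got[order(got$frag_start, got$ref_start, got$orientation),
               c("frag_start", "frag_end", "ref_start", "ref_end",
                 "orientation")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[, colnames(got)])
  }
})

test_that("fragments spanning units and MGEs anchor with unanchored gaps", {
  tr <- mini_truth6()
  tm <- mini_template()
  # slice covering [MGE, unit1, MGE, unit2]
  u2 <- tr$unit_intervals[2, ]
  m1 <- tr$mge_intervals[1, ]
  frag <- substr(tr$resistant_sequence, m1$start, u2$end)
  bl <- anchor_fragment(frag, tm$sequence, k = 21)
  expect_gte(nrow(bl), 2L)
  gaps <- bl$frag_start[-1] - bl$frag_end[-nrow(bl)] - 1L
  expect_true(any(abs(gaps - mini_sizes()$mge) <= 2))
})

test_that("segmentation recovers every repeat grammar exactly", {
  tm <- mini_template()
  sz <- mini_sizes()
  templates <- unit_template_table(tm, sz)
  shared <- shared_downstream_end(tm)
  grammars <- list(
    c("full"),
    c("full", "full"),
    c("full", "truncated"),
    c("inverted_full"),
    c("full", "truncated", "full", "inverted_full", "inverted_minimal",
      "forward_variant"),
    c("truncated", "inverted_minimal", "full"))
  for (g in seq_along(grammars)) {
    spec <- repeat_array_spec(grammars[[g]], sizes = sz)
    tr <- build_resistant_locus(tm, spec, seed = 200 + g)
    bl <- anchor_fragment(tr$resistant_sequence, tm$sequence, k = 21)
    seg <- segment_units(bl, templates, shared,
                         fragment_length = nchar(tr$resistant_sequence))
    expect_equal(seg$units$unit_type, grammars[[g]],
                 info = paste("grammar", g))
    expect_equal(seg$units$orientation,
                 unname(sz$orientations[grammars[[g]]]),
                 info = paste("grammar", g))
    # one MGE-sized novel insertion per unit plus the outer boundary; the
    # measured gap can be short by up to the embedded junction
    # microhomology (plus coincidental single-base junction matches),
    # which the flanking anchor absorbs
    expect_equal(nrow(seg$insertions), length(grammars[[g]]) + 1L)
    expect_true(all(seg$insertions$length <= sz$mge + 2))
    expect_true(all(seg$insertions$length >= sz$mge - spec$microhomology - 2))
  }
})

test_that("fragments outside the repeat region give no unit calls", {
  tm <- mini_template()
  frag <- substr(tm$sequence, 10000, 15000)
  bl <- anchor_fragment(frag, tm$sequence, k = 21)
  seg <- segment_units(bl, unit_template_table(tm, mini_sizes()),
                       shared_downstream_end(tm),
                       fragment_length = nchar(frag))
  expect_equal(nrow(seg$units), 0L)
})

test_that("overlapping blocks are rejected as an anchoring bug", {
  fake <- data.frame(frag_start = c(1L, 50L), frag_end = c(100L, 150L),
                     ref_start = c(1L, 50L), ref_end = c(100L, 150L),
                     orientation = "forward", identity = 1, n_seeds = 1L)
  expect_error(segment_units(fake, unit_template_table(mini_template()),
                             shared_downstream_end(mini_template())),
               "overlap")
})

test_that("novel insertions are separated from transposed reference copies", {
  tr <- mini_truth6()
  tm <- mini_template()
  mge <- tr$mge_sequence
  res <- detect_novel_insertion(mge, tm$sequence)
  expect_equal(res$status, "novel")
  expect_equal(res$length, mini_sizes()$mge)
  expect_lt(res$anchored_fraction, 0.2)

  transposed <- substr(tm$sequence, 5001, 6000)
  res2 <- detect_novel_insertion(transposed, tm$sequence)
  expect_equal(res2$status, "known")
  expect_gt(res2$anchored_fraction, 0.9)

  expect_null(detect_novel_insertion("", tm$sequence))
})

test_that("junction microhomology is a symmetric capped common prefix", {
  expect_equal(junction_microhomology("GATTACAGAA", "GATTACATAA"), 7L)
  expect_equal(junction_microhomology("ATTT", "CTTT"), 0L)
  expect_equal(junction_microhomology("ACGTACGTAC", "ACGTACGTAC", max_k = 10), 10L)
  a <- "ACGGGTTTAC"
  b <- "ACGGGAAATT"
  expect_equal(junction_microhomology(a, b), junction_microhomology(b, a))
  expect_error(junction_microhomology("", "A"))
})

test_that("the generator embeds the truncation-point microhomology", {
  tr <- mini_truth6()
  tm <- mini_template()
  trunc_start <- unit_template_table(tm, mini_sizes())
  trunc_start <- trunc_start$ref_start[trunc_start$unit_type == "truncated"]
  repeat_start_seq <- substr(tm$sequence, trunc_start, trunc_start + 49)
  mh <- junction_microhomology(tr$mge_sequence, repeat_start_seq)
  expect_equal(mh, 7L)
})

test_that("gene occurrence counting is strand-aware and deduplicated", {
  set.seed(33)
  gene <- random_dna(200)
  backbone <- random_dna(3000)
  asm <- paste0(backbone, gene, random_dna(500), revcomp(gene),
                random_dna(500), gene)
  expect_equal(count_gene_occurrences(asm, gene), 3L)
  expect_equal(count_gene_occurrences(backbone, gene), 0L)
  expect_error(count_gene_occurrences(asm, "ACGT"), "100")
  # palindromic probe: one site, counted once
  half <- random_dna(100)
  pal <- paste0(half, revcomp(half))
  asm2 <- paste0(random_dna(1000), pal, random_dna(1000))
  expect_equal(count_gene_occurrences(asm2, pal), 1L)
})
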