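test_that("default layout reproduces the annotated contig geometry", {
  lay <- locus_layout("kochia")
  expect_equal(lay$contig_length, 399779L)
  expect_equal(nrow(lay$genes), 13L)
  eps <- lay$genes[lay$genes$gene_id == "KS_00460", ]
  expect_equal(c(eps$start, eps$end), c(91663L, 97214L))
  expect_equal(eps$length, 5551L)
})

test_that("susceptible locus generation is deterministic and validated", {
  lay <- locus_layout("mini")
  t1 <- build_susceptible_locus(lay, seed = 7)
  t2 <- build_susceptible_locus(lay, seed = 7)
  expect_identical(t1$sequence, t2$sequence)
  expect_equal(nchar(t1$sequence), lay$contig_length)

  empty <- locus_layout("mini", genes = kochia_gene_table()[0, ])
  t0 <- build_susceptible_locus(empty, seed = 1)
  expect_equal(nrow(t0$genes), 0L)
  expect_equal(nchar(t0$sequence), empty$contig_length)

  bad <- locus_layout("mini")
  bad$allow_overlap <- list()
  expect_error(build_susceptible_locus(bad, seed = 1), "overlap")
})

test_that("resistant locus construction conserves length and copies", {
  tm <- mini_template()
  sz <- mini_sizes()
  spec2 <- repeat_array_spec(c("full", "full"), sizes = sz)
  tr2 <- build_resistant_locus(tm, spec2, seed = 9)
  shared_end <- shared_downstream_end(tm)
  full_len <- sz$units[["full"]]
  expected <- nchar(tm$sequence) + full_len + 3L * sz$mge
  expect_equal(nchar(tr2$resistant_sequence), expected)
  expect_equal(sum(tr2$segments$end - tr2$segments$start + 1),
               nchar(tr2$resistant_sequence))
  expect_equal(unname(tr2$per_unit_copy_truth["full"]), 2L)
  expect_equal(count_gene_occurrences(tr2$resistant_sequence,
                                      gene_sequence(tm)), 2L)

  # one unit, no MGE anywhere: the construction is the identity
  spec1 <- repeat_array_spec("full", mge_before = FALSE, flanking_mge = FALSE,
                             sizes = sz)
  tr1 <- build_resistant_locus(tm, spec1, seed = 9)
  expect_identical(tr1$resistant_sequence, tm$sequence)
})

test_that("six-repeat array carries six EPSPS copies", {
  tr <- mini_truth6()
  expect_equal(count_gene_occurrences(tr$resistant_sequence,
                                      gene_sequence(mini_template())), 6L)
  expect_equal(nrow(tr$unit_intervals), 6L)
  # one MGE per repeat plus the outer boundary
  expect_equal(nrow(tr$mge_intervals), 7L)
  # CNV interval contains the EPSPS gene
  eps <- tr$template$genes[tr$template$genes$gene_id == "KS_00460", ]
  expect_lte(tr$cnv_interval[1], eps$start)
  expect_gte(tr$cnv_interval[2], eps$end)
})

test_that("a supplied MGE present in the template is rejected", {
  tm <- mini_template()
  sz <- mini_sizes()
  inside <- substr(tm$sequence, 501, 500 + sz$mge)
  spec <- repeat_array_spec("full", sizes = sz, mge_sequence = inside)
  expect_error(build_resistant_locus(tm, spec), "mer")
})

test_that("short-read simulator hits its read count and coverage", {
  seqc <- random_dna(100000)
  rs <- simulate_short_reads(seqc, coverage = 50, read_length = 100, seed = 3)
  expect_equal(nrow(rs$reads), 50000L)
  expect_identical(rs$reads,
                   simulate_short_reads(seqc, 50, 100, seed = 3)$reads)
  expect_error(simulate_short_reads(seqc, 0, 100), "coverage")

  dp <- depth_from_placements(rs, 100000)
  win <- mean(dp$depth[45001:55000])
  expect_lt(abs(win - 50), 3 * sqrt(50 / 10000) * 50)  # generous CLT bound
})

test_that("long-fragment simulator respects sizes and carries truth", {
  seqc <- random_dna(40000)
  fr <- simulate_long_fragments(seqc, c(7800, 14100), n = 4, seed = 5)
  expect_equal(nrow(fr), 4L)
  expect_true(all(fr$size >= 7800 & fr$size <= 14100))
  for (i in 1:4)
    expect_identical(fr$sequence[i], substr(seqc, fr$start[i], fr$end[i]))
  expect_equal(nrow(simulate_long_fragments(seqc, c(100, 200), 0)), 0L)
  expect_error(simulate_long_fragments(seqc, c(200, 100), 1), "size_range")
})

test_that("qPCR simulator encodes log2 copy number in Ct", {
  ct1 <- simulate_qpcr(c(M = 1), efficiency = 2, noise_sd = 0, seed = 1)
  expect_equal(ct1$ct[ct1$marker == "M"], ct1$ct[ct1$marker == "ALS"])
  ct4 <- simulate_qpcr(c(M = 4), efficiency = 2, noise_sd = 0, c0 = 25)
  expect_equal(ct4$ct[ct4$marker == "M"], 23)
  ct0 <- simulate_qpcr(c(M = 0), noise_sd = 0)
  expect_true(is.na(ct0$ct[ct0$marker == "M"]))
  expect_error(simulate_qpcr(c(M = -1)), ">= 0")
  expect_error(simulate_qpcr(c(M = 1), efficiency = 2.5), "efficiency")
})

test_that("projected reads reproduce template-scale depth", {
  tr <- mini_truth_full(6)
  rs <- simulate_short_reads(tr$resistant_sequence, 30, 100, seed = 11)
  pr <- project_reads_to_template(rs, tr)
  L <- nchar(tr$template$sequence)
  expect_true(all(pr$reads$start >= 1))
  expect_true(all(pr$reads$start + pr$reads$length - 1 <= L))
  dp <- depth_from_placements(pr, L)
  # flank stays at nominal coverage, repeat region is ~6x elevated
  flank <- mean(dp$depth[10000:15000])
  core <- mean(dp$depth[tr$cnv_interval[1]:tr$cnv_interval[2]])
  expect_lt(abs(flank - 30), 5)
  expect_gt(core / flank, 4)
})
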