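test_that("depth from placements counts overlapping reads per base", {
  one <- data.frame(fragment_id = "r1", start = 1L, length = 5L, strand = "+")
  dp <- depth_from_placements(one, 10)
  expect_equal(dp$depth, c(rep(1, 5), rep(0, 5)))

  none <- one[0, ]
  expect_equal(depth_from_placements(none, 10)$depth, rep(0, 10))

  two <- data.frame(fragment_id = c("a", "b"), start = c(3L, 3L),
                    length = c(4L, 4L), strand = "+")
  expect_equal(depth_from_placements(two, 10)$depth,
               c(0, 0, 2, 2, 2, 2, 0, 0, 0, 0))

  oob <- data.frame(fragment_id = "bad", start = 8L, length = 5L, strand = "+")
  expect_error(depth_from_placements(oob, 10), "bad")

  # conservation: sum(depth) equals summed read lengths
  rs <- simulate_short_reads(random_dna(5000), 10, 50, seed = 2)
  expect_equal(sum(depth_from_placements(rs, 5000)$depth),
               sum(rs$reads$length))
})

test_that("boundary detection recovers a sharp constructed step exactly", {
  depth <- rep(10, 150000)
  depth[41684:101128] <- 70
  prof <- structure(list(contig_id = "c", depth = depth, window = 1L),
                    class = "DepthProfile")
  calls <- detect_cnv_boundaries(prof, window = 500, fold_threshold = 2,
                                 min_span = 5000)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 41684)
  expect_equal(calls$end, 101128)
  expect_equal(calls$fold_median, 7)
  expect_equal(calls$fold_max, 7)
})

test_that("flat and empty profiles yield no CNV call", {
  flat <- structure(list(contig_id = "c", depth = rep(30, 50000), window = 1L),
                    class = "DepthProfile")
  expect_equal(nrow(detect_cnv_boundaries(flat, 500, 2, 5000)), 0L)
  zero <- structure(list(contig_id = "c", depth = rep(0, 50000), window = 1L),
                    class = "DepthProfile")
  expect_equal(nrow(detect_cnv_boundaries(zero, 500, 2, 5000)), 0L)
})

test_that("flank-normalized copy number follows the read-rate formula", {
  # flanks at 10 reads/kb, target at 31.2 reads/kb -> 3.12 copies
  mk_reads <- function(n, lo, hi) {
    starts <- as.integer(round(seq(lo, hi - 40, length.out = n)))
    data.frame(fragment_id = sprintf("x%d", seq_len(n) + lo), start = starts,
               length = 20L, strand = "+")
  }
  reads <- rbind(mk_reads(10, 1, 1000), mk_reads(156, 1001, 6000),
                 mk_reads(10, 6001, 7000))
  units <- list(unit_definition("upstream_flank", 1, 1000),
                unit_definition("target", 1001, 6000),
                unit_definition("downstream_flank", 6001, 7000))
  est <- estimate_unit_copy_number(reads, units)
  expect_equal(est$normalized_copies[est$unit == "target"], 3.12)
  expect_equal(est$normalized_copies[est$unit == "upstream_flank"], 1.0)

  no_flank_reads <- mk_reads(5, 1001, 6000)
  expect_error(estimate_unit_copy_number(no_flank_reads, units), "baseline")
})

test_that("masking leaves the unmasked rate invariant", {
  units <- list(unit_definition("upstream_flank", 1, 1000),
                unit_definition("target", 1001, 3000,
                                mask = data.frame(start = 1501, end = 2000)),
                unit_definition("downstream_flank", 3001, 4000))
  base <- data.frame(fragment_id = sprintf("r%d", 1:30),
                     start = c(seq(1, 950, length.out = 10),
                               seq(1001, 1450, length.out = 10),
                               seq(3001, 3950, length.out = 10)),
                     length = 20L, strand = "+")
  base$start <- as.integer(base$start)
  est1 <- estimate_unit_copy_number(base, units)
  # pile extra reads wholly inside the masked interval
  masked_reads <- data.frame(fragment_id = sprintf("m%d", 1:50),
                             start = rep(1700L, 50), length = 20L,
                             strand = "+")
  est2 <- estimate_unit_copy_number(rbind(base, masked_reads), units)
  expect_equal(est1$reads_per_unmasked_kb, est2$reads_per_unmasked_kb)
  expect_equal(est1$unmasked_length[2], 2000 - 500)
})

test_that("copy estimates increase monotonically with simulated copies", {
  ests <- vapply(c(2L, 4L, 6L), function(n) {
    tr <- mini_truth_full(n)
    rs <- simulate_short_reads(tr$resistant_sequence, 30, 100, seed = 21)
    pr <- project_reads_to_template(rs, tr)
    est <- estimate_unit_copy_number(pr, template_unit_set(tr$template))
    est$normalized_copies[est$unit == "full_repeat"]
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
  expect_lt(abs(ests[3] - 6) / 6, 0.1)
})

test_that("gene partition uses strict containment", {
  genes <- kochia_gene_table()
  part <- genes_in_interval(genes, c(41684, 101128))
  expect_equal(nrow(part$inside), 7L)
  expect_equal(part$inside$gene_id, sprintf("KS_%05d", 454:460))
  expect_equal(nrow(part$outside), 6L)

  empty <- genes_in_interval(genes[0, ], c(1, 10))
  expect_equal(nrow(empty$inside), 0L)
  expect_equal(nrow(empty$outside), 0L)

  straddle <- data.frame(gene_id = "g", start = 41000L, end = 42000L)
  expect_equal(nrow(genes_in_interval(straddle, c(41684, 101128))$inside), 0L)
})

test_that("expression-response classification follows the strict sign rule", {
  genes <- kochia_gene_table()
  cnv <- genes_in_interval(genes, c(41684, 101128))$inside
  de <- data.frame(gene = cnv$gene_id, log2_de = cnv$log2_de,
                   fdr_p = cnv$fdr_p)
  res <- classify_expression_response(de, alpha = 0.05)
  expect_equal(unname(res$counts), c(5L, 1L, 1L))
  expect_equal(res$labels$label[res$labels$gene == "KS_00457"], "under")
  expect_equal(res$labels$label[res$labels$gene == "KS_00455"],
               "not_significant")

  expect_equal(unname(classify_expression_response(de[0, ])$counts),
               c(0L, 0L, 0L))
  zero <- data.frame(gene = "g", log2_de = 0, fdr_p = 0.001)
  expect_equal(classify_expression_response(zero)$labels$label,
               "not_significant")
  nap <- data.frame(gene = "g", log2_de = 2, fdr_p = NA)
  res2 <- classify_expression_response(nap)
  expect_equal(res2$labels$label, "not_evaluable")
  expect_equal(sum(res2$counts), 0L)
})
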