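snp_tbl <- function(chrom, pos0, ref, alt) {
  df <- data.frame(chrom = chrom, pos0 = pos0, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  class(df) <- c("snp_table", "data.frame")
  df
}

test_that("alternate genome differs exactly at the SNP positions", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  snps <- snp_tbl("chr1", c(1, 4, 7), c("C", "A", "T"), c("T", "G", "A"))
  alt <- build_alt_genome(genome, snps)
  expect_equal(as.character(alt[[1]]), "ATGTGCGAAC")
  # hamming distance equals the SNP count
  d <- sum(strsplit(as.character(alt[[1]]), "")[[1]] !=
             strsplit(as.character(genome[[1]]), "")[[1]])
  expect_equal(d, 3)
  # empty table is the identity
  expect_identical(as.character(build_alt_genome(genome, snps[0, ])[[1]]),
                   as.character(genome[[1]]))
  # swapped ref/alt is an involution
  swapped <- snp_tbl("chr1", c(1, 4, 7), c("T", "G", "A"), c("C", "A", "T"))
  back <- build_alt_genome(alt, swapped)
  expect_identical(as.character(back[[1]]), as.character(genome[[1]]))
  # ref mismatch errors with the position
  badsnp <- snp_tbl("chr1", 2, "A", "G")
  expect_error(build_alt_genome(genome, badsnp), "3")
})

test_that("read genotyping counts allele matches and ignores third bases", {
  # read covers blocks [10,14) + [20,24): read = pos 10..13, 20..23
  blocks <- cbind(c(10, 20), c(14, 24))
  snps <- snp_tbl("chr1", c(11, 21, 22, 30), c("A", "C", "G", "T"),
                  c("G", "T", "A", "C"))
  read <- "AAGATTTT"  # pos0 11 -> "A" (ref), 21 -> "T" (alt), 22 -> "T" (n.)
  sup <- genotype_read(blocks, read, "+", snps)
  expect_equal(unname(sup["ref"]), 1L)
  expect_equal(unname(sup["alt"]), 1L)
  # read covering no SNP
  sup0 <- genotype_read(cbind(40, 48), "ACGTACGT", "+", snps)
  expect_equal(unname(sup0), c(0L, 0L))
})

test_that("allele assignment matches a brute-force rule transcription", {
  brute <- function(cov, a, b) {
    if (cov < 0.60) return("excluded_low_coverage")
    if (a + b == 1) return(if (a == 1) "A" else "B")
    if (a > 0 && a >= 2 * b) return("A")
    if (b > 0 && b >= 2 * a) return("B")
    "unassigned"
  }
  for (a in 0:10) for (b in 0:10) {
    expect_equal(assign_allele(0.8, a, b), brute(0.8, a, b),
                 label = sprintf("supports (%d,%d)", a, b))
  }
  expect_equal(assign_allele(0.59, 3, 0), "excluded_low_coverage")
  expect_equal(assign_allele(0.60, 3, 0), "A")
  expect_equal(assign_allele(0.8, 1, 0), "A")
  expect_equal(assign_allele(0.8, 2, 1), "A")
  expect_equal(assign_allele(0.8, 3, 2), "unassigned")
})

test_that("dual-mapping averaging is the element-wise mean", {
  mk_calls <- function(nA, nB) {
    data.frame(read_id = sprintf("r%d", seq_len(nA + nB)), cell = "c1",
               gene = "g1", coverage_fraction = 1,
               support_a = c(rep(1, nA), rep(0, nB)),
               support_b = c(rep(0, nA), rep(1, nB)),
               assignment = c(rep("A", nA), rep("B", nB)),
               stringsAsFactors = FALSE)
  }
  avg <- dual_map_average(mk_calls(10, 4), mk_calls(8, 6))
  expect_equal(avg$count_a, 9)
  expect_equal(avg$count_b, 5)
  # symmetric
  avg2 <- dual_map_average(mk_calls(8, 6), mk_calls(10, 4))
  expect_equal(avg2$count_a, avg$count_a)
  # idempotent
  same <- dual_map_average(mk_calls(10, 4), mk_calls(10, 4))
  expect_equal(same$count_a, 10)
  expect_equal(same$count_b, 4)
  # a cell present in one mapping only is an error
  other <- mk_calls(3, 3); other$cell <- "c2"
  expect_error(dual_map_average(mk_calls(1, 1), other), "cell")
})

test_that("maternal fractions are recovered within binomial noise", {
  ref <- make_reference(n_genes = 5, n_snps_per_kb = 12, seed = 21)
  tx_m <- vapply(rownames(ref$index$transcripts),
                 scanlong:::transcript_sequence, character(1), ref = ref,
                 allele = "maternal")
  tx_p <- vapply(rownames(ref$index$transcripts),
                 scanlong:::transcript_sequence, character(1), ref = ref,
                 allele = "paternal")
  ms <- c(0, 0.25, 0.5, 0.75, 1)
  des <- library_design(default_barcodes(5),
                        transcript_ids = rownames(ref$index$transcripts),
                        maternal_fraction = ms)
  sim <- synthesize_reads(ref, des, error_model(), n_reads = 3000,
                          seed = 22)
  asg <- assign_to_transcripts(sim$alignments, ref$index)
  first <- !duplicated(asg$read_id)
  gene_of <- setNames(asg$gene_id, asg$read_id)[first]
  seqs <- ifelse(sim$truth$allele == "maternal", tx_m[sim$truth$transcript],
                 tx_p[sim$truth$transcript])
  reads <- read_set(sim$truth$read_id, seqs)
  calls <- allelic_calls(sim$alignments, reads, ref$index, ref$snps,
                         gene_of)
  avg <- dual_map_average(calls, calls)
  for (i in seq_along(ms)) {
    cell <- des$cells$cell[i]
    sub <- avg[avg$cell == cell, ]
    tot_a <- sum(sub$count_a); tot_b <- sum(sub$count_b)
    n <- tot_a + tot_b
    est <- tot_a / n
    expect_lt(abs(est - ms[i]), 3 * sqrt(0.25 / n) + 1e-9,
              label = sprintf("m = %.2f (est %.3f, n = %d)", ms[i], est, n))
  }
  # zero-error pure-strain assignment error is exactly zero
  err <- estimate_assignment_error(
    calls, setNames(c("A", "B"), des$cells$cell[c(5, 1)]))
  expect_equal(err$error_rate, c(0, 0))
})

test_that("assignment error is wrong calls over assigned calls", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:1100), cell = "pureA", gene = "g1",
    coverage_fraction = 1, support_a = 1, support_b = 0,
    assignment = c(rep("A", 987), rep("B", 13), rep("unassigned", 100)),
    stringsAsFactors = FALSE)
  err <- estimate_assignment_error(calls, c(pureA = "A"))
  expect_equal(err$error_rate[err$strain == "A"], 13 / 1000)
  expect_true(is.na(err$error_rate[err$strain == "B"]))
})

test_that("allelic summary reports discriminable fractions", {
  ref <- make_reference(n_genes = 6, n_snps_per_kb = 8, seed = 31)
  des <- library_design(default_barcodes(2),
                        transcript_ids = rownames(ref$index$transcripts),
                        maternal_fraction = 1)
  sim <- synthesize_reads(ref, des, error_model(), n_reads = 400, seed = 32)
  asg <- assign_to_transcripts(sim$alignments, ref$index)
  expr <- compute_matrix(asg)
  first <- !duplicated(asg$read_id)
  gene_of <- setNames(asg$gene_id, asg$read_id)[first]
  tx_m <- vapply(rownames(ref$index$transcripts),
                 scanlong:::transcript_sequence, character(1), ref = ref,
                 allele = "maternal")
  reads <- read_set(sim$truth$read_id, tx_m[sim$truth$transcript])
  calls <- allelic_calls(sim$alignments, reads, ref$index, ref$snps,
                         gene_of)
  avg <- dual_map_average(calls, calls)
  sm <- allelic_summary(avg, expr, ref$index, ref$snps)
  # pure maternal cells read off as fully maternal
  expect_true(all(abs(sm$maternal_fraction - 1) < 1e-9))
  # discriminable fraction equals the truth fraction of SNP-bearing tx
  snp_gr <- GenomicRanges::GRanges(
    ref$snps$chrom, IRanges::IRanges(ref$snps$pos0 + 1, ref$snps$pos0 + 1))
  ov <- GenomicRanges::findOverlaps(ref$index$exon_gr, snp_gr)
  tx_with <- unique(
    S4Vectors::mcols(ref$index$exon_gr)$transcript_id[
      S4Vectors::queryHits(ov)])
  for (i in seq_len(nrow(sm))) {
    cell <- sm$cell[i]
    tx_expr <- rownames(expr$tx_counts)[expr$tx_counts[, cell] > 0]
    expect_equal(sm$frac_tx_discriminable[i], mean(tx_expr %in% tx_with))
  }
})
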