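test_that("barcode scoring gives +2 per match, -2 per substitution", {
  bc <- test_barcode()
  win <- paste0("GGCC", bc, "TTAA")
  expect_equal(score_barcode(win, bc), 48L)
  chars <- sub_bases_at(strsplit(bc, "")[[1]], 5)
  expect_equal(score_barcode(paste0("GGCC", paste(chars, collapse = ""),
                                    "TTAA"), bc), 44L)
  expect_equal(score_barcode(revcomp(win), bc), 48L)
  expect_error(score_barcode(win, "ACGT"), "24")
})

test_that("random windows rarely reach the assignment cutoff", {
  set.seed(1)
  bases <- c("A", "C", "G", "T")
  windows <- vapply(1:20, function(i)
    paste(sample(bases, 150, replace = TRUE), collapse = ""), character(1))
  barcodes <- vapply(1:200, function(i)
    paste(sample(bases, 24, replace = TRUE), collapse = ""), character(1))
  hits <- 0
  for (w in windows) {
    scores <- vapply(barcodes, function(b) score_barcode(w, b), integer(1))
    hits <- hits + sum(scores >= 31)
  }
  expect_lt(hits / (length(windows) * length(barcodes)), 0.01)
})

test_that("demultiplexing assigns at score 31 and discards below", {
  bc1 <- test_barcode()
  bc2 <- default_barcodes(1)
  # 3 substitutions + 1 deletion: 20*2 - 3*2 - 3 = 31
  chars <- sub_bases_at(strsplit(bc1, "")[[1]], c(3, 9, 15))[-20]
  win31 <- paste0("GGCC", paste(chars, collapse = ""), "TTAA")
  expect_equal(score_barcode(win31, bc1), 31L)
  reads <- read_set("r31", win31)
  asg <- demultiplex(reads, c(bc1, bc2))
  expect_equal(asg$reason, "assigned")
  expect_equal(asg$barcode_index, 1L)
  # one more substitution: 19*2 - 4*2 - 3 = 27 < 31
  chars30 <- sub_bases_at(strsplit(bc1, "")[[1]], c(3, 9, 15, 22))[-20]
  win_low <- paste0("GGCC", paste(chars30, collapse = ""), "TTAA")
  expect_lt(score_barcode(win_low, bc1), 31L)
  asg_low <- demultiplex(read_set("rlow", win_low), c(bc1, bc2))
  expect_equal(asg_low$reason, "below_cutoff")
  expect_true(is.na(asg_low$barcode_index))
})

test_that("ties at the maximum score are left unassigned", {
  bc1 <- test_barcode()
  reads <- read_set("rtie", paste0("CC", bc1, "GG"))
  asg <- demultiplex(reads, c(bc1, bc1))  # same barcode twice -> tie
  expect_equal(asg$reason, "tie")
  expect_true(is.na(asg$barcode_index))
})

test_that("demultiplexing is invariant to reverse complementation", {
  ref <- make_reference(n_genes = 3, seed = 5)
  des <- library_design(default_barcodes(6),
                        transcript_ids = rownames(ref$index$transcripts))
  sim <- synthesize_reads(ref, des, error_model(p_sub = 0.05),
                          n_reads = 40, seed = 3)
  a1 <- demultiplex(sim$reads, des$barcodes)
  rc_reads <- read_set(sim$reads$read_id, revcomp(sim$reads$sequence))
  a2 <- demultiplex(rc_reads, des$barcodes)
  expect_equal(a1$barcode_index, a2$barcode_index)
  expect_equal(a1$best_score, a2$best_score)
})

test_that("read filters use strict less-than thresholds", {
  reads <- read_set(c("a", "b", "c", "d"),
                    c(strrep("A", 500), strrep("A", 99), strrep("A", 100),
                      strrep("A", 100)),
                    mean_q = c(6.9, 20, 7.0, 6.99))
  flt <- filter_reads(reads)
  expect_equal(flt$kept$read_id, "c")
  expect_equal(unname(flt$stats["low_quality"]), 2)
  expect_equal(unname(flt$stats["short"]), 1)
  expect_equal(unname(flt$stats["kept"] + flt$stats["low_quality"] +
                        flt$stats["short"]), length(reads))
})

test_that("structure detection recognizes the amplicon architecture", {
  ref <- make_reference(n_genes = 3, seed = 5)
  des <- library_design(default_barcodes(2),
                        transcript_ids = rownames(ref$index$transcripts))
  sim <- synthesize_reads(ref, des, error_model(), n_reads = 6, seed = 4)
  st <- find_structure(sim$reads$sequence[1], des)
  expect_equal(st$klass, "full_length")
  expect_equal(st$internal_anchor_hits, 0)
  # truncated amplicon (TSO end removed) -> polyT side only
  simt <- synthesize_reads(ref, des, error_model(truncation_prob = 1),
                           n_reads = 4, seed = 4)
  stt <- find_structure(simt$reads$sequence[1], des)
  expect_equal(stt$klass, "polyT_only")
  # concatenation of two amplicons -> chimeric with internal anchors
  chim <- paste0(sim$reads$sequence[1], sim$reads$sequence[2])
  stc <- find_structure(chim, des)
  expect_equal(stc$klass, "chimeric")
  expect_gte(stc$internal_anchor_hits, 1)
  # no architecture at all
  stn <- find_structure(strrep("ACGT", 100), des)
  expect_equal(stn$klass, "none")
})

test_that("orientation and trimming recover the exact transcript", {
  ref <- make_reference(n_genes = 4, seed = 6)
  des <- library_design(default_barcodes(2),
                        transcript_ids = rownames(ref$index$transcripts),
                        maternal_fraction = 1)
  sim <- synthesize_reads(ref, des, error_model(), n_reads = 30, seed = 8)
  for (i in seq_len(30)) {
    st <- find_structure(sim$reads$sequence[i], des)
    expect_equal(st$klass, "full_length")
    ot <- orient_and_trim(sim$reads[i], st, des)
    want <- scanlong:::transcript_sequence(ref, sim$truth$transcript[i],
                                           "maternal")
    expect_identical(ot$sequence, want)
    expect_equal(ot$transcribed_strand, sim$truth$strand[i])
  }
  # re-orienting an oriented read is the identity
  i <- 1
  st <- find_structure(sim$reads$sequence[i], des)
  ot <- orient_and_trim(sim$reads[i], st, des)
  s_flip <- revcomp(sim$reads$sequence[i])
  st_flip <- find_structure(s_flip, des)
  ot_flip <- orient_and_trim(read_set("rf", s_flip,
                                      list(rev(sim$reads$qualities[[i]]))),
                             st_flip, des)
  expect_identical(ot_flip$sequence, ot$sequence)
  # refuses non-full-length input
  stt <- find_structure(strrep("ACGT", 100), des)
  expect_error(orient_and_trim(sim$reads[1], stt, des), "full_length")
})

test_that("cell QC thresholds are strict less-than exclusions", {
  genes_ok <- setNames(rep(1, 5000), sprintf("g%d", 1:5000))
  genes_few <- setNames(rep(1, 2999), sprintf("g%d", 1:2999))
  genes_3000 <- setNames(rep(1, 3000), sprintf("g%d", 1:3000))
  qc <- compute_cell_qc(100000, gene_counts = genes_ok,
                        base_mapping_ratio = 0.90)
  expect_true(qc$pass)
  expect_false(compute_cell_qc(99999, gene_counts = genes_ok,
                               base_mapping_ratio = 0.90)$pass)
  expect_false(compute_cell_qc(100000, gene_counts = genes_ok,
                               base_mapping_ratio = 0.849)$pass)
  expect_true(compute_cell_qc(100000, gene_counts = genes_ok,
                              base_mapping_ratio = 0.85)$pass)
  expect_false(compute_cell_qc(100000, gene_counts = genes_few,
                               base_mapping_ratio = 0.90)$pass)
  expect_true(compute_cell_qc(100000, gene_counts = genes_3000,
                              base_mapping_ratio = 0.90)$pass)
})

test_that("length histogram bins deterministically and conserves counts", {
  h <- length_histogram(c(150, 151, 349), width = 100)
  expect_equal(h$bin_start, c(100, 300))
  expect_equal(h$count, c(2L, 1L))
  expect_equal(sum(h$count), 3L)
  expect_equal(nrow(length_histogram(numeric(0))), 0)
})

test_that("error-free library demultiplexes perfectly to truth cells", {
  ref <- make_reference(n_genes = 4, seed = 6)
  des <- library_design(default_barcodes(8),
                        transcript_ids = rownames(ref$index$transcripts))
  sim <- synthesize_reads(ref, des, error_model(truncation_prob = 0.1),
                          n_reads = 300, seed = 11)
  asg <- demultiplex(sim$reads, des$barcodes)
  nontrunc <- !sim$truth$truncated
  expect_true(all(asg$reason[nontrunc] == "assigned"))
  cells <- des$cells$cell[asg$barcode_index]
  ok <- asg$reason == "assigned"
  expect_true(all(cells[ok] == sim$truth$cell[ok]))
})
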