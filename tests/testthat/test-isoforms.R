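test_that("reads with identical chains form one cluster", {
  idx <- toy_index()
  aln <- aln_set(list(cbind(c(110, 300, 500), c(200, 400, 590)),
                      cbind(c(105, 300, 500), c(200, 400, 595))))
  cl <- cluster_reads(aln, idx)
  expect_equal(length(cl), 1)
  expect_equal(length(cl[[1]]$read_ids), 2)
})

test_that("edges within tolerance of annotated sites snap together", {
  idx <- toy_index()
  aln <- aln_set(list(cbind(c(110, 300, 500), c(200, 400, 590)),
                      cbind(c(110, 303, 500), c(197, 400, 590))))
  cl <- cluster_reads(aln, idx)
  expect_equal(length(cl), 1)
  expect_equal(unname(cl[[1]]$chain[, 1]), c(200, 400))
  expect_equal(unname(cl[[1]]$chain[, 2]), c(300, 500))
})

test_that("chains differing by a whole junction stay distinct", {
  idx <- toy_index()
  aln <- aln_set(list(cbind(c(110, 300, 500), c(200, 400, 590)),
                      cbind(c(110, 500), c(200, 590))))
  cl <- cluster_reads(aln, idx)
  expect_equal(length(cl), 2)
})

test_that("depth filter distinguishes annotated and novel regions", {
  idx <- toy_index()
  known2 <- model_of(cbind(c(110, 300, 500), c(200, 400, 590)),
                     index = idx, n_reads = 2)
  known1 <- model_of(cbind(c(110, 300, 500), c(200, 400, 590)),
                     index = idx, n_reads = 1)
  novel4 <- model_of(cbind(c(110, 300), c(200, 600)), index = idx,
                     n_reads = 4)  # retained intron region
  novel5 <- model_of(cbind(c(110, 300), c(200, 600)), index = idx,
                     n_reads = 5)
  kept <- filter_clusters(list(known2, known1, novel4, novel5), idx)
  expect_equal(length(kept), 2)
  expect_equal(vapply(kept, function(m) length(m$read_ids), integer(1)),
               c(2L, 5L))
})

test_that("collapse merges identical chains and 5' truncations", {
  idx <- toy_index()
  full <- model_of(cbind(c(110, 300, 500), c(200, 400, 590)), index = idx,
                   n_reads = 3)
  full2 <- model_of(cbind(c(112, 300, 500), c(200, 400, 588)), index = idx,
                    n_reads = 2)
  trunc <- model_of(cbind(c(310, 500), c(400, 590)), index = idx,
                    n_reads = 2)  # same 3' end, one junction missing
  other <- model_of(cbind(c(110, 500), c(200, 590)), index = idx,
                    n_reads = 2)
  out <- collapse_models(list(full, full2, trunc, other), idx)
  expect_equal(length(out), 2)
  sizes <- sort(vapply(out, function(m) length(m$read_ids), integer(1)))
  expect_equal(sizes, c(2L, 7L))
})

test_that("on the minus strand a 5' truncation is a genomic prefix", {
  ex <- toy_gene_exons()
  ex$strand <- "-"
  idx <- annotation_index(ex)
  full <- model_of(cbind(c(110, 300, 500), c(200, 400, 590)),
                   strand = "-", index = idx, n_reads = 3)
  # minus-strand 5' truncation keeps the low-coordinate (3') junctions
  trunc <- model_of(cbind(c(110, 300), c(200, 390)), strand = "-",
                    index = idx, n_reads = 2)
  out <- collapse_models(list(full, trunc), idx)
  expect_equal(length(out), 1)
  expect_equal(length(out[[1]]$read_ids), 5)
})

test_that("the worked classification examples reproduce", {
  idx <- toy_index()
  # exact chain -> known
  expect_equal(classify_model(model_of(
    cbind(c(100, 300, 500), c(200, 400, 600)), index = idx), idx),
    "known")
  # two annotated skip junctions combined -> CJ (five-exon gene)
  expect_equal(classify_model(model_of(
    cbind(c(100, 500, 900), c(200, 600, 1000)), chrom = "chr2",
    index = idx), idx), "CJ")
  # donor 200 and acceptor 500 annotated, pairing novel -> CS
  expect_equal(classify_model(model_of(
    cbind(c(100, 500), c(200, 600)), index = idx), idx), "CS")
  # retained intron (200,300)...? exons [100,400),[500,600) retain (400,500)'s
  # left neighbour: intron (200,300) inside [100,400) -> IR
  expect_equal(classify_model(model_of(
    cbind(c(100, 500), c(400, 600)), index = idx), idx), "IR")
  # mono-exon inside an annotated exon -> ME
  expect_equal(classify_model(model_of(cbind(310, 390), index = idx),
                              idx), "ME")
  # mono-exon spanning two exons plus their intron -> MIR
  expect_equal(classify_model(model_of(cbind(100, 400), index = idx),
                              idx), "MIR")
  # mono-exon away from all genes -> intergenic
  expect_equal(classify_model(model_of(cbind(5000, 5100), index = idx),
                              idx), "intergenic")
  # truncated subchain -> known, not novel
  expect_equal(classify_model(model_of(
    cbind(c(310, 500), c(400, 600)), index = idx), idx), "known")
})

test_that("classifier agrees with a literal brute-force oracle", {
  set.seed(42)
  n_agree <- 0
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    case <- random_classifier_case()
    got <- classify_model(case$model, case$index)
    want <- oracle_classify(case$model, case$exons_df)
    if (!identical(got, want)) {
      info <- sprintf(
        "case %d: got %s, oracle %s (exons %s)", i, got, want,
        paste(apply(case$model$exons, 1, paste, collapse = "-"),
              collapse = ","))
      fail(info)
    }
    n_agree <- n_agree + identical(got, want)
  }
  expect_equal(n_agree, n_cases)
})

test_that("expression filters follow the strict boundary semantics", {
  cells <- sprintf("c%d", 1:4)
  rpt <- matrix(0, 2, 4, dimnames = list(c("n1", "n2"), cells))
  host <- matrix(2, 2, 4, dimnames = list(c("n1", "n2"), cells))
  # n1: RPT10k exactly 0.1 and share exactly 5% in exactly 3 cells
  rpt["n1", 1:3] <- 0.1
  host["n1", 1:3] <- 2
  out <- filter_novel(rpt, host)
  expect_true(out$retained[out$model == "n1"])
  # below the expression floor everywhere -> dropped
  rpt2 <- rpt; rpt2["n1", 1:3] <- 0.09
  expect_false(filter_novel(rpt2, host)$retained[1])
  # share below 5% -> dropped
  host3 <- host; host3["n1", 1:3] <- 0.1 / 0.049
  expect_false(filter_novel(rpt, host3)$retained[1])
  # detected in only 2 cells -> dropped
  rpt4 <- rpt; rpt4["n1", 3] <- 0
  expect_false(filter_novel(rpt4, host)$retained[1])
  # inconsistent host expression errors
  host5 <- host; host5["n1", 1] <- 0
  expect_error(filter_novel(rpt, host5), "host gene")
})

test_that("raising the min-cells threshold never adds retained models", {
  set.seed(7)
  rpt <- matrix(runif(40, 0, 0.5), 8, 5,
                dimnames = list(sprintf("n%d", 1:8), sprintf("c%d", 1:5)))
  host <- matrix(2, 8, 5, dimnames = dimnames(rpt))
  kept <- vapply(1:5, function(k)
    sum(filter_novel(rpt, host, min_cells = k)$retained), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("cross-cell merging unifies chains and counts cells", {
  idx <- toy_index()
  m1 <- model_of(cbind(c(110, 500), c(200, 600)), index = idx, n_reads = 2)
  m2 <- model_of(cbind(c(115, 500), c(200, 597)), index = idx, n_reads = 3)
  m3 <- model_of(cbind(c(110, 300), c(200, 420)), index = idx, n_reads = 2)
  per_cell <- list(cellA = list(m1), cellB = list(m2), cellC = list(m3))
  mg <- merge_across_cells(per_cell)
  expect_equal(nrow(mg$table), 2)
  merged <- mg$catalogue[[which(mg$table$n_cells == 2)]]
  expect_setequal(merged$cells, c("cellA", "cellB"))
  # catalogue size equals the number of distinct chains
  keys <- c(scanlong:::chain_key(m1$chain), scanlong:::chain_key(m2$chain),
            scanlong:::chain_key(m3$chain))
  expect_equal(nrow(mg$table), length(unique(keys)))
})

test_that("planted novel isoforms are recovered with true categories", {
  ref <- make_planted_reference(seed = 2)
  des <- library_design(default_barcodes(4),
                        transcript_ids = rownames(ref$index$transcripts))
  sim <- synthesize_reads(ref, des, error_model(), n_reads = 900, seed = 7)
  iso <- discover_isoforms(sim$alignments, ref$base_index)
  calls <- iso$calls[iso$calls$retained, ]
  cat_of <- setNames(calls$category, calls$host_gene)
  for (i in seq_len(nrow(ref$novel_truth))) {
    nt <- ref$novel_truth[i, ]
    expect_true(nt$host_gene %in% names(cat_of),
                label = sprintf("%s recovered", nt$transcript_id))
    expect_equal(unname(cat_of[nt$host_gene]), nt$category)
  }
  # each planted model had at least 5 supporting reads and 3 cells
  expect_true(all(calls$n_cells_detected >= 3))
})
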