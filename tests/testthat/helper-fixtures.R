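# Shared fixtures, all built in code.

# three-exon gene matching the worked classification examples:
# T1 exons [100,200), [300,400), [500,600) on "+"
toy_gene_exons <- function(chrom = "chr1") {
  data.frame(gene_id = "g1", transcript_id = "t1", chrom = chrom,
             strand = "+", start = c(100, 300, 500),
             end = c(200, 400, 600), stringsAsFactors = FALSE)
}

# five-exon gene with two exon-skipping isoforms; combining the two skip
# junctions yields a chain matching no single transcript (a CJ)
cj_gene_exons <- function(chrom = "chr2") {
  starts <- c(100, 300, 500, 700, 900)
  ends <- starts + 100
  rbind(
    data.frame(gene_id = "g2", transcript_id = "t2a", chrom = chrom,
               strand = "+", start = starts, end = ends,
               stringsAsFactors = FALSE),
    data.frame(gene_id = "g2", transcript_id = "t2b", chrom = chrom,
               strand = "+", start = starts[c(1, 3, 4, 5)],
               end = ends[c(1, 3, 4, 5)], stringsAsFactors = FALSE),
    data.frame(gene_id = "g2", transcript_id = "t2c", chrom = chrom,
               strand = "+", start = starts[c(1, 2, 3, 5)],
               end = ends[c(1, 2, 3, 5)], stringsAsFactors = FALSE))
}

toy_index <- function() annotation_index(rbind(toy_gene_exons(),
                                               cj_gene_exons()))

# a model from raw exon coordinates, classified against `index`
model_of <- function(exons, strand = "+", chrom = "chr1", index = NULL,
                     n_reads = 1) {
  transcript_model(chrom, strand, exons,
                   read_ids = sprintf("r%d", seq_len(n_reads)),
                   any_unannotated_edge = FALSE, index = index)
}

# fixed 24-nt barcode used in scoring tests
test_barcode <- function() "ACGTACGTAAGGCCTTACGGATCC"

# substitute a different base at the given positions
sub_bases_at <- function(chars, idx) {
  o <- c("A", "C", "G", "T")
  chars[idx] <- o[match(chars[idx], o) %% 4 + 1]
  chars
}

# alignment_set from a list of block matrices
aln_set <- function(blocks, chrom = "chr1", strand = "+", cell = NULL,
                    read_id = sprintf("r%03d", seq_along(blocks))) {
  df <- data.frame(read_id = read_id,
                   chrom = rep_len(chrom, length(blocks)),
                   strand = rep_len(strand, length(blocks)),
                   blocks = scanlong:::format_blocks(blocks),
                   aligned_base_fraction = 1,
                   secondary = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cell)) df$cell <- rep_len(cell, length(blocks))
  class(df) <- c("alignment_set", "data.frame")
  df
}

# literal brute-force classifier over the raw exon table: loops over
# transcripts, junctions and intron intervals without using the index's
# precomputed chain keys or site sets; mirrors the category definitions
oracle_classify <- function(model, exons_df) {
  ex <- exons_df[exons_df$chrom == model$chrom &
                 exons_df$strand == model$strand, , drop = FALSE]
  tx_list <- split(ex, ex$transcript_id)
  chains <- lapply(tx_list, function(e) {
    e <- e[order(e$start), ]
    k <- nrow(e)
    if (k < 2) matrix(numeric(0), ncol = 2)
    else cbind(e$end[-k], e$start[-1])
  })
  same_chain <- function(a, b) {
    nrow(a) == nrow(b) && (nrow(a) == 0 || all(a == b))
  }
  sub_chain <- function(big, small) {
    k <- nrow(small)
    if (k == 0) return(TRUE)
    if (nrow(big) < k) return(FALSE)
    for (off in 0:(nrow(big) - k))
      if (all(big[off + seq_len(k), , drop = FALSE] == small)) return(TRUE)
    FALSE
  }
  gene_spans <- do.call(rbind, lapply(
    split(exons_df[exons_df$chrom == model$chrom, , drop = FALSE],
          exons_df$gene_id[exons_df$chrom == model$chrom]),
    function(e) data.frame(gene_id = e$gene_id[1], start = min(e$start),
                           end = max(e$end))))
  mexons <- model$exons
  mchain <- model$chain

  # host gene: maximal summed exonic overlap, then any span overlap
  ov_by_gene <- vapply(split(ex, ex$gene_id), function(e) {
    tot <- 0
    for (i in seq_len(nrow(e)))
      for (j in seq_len(nrow(mexons)))
        tot <- tot + max(0, min(e$end[i], mexons[j, 2]) -
                             max(e$start[i], mexons[j, 1]))
    tot
  }, numeric(1))
  host <- if (length(ov_by_gene) > 0 && max(ov_by_gene) > 0)
    names(ov_by_gene)[which.max(ov_by_gene)] else NA_character_
  if (is.na(host) && !is.null(gene_spans)) {
    for (gi in seq_len(nrow(gene_spans)))
      if (gene_spans$end[gi] > mexons[1, 1] &&
          gene_spans$start[gi] < mexons[nrow(mexons), 2]) {
        host <- gene_spans$gene_id[gi]; break
      }
  }

  if (nrow(mexons) == 1) {
    s <- mexons[1, 1]; e <- mexons[1, 2]
    for (i in seq_len(nrow(ex)))
      if (ex$start[i] <= s && ex$end[i] >= e) return("ME")
    for (ch in chains) {
      if (nrow(ch) == 0) next
      for (i in seq_len(nrow(ch)))
        if (ch[i, 1] >= s + 1 && ch[i, 2] <= e - 1) return("MIR")
    }
    overlaps_gene <- FALSE
    if (!is.null(gene_spans))
      for (gi in seq_len(nrow(gene_spans)))
        if (gene_spans$end[gi] > s && gene_spans$start[gi] < e)
          overlaps_gene <- TRUE
    if (!overlaps_gene) return("intergenic")
    return("discarded")
  }

  for (ch in chains) if (same_chain(ch, mchain)) return("known")
  if (is.na(host)) {
    overlaps_gene <- FALSE
    if (!is.null(gene_spans))
      for (gi in seq_len(nrow(gene_spans)))
        if (gene_spans$end[gi] > mexons[1, 1] &&
            gene_spans$start[gi] < mexons[nrow(mexons), 2])
          overlaps_gene <- TRUE
    return(if (overlaps_gene) "discarded" else "intergenic")
  }

  host_ex <- ex[ex$gene_id == host, , drop = FALSE]
  host_chains <- chains[unique(host_ex$transcript_id)]
  for (ch in host_chains) {
    if (nrow(ch) == 0) next
    for (i in seq_len(nrow(ch)))
      for (j in seq_len(nrow(mexons)))
        if (ch[i, 1] >= mexons[j, 1] + 1 && ch[i, 2] <= mexons[j, 2] - 1)
          return("IR")
  }
  for (ch in chains) if (sub_chain(ch, mchain)) return("known")

  host_j <- unique(do.call(rbind, host_chains))
  all_j_known <- all(apply(mchain, 1, function(j)
    any(host_j[, 1] == j[1] & host_j[, 2] == j[2])))
  if (all_j_known) return("CJ")
  if (all(mchain[, 1] %in% host_j[, 1]) &&
      all(mchain[, 2] %in% host_j[, 2])) return("CS")
  "discarded"
}

# random toy annotation + random model for classifier agreement testing
random_classifier_case <- function() {
  n_exons <- sample(3:5, 1)
  gap <- sample(80:200, n_exons, replace = TRUE)
  w <- sample(60:150, n_exons, replace = TRUE)
  starts <- 100 + cumsum(c(0, (w + gap)[-n_exons]))
  ends <- starts + w
  strand <- sample(c("+", "-"), 1)
  rows <- data.frame(gene_id = "gA", transcript_id = "tA1", chrom = "chrR",
                     strand = strand, start = starts, end = ends,
                     stringsAsFactors = FALSE)
  if (n_exons >= 3 && runif(1) < 0.7) {
    keep <- sort(sample(seq_len(n_exons), n_exons - 1))
    rows <- rbind(rows, data.frame(gene_id = "gA", transcript_id = "tA2",
                                   chrom = "chrR", strand = strand,
                                   start = starts[keep], end = ends[keep],
                                   stringsAsFactors = FALSE))
  }
  index <- annotation_index(rows)

  kind <- sample(c("exact", "subset", "fused", "mono_in", "mono_span",
                   "mono_out", "shift"), 1)
  exons <- cbind(start = starts, end = ends)
  model_exons <- switch(kind,
    exact = exons,
    subset = {
      keep <- sort(sample(seq_len(n_exons), max(2, n_exons - 1)))
      exons[keep, , drop = FALSE]
    },
    fused = {
      i <- sample(seq_len(n_exons - 1), 1)
      fused <- rbind(cbind(exons[i, 1], exons[i + 1, 2]))
      out <- rbind(exons[seq_len(i - 1), , drop = FALSE], fused,
                   exons[-seq_len(i + 1), , drop = FALSE])
      colnames(out) <- c("start", "end")
      out
    },
    mono_in = {
      i <- sample(seq_len(n_exons), 1)
      cbind(start = starts[i] + 5, end = ends[i] - 5)
    },
    mono_span = {
      i <- sample(seq_len(n_exons - 1), 1)
      cbind(start = starts[i], end = ends[i + 1])
    },
    mono_out = cbind(start = max(ends) + 300, end = max(ends) + 400),
    shift = {
      ex2 <- exons
      i <- sample(seq_len(n_exons), 1)
      side <- sample(1:2, 1)
      ex2[i, side] <- ex2[i, side] + sample(c(-40, 40), 1)
      ex2 <- ex2[ex2[, 1] < ex2[, 2], , drop = FALSE]
      if (any(diff(as.vector(t(ex2))) <= 0)) exons else ex2
    })
  list(index = index, exons_df = rows,
       model = transcript_model("chrR", strand, model_exons, "r1",
                                any_unannotated_edge = FALSE,
                                index = index))
}
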