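# chain containment: does `big` (m x 2) contain `small` (k x 2) as a
# contiguous subchain with each edge within +/- tol?
chain_contains <- function(big, small, tol = 5) {
  k <- nrow(small); m <- nrow(big)
  if (k == 0) return(TRUE)
  if (m < k) return(FALSE)
  for (off in 0:(m - k)) {
    seg <- big[off + seq_len(k), , drop = FALSE]
    if (all(abs(seg - small) <= tol)) return(TRUE)
  }
  FALSE
}

#' Assign spliced alignments to annotated transcripts
#'
#' A read's candidate transcripts are those on the same chromosome and
#' strand whose junction chain contains the read's junction chain as a
#' contiguous subchain (each edge within `tol` bases) and whose genomic
#' span covers the read's blocks. Weight 1 per read is split equally among
#' its candidates; reads with no candidate are returned unassigned so they
#' can be routed to region classification.
#'
#' @param alignments an `alignment_set` (primary alignments).
#' @param index an `annotation_index`.
#' @param tol junction edge tolerance in bases (default 5).
#' @param use_strand require strand agreement (default TRUE).
#' @return data.frame: read_id, cell (if present), transcript_id, gene_id,
#'   weight; unassigned reads have NA transcript_id and weight 0.
#' @export
assign_to_transcripts <- function(alignments, index, tol = 5,
                                  use_strand = TRUE) {
  tx <- index$transcripts
  blocks <- parse_blocks(alignments$blocks)
  has_cell <- "cell" %in% names(alignments)
  out <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    b <- blocks[[i]]
    chain <- blocks_to_chain(b)
    span <- c(b[1, 1], b[nrow(b), 2])
    cand <- tx[tx$chrom == alignments$chrom[i] &
               (!use_strand | tx$strand == alignments$strand[i]) &
               tx$start <= span[1] + tol & tx$end >= span[2] - tol, ,
               drop = FALSE]
    if (nrow(cand) > 0) {
      ok <- vapply(cand$transcript_id, function(t)
        chain_contains(index$chains[[t]], chain, tol), logical(1))
      cand <- cand[ok, , drop = FALSE]
    }
    if (nrow(cand) == 0) {
      out[[i]] <- data.frame(read_id = alignments$read_id[i],
                             cell = if (has_cell) alignments$cell[i]
                             else NA_character_,
                             transcript_id = NA_character_,
                             gene_id = NA_character_, weight = 0,
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(read_id = alignments$read_id[i],
                             cell = if (has_cell) alignments$cell[i]
                             else NA_character_,
                             transcript_id = cand$transcript_id,
                             gene_id = cand$gene_id,
                             weight = 1 / nrow(cand),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read_id = character(0), cell = character(0),
                      transcript_id = character(0), gene_id = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Expression matrices in reads per 10,000 mapped reads
#'
#' Builds transcript- and gene-level raw count matrices (features x cells)
#' from weighted assignments and normalizes each cell to reads per 10,000
#' mapped reads: RPT10k and RPG10k. The per-cell normalizing total is the
#' summed assignment weight (the number of assigned reads), so RPG10k sums
#' to 10,000 per cell.
#'
#' @param assignments data.frame from [assign_to_transcripts()] with a
#'   `cell` column.
#' @param cells optional character vector fixing the cell order.
#' @return a `scan_expr` list: tx_counts, gene_counts, rpt10k, rpg10k
#'   (matrices features x cells), mapped_total (per cell).
#' @export
compute_matrix <- function(assignments, cells = NULL) {
  a <- assignments[!is.na(assignments$transcript_id), , drop = FALSE]
  if (is.null(cells)) cells <- sort(unique(a$cell))
  empty <- setdiff(unique(assignments$cell), NA)
  tx_ids <- sort(unique(a$transcript_id))
  gene_ids <- sort(unique(a$gene_id))
  tx_counts <- matrix(0, length(tx_ids), length(cells),
                      dimnames = list(tx_ids, cells))
  for (j in seq_along(cells)) {
    sub <- a[a$cell == cells[j], , drop = FALSE]
    if (nrow(sub) == 0) next
    agg <- tapply(sub$weight, sub$transcript_id, sum)
    tx_counts[names(agg), j] <- agg
  }
  zero <- colSums(tx_counts) == 0
  if (any(zero)) {
    warning(sprintf("cells with zero mapped reads omitted: %s",
                    paste(cells[zero], collapse = ", ")))
    tx_counts <- tx_counts[, !zero, drop = FALSE]
    cells <- cells[!zero]
  }
  gene_of_tx <- a$gene_id[match(rownames(tx_counts), a$transcript_id)]
  gene_counts <- rowsum(tx_counts, gene_of_tx)
  mapped_total <- colSums(gene_counts)
  rpt10k <- sweep(tx_counts, 2, mapped_total, "/") * 10000
  rpg10k <- sweep(gene_counts, 2, mapped_total, "/") * 10000
  structure(list(tx_counts = tx_counts, gene_counts = gene_counts,
                 rpt10k = rpt10k, rpg10k = rpg10k,
                 mapped_total = mapped_total),
            class = "scan_expr")
}

#' @export
print.scan_expr <- function(x, ...) {
  cat(sprintf("scan_expr: %d transcripts, %d genes x %d cells\n",
              nrow(x$tx_counts), nrow(x$gene_counts), ncol(x$tx_counts)))
  invisible(x)
}

#' Classify reads into exonic, intronic and intergenic compartments
#'
#' Precedence exon > intron > intergenic: a read is exonic if any block
#' overlaps an annotated exon, else intronic if any block overlaps a gene
#' span, else intergenic. One label per read_id (redundancy removal:
#' primary alignments only; the first record wins).
#'
#' @param alignments an `alignment_set`.
#' @param index an `annotation_index`.
#' @return list: `labels` (data.frame read_id, cell, region), `counts`
#'   (per-cell exonic/intronic/intergenic counts when cells are present,
#'   else totals).
#' @export
classify_regions <- function(alignments, index) {
  aln <- alignments[!duplicated(alignments$read_id), , drop = FALSE]
  blocks <- parse_blocks(aln$blocks)
  nb <- vapply(blocks, nrow, integer(1))
  gr <- GenomicRanges::GRanges(
    rep(aln$chrom, nb),
    IRanges::IRanges(unlist(lapply(blocks, function(m) m[, 1])) + 1,
                     unlist(lapply(blocks, function(m) m[, 2]))))
  read_of_block <- rep(seq_len(nrow(aln)), nb)
  ex_hit <- IRanges::overlapsAny(gr, index$exon_gr,
                                       ignore.strand = TRUE)
  gene_hit <- IRanges::overlapsAny(gr, index$gene_gr,
                                         ignore.strand = TRUE)
  exonic <- tapply(ex_hit, read_of_block, any)
  genic <- tapply(gene_hit, read_of_block, any)
  region <- ifelse(exonic, "exon", ifelse(genic, "intron", "intergenic"))
  labels <- data.frame(read_id = aln$read_id,
                       cell = if ("cell" %in% names(aln)) aln$cell
                       else NA_character_,
                       region = as.character(region),
                       stringsAsFactors = FALSE)
  counts <- if (all(is.na(labels$cell))) {
    t <- table(factor(labels$region,
                      levels = c("exon", "intron", "intergenic")))
    as.data.frame(rbind(t))
  } else {
    as.data.frame.matrix(table(labels$cell,
                               factor(labels$region,
                                      levels = c("exon", "intron",
                                                 "intergenic"))))
  }
  list(labels = labels, counts = counts)
}

#' Quantify lncRNAs from intergenic reads
#'
#' Only reads labeled intergenic against the primary annotation take part;
#' they are assigned to the transcripts of a secondary (lncRNA) annotation
#' with the same junction-compatibility rules and normalized to reads per
#' 10,000 within the lncRNA compartment.
#'
#' @param alignments `alignment_set` of the intergenic reads against the
#'   coordinate system of `lnc_index` (same genome when the lncRNA models
#'   are genomic).
#' @param region_labels data.frame from [classify_regions()] (`labels`).
#' @param lnc_index `annotation_index` of the lncRNA reference.
#' @param tol junction tolerance.
#' @return a `scan_expr` over lncRNA transcripts (empty with a warning when
#'   the reference is empty).
#' @export
quantify_lncrna <- function(alignments, region_labels, lnc_index, tol = 5) {
  if (nrow(lnc_index$transcripts) == 0) {
    warning("empty lncRNA reference: returning empty matrix")
    return(structure(list(tx_counts = matrix(0, 0, 0),
                          gene_counts = matrix(0, 0, 0),
                          rpt10k = matrix(0, 0, 0),
                          rpg10k = matrix(0, 0, 0),
                          mapped_total = numeric(0)),
                     class = "scan_expr"))
  }
  inter_ids <- region_labels$read_id[region_labels$region == "intergenic"]
  aln <- alignments[alignments$read_id %in% inter_ids, , drop = FALSE]
  asg <- assign_to_transcripts(aln, lnc_index, tol)
  compute_matrix(asg)
}

#' Saturation of detected genes and isoforms versus sequencing depth
#'
#' Subsamples assigned reads without replacement at each depth, `n_draws`
#' times, and reports the mean number of genes and transcripts detected
#' (raw count > 0). Deterministic given `seed`.
#'
#' @param assignments data.frame from [assign_to_transcripts()].
#' @param depths integer vector of read depths (<= number of reads).
#' @param n_draws subsample replicates per depth (default 10).
#' @param seed RNG seed.
#' @return data.frame: depth, mean_genes, mean_transcripts.
#' @export
saturation <- function(assignments, depths, n_draws = 10, seed = 1) {
  by_read <- split(assignments[!is.na(assignments$transcript_id),
                               c("transcript_id", "gene_id")],
                   assignments$read_id[!is.na(assignments$transcript_id)])
  total <- length(by_read)
  if (any(depths > total))
    stop(sprintf("depth %d exceeds the %d assigned reads",
                 max(depths), total))
  with_seed(seed, {
    res <- lapply(depths, function(d) {
      draws <- vapply(seq_len(n_draws), function(r) {
        idx <- if (d == total) seq_len(total) else sample.int(total, d)
        sub <- by_read[idx]
        c(genes = length(unique(unlist(lapply(sub, `[[`, "gene_id")))),
          tx = length(unique(unlist(lapply(sub, `[[`,
                                           "transcript_id")))))
      }, numeric(2))
      data.frame(depth = d, mean_genes = mean(draws["genes", ]),
                 mean_transcripts = mean(draws["tx", ]))
    })
    do.call(rbind, res)
  })
}
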