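#' Build the alternate strain genome from SNP substitutions
#'
#' Replaces the reference base with the alternate allele at every SNP
#' position. Substitutions only, so lengths and coordinates are unchanged
#' and the two genomes stay directly comparable.
#'
#' @param genome a [Biostrings::DNAStringSet] (names = chromosomes).
#' @param snps a `snp_table`; every ref allele must match the genome.
#' @return the alternate `DNAStringSet`.
#' @export
build_alt_genome <- function(genome, snps) {
  out <- genome
  for (ch in unique(snps$chrom)) {
    if (!ch %in% names(out)) stop(sprintf("unknown chromosome '%s'", ch))
    sn <- snps[snps$chrom == ch, , drop = FALSE]
    at <- sn$pos0 + 1
    idx <- match(ch, names(out))
    have <- strsplit(Biostrings::letter(out[[idx]], at), "")[[1]]
    bad <- which(have != sn$ref)
    if (length(bad) > 0)
      stop(sprintf("ref allele mismatch at %s:%d (genome %s, VCF %s)",
                   ch, sn$pos0[bad[1]] + 1, have[bad[1]], sn$ref[bad[1]]))
    out[[idx]] <- Biostrings::replaceLetterAt(
      out[[idx]], at, paste(sn$alt, collapse = ""))
  }
  out
}

#' Count strain-supporting SNPs within a read's alignment
#'
#' For every SNP falling inside the alignment blocks, the read base at the
#' SNP position (through the block-wise genome-to-read coordinate map) is
#' compared with both alleles; matches increment the respective counter and
#' third bases (sequencing error) are ignored.
#'
#' @param blocks numeric matrix (start, end) of aligned genomic blocks,
#'   0-based half-open, in read order along the genome.
#' @param read_seq read sequence in genome-plus-strand orientation.
#' @param strand alignment strand; "-" reads are reverse-complemented
#'   internally before position lookup.
#' @param snps a `snp_table` restricted to the alignment's chromosome.
#' @return integer vector c(ref = matches to the ref allele, alt = matches
#'   to the alt allele).
#' @export
genotype_read <- function(blocks, read_seq, strand, snps) {
  if (strand == "-") read_seq <- revcomp(read_seq)
  offs <- cumsum(c(0, blocks[, 2] - blocks[, 1]))
  support <- c(ref = 0L, alt = 0L)
  if (nrow(snps) == 0) return(support)
  for (i in seq_len(nrow(blocks))) {
    inside <- snps$pos0 >= blocks[i, 1] & snps$pos0 < blocks[i, 2]
    if (!any(inside)) next
    read_pos <- offs[i] + snps$pos0[inside] - blocks[i, 1] + 1
    base <- substring(read_seq, read_pos, read_pos)
    support["ref"] <- support["ref"] + sum(base == snps$ref[inside])
    support["alt"] <- support["alt"] + sum(base == snps$alt[inside])
  }
  support
}

#' Assign a read to a parental strain
#'
#' Reads covering less than `min_coverage` of the host gene's shortest
#' transcript are excluded. A read with exactly one informative SNP goes to
#' that SNP's strain; with more, a strain wins only when its SNP count is
#' at least twice the other's (and at least one). Anything else is
#' unassigned.
#'
#' @param coverage_fraction fraction of the gene's shortest annotated
#'   transcript covered by the read (capped at 1).
#' @param support_a,support_b informative SNP counts for strains A and B.
#' @param min_coverage coverage threshold (default 0.60; equality passes).
#' @return assignment string: "A", "B", "unassigned", or
#'   "excluded_low_coverage".
#' @export
assign_allele <- function(coverage_fraction, support_a, support_b,
                          min_coverage = 0.60) {
  if (coverage_fraction < min_coverage) return("excluded_low_coverage")
  total <- support_a + support_b
  if (total == 1) return(if (support_a == 1) "A" else "B")
  if (support_a >= 1 && support_a >= 2 * support_b) return("A")
  if (support_b >= 1 && support_b >= 2 * support_a) return("B")
  "unassigned"
}

# coverage of the gene's shortest annotated transcript:
# aligned bases overlapping the gene span / min spliced length, capped at 1
coverage_fraction_of <- function(blocks, gene_id, index) {
  tx <- index$transcripts[index$transcripts$gene_id == gene_id, ,
                          drop = FALSE]
  if (nrow(tx) == 0) return(0)
  shortest <- min(tx$spliced_length)
  g <- index$genes[gene_id, ]
  ov <- pmin(blocks[, 2], g$end) - pmax(blocks[, 1], g$start)
  min(sum(pmax(ov, 0)) / shortest, 1)
}

#' Per-read allelic calls for one reference mapping
#'
#' Combines gene assignment, shortest-transcript coverage, SNP genotyping
#' and the assignment rules into per-read calls.
#'
#' @param alignments `alignment_set` (with `cell` when available).
#' @param reads a `read_set` supplying read sequences (genome-plus-strand
#'   orientation is derived from the alignment strand).
#' @param index an `annotation_index`.
#' @param snps a `snp_table`.
#' @param gene_of named character: read_id -> gene (e.g. from
#'   [assign_to_transcripts()]); reads without a gene are skipped.
#' @param min_coverage coverage threshold (default 0.60).
#' @return data.frame: read_id, cell, gene, coverage_fraction, support_a,
#'   support_b, assignment.
#' @export
allelic_calls <- function(alignments, reads, index, snps, gene_of,
                          min_coverage = 0.60) {
  seq_of <- setNames(reads$sequence, reads$read_id)
  blocks <- parse_blocks(alignments$blocks)
  has_cell <- "cell" %in% names(alignments)
  snps_by_chrom <- split(as.data.frame(snps), snps$chrom)
  n <- nrow(alignments)
  v_gene <- character(n); v_cov <- numeric(n)
  v_a <- integer(n); v_b <- integer(n); v_asg <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    rid <- alignments$read_id[i]
    gene <- gene_of[rid]
    if (is.na(gene)) next
    keep[i] <- TRUE
    b <- blocks[[i]]
    cov <- coverage_fraction_of(b, gene, index)
    sn <- snps_by_chrom[[alignments$chrom[i]]]
    if (is.null(sn)) sn <- snps[0, , drop = FALSE]
    sup <- genotype_read(b, seq_of[[rid]], alignments$strand[i], sn)
    v_gene[i] <- gene; v_cov[i] <- cov
    v_a[i] <- sup[["ref"]]; v_b[i] <- sup[["alt"]]
    v_asg[i] <- assign_allele(cov, sup[["ref"]], sup[["alt"]],
                              min_coverage)
  }
  out <- data.frame(
    read_id = alignments$read_id, cell = if (has_cell) alignments$cell
    else NA_character_,
    gene = v_gene, coverage_fraction = v_cov,
    support_a = v_a, support_b = v_b, assignment = v_asg,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per cell x gene counts of A/B assignments from a call table
allelic_counts <- function(calls) {
  assigned <- calls[calls$assignment %in% c("A", "B"), , drop = FALSE]
  key <- paste(assigned$cell, assigned$gene, sep = "\r")
  a <- tapply(assigned$assignment == "A", key, sum)
  b <- tapply(assigned$assignment == "B", key, sum)
  parts <- strsplit(names(a), "\r", fixed = TRUE)
  data.frame(cell = vapply(parts, `[`, character(1), 1),
             gene = vapply(parts, `[`, character(1), 2),
             count_a = as.numeric(a), count_b = as.numeric(b),
             stringsAsFactors = FALSE)
}

#' Average allelic calls from the two reference mappings
#'
#' Per cell and gene, the maternal (strain A) and paternal (strain B)
#' counts are the means of the counts observed under the two reference
#' genomes; fractions are recomputed from the averaged counts. Symmetric
#' in its two arguments and idempotent on identical call sets.
#'
#' @param calls_ref_a,calls_ref_b call tables from [allelic_calls()] under
#'   reference A and reference B (same reads).
#' @return an `allelic_matrix` data.frame: cell, gene, count_a, count_b,
#'   maternal_fraction.
#' @export
dual_map_average <- function(calls_ref_a, calls_ref_b) {
  ca <- allelic_counts(calls_ref_a)
  cb <- allelic_counts(calls_ref_b)
  if (!setequal(unique(ca$cell), unique(cb$cell)))
    stop("cell present in only one mapping")
  key_a <- paste(ca$cell, ca$gene, sep = "\r")
  key_b <- paste(cb$cell, cb$gene, sep = "\r")
  keys <- union(key_a, key_b)
  ia <- match(keys, key_a); ib <- match(keys, key_b)
  count_a <- (ifelse(is.na(ia), 0, ca$count_a[ia]) +
              ifelse(is.na(ib), 0, cb$count_a[ib])) / 2
  count_b <- (ifelse(is.na(ia), 0, ca$count_b[ia]) +
              ifelse(is.na(ib), 0, cb$count_b[ib])) / 2
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(cell = vapply(parts, `[`, character(1), 1),
                    gene = vapply(parts, `[`, character(1), 2),
                    count_a = count_a, count_b = count_b,
                    maternal_fraction = ifelse(count_a + count_b > 0,
                                               count_a /
                                                 (count_a + count_b), NA),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("allelic_matrix", "data.frame")
  out
}

#' Per-cell allelic summary
#'
#' For every cell: the fraction of expressed transcripts (and genes) that
#' carry at least one exonic strain-discriminating SNP, and the maternal
#' fraction of assigned reads from the averaged counts.
#'
#' @param matrix an `allelic_matrix` from [dual_map_average()].
#' @param expr a `scan_expr` (defines which transcripts/genes are
#'   expressed per cell, raw count > 0).
#' @param index an `annotation_index`.
#' @param snps a `snp_table`.
#' @return data.frame per cell: frac_tx_discriminable,
#'   frac_genes_discriminable, maternal_fraction.
#' @export
allelic_summary <- function(matrix, expr, index, snps) {
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos0 + 1, snps$pos0 + 1))
  ov <- GenomicRanges::findOverlaps(index$exon_gr, snp_gr)
  tx_with_snp <- unique(S4Vectors::mcols(index$exon_gr)$transcript_id[
    S4Vectors::queryHits(ov)])
  gene_with_snp <- unique(S4Vectors::mcols(index$exon_gr)$gene_id[
    S4Vectors::queryHits(ov)])
  cells <- colnames(expr$tx_counts)
  rows <- lapply(cells, function(cell) {
    tx_expr <- rownames(expr$tx_counts)[expr$tx_counts[, cell] > 0]
    g_expr <- rownames(expr$gene_counts)[expr$gene_counts[, cell] > 0]
    m <- matrix[matrix$cell == cell, , drop = FALSE]
    tot_a <- sum(m$count_a); tot_b <- sum(m$count_b)
    data.frame(cell = cell,
               frac_tx_discriminable =
                 if (length(tx_expr) > 0)
                   mean(tx_expr %in% tx_with_snp) else NA,
               frac_genes_discriminable =
                 if (length(g_expr) > 0)
                   mean(g_expr %in% gene_with_snp) else NA,
               maternal_fraction = if (tot_a + tot_b > 0)
                 tot_a / (tot_a + tot_b) else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assignment error rate from known pure-strain cells
#'
#' With cells of known single-strain origin, the error per strain is the
#' fraction of assigned informative reads that went to the wrong strain.
#'
#' @param calls call table (with `cell`) from [allelic_calls()] or the
#'   union of both mappings.
#' @param truth_strain named character: cell -> "A" or "B".
#' @return data.frame per strain: n_assigned, n_wrong, error_rate (NA when
#'   no reads were assigned for a strain).
#' @export
estimate_assignment_error <- function(calls, truth_strain) {
  assigned <- calls[calls$assignment %in% c("A", "B"), , drop = FALSE]
  assigned$truth <- truth_strain[assigned$cell]
  rows <- lapply(c("A", "B"), function(s) {
    sub <- assigned[!is.na(assigned$truth) & assigned$truth == s, ,
                    drop = FALSE]
    n <- nrow(sub)
    wrong <- sum(sub$assignment != s)
    data.frame(strain = s, n_assigned = n, n_wrong = wrong,
               error_rate = if (n > 0) wrong / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
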