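#' Library design for simulated barcoded full-length cDNA reads
#'
#' Describes the amplicon architecture and the cells of a pooled library.
#' The sense amplicon is `anchor + tso_tail + transcript + polyA +
#' rc(barcode) + rc(anchor)`, so on the antisense strand the barcode sits
#' next to the polyT tract, as in first-strand RT priming. Barcodes must be
#' 24 nt, distinct, and pairwise edit distance >= 8.
#'
#' @param barcodes character vector of 24-nt cell barcodes (max 48).
#' @param n_cells number of cells (<= length(barcodes)).
#' @param transcript_ids transcripts available for expression.
#' @param expression transcripts x cells matrix of sampling probabilities;
#'   default uniform. Columns are normalized to sum to 1.
#' @param maternal_fraction scalar or per-cell vector in [0,1].
#' @param anchor shared PCR anchor sequence.
#' @param tso_tail template-switch tail appended to the anchor at the 5'
#'   end of the cDNA.
#' @param polyT_len length of the polyA/polyT tract.
#' @return a `library_design` list.
#' @export
library_design <- function(barcodes, n_cells = length(barcodes),
                           transcript_ids, expression = NULL,
                           maternal_fraction = 0.5,
                           anchor = SCAN_ANCHOR, tso_tail = SCAN_TSO_TAIL,
                           polyT_len = 25) {
  barcodes <- toupper(barcodes)
  if (any(nchar(barcodes) != 24)) stop("all barcodes must be 24 nt")
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct")
  if (length(barcodes) > 48) stop("at most 48 barcodes per library")
  if (n_cells < 1 || n_cells > length(barcodes))
    stop("n_cells must be between 1 and the number of barcodes")
  if (length(barcodes) > 1) {
    d <- utils::adist(barcodes)
    if (min(d[upper.tri(d)]) < 8)
      stop("barcodes must have pairwise edit distance >= 8")
  }
  if (is.null(expression)) {
    expression <- matrix(1 / length(transcript_ids),
                         nrow = length(transcript_ids), ncol = n_cells)
  }
  stopifnot(nrow(expression) == length(transcript_ids),
            ncol(expression) == n_cells)
  expression <- sweep(expression, 2, colSums(expression), "/")
  rownames(expression) <- transcript_ids
  m <- rep_len(maternal_fraction, n_cells)
  stopifnot(all(m >= 0 & m <= 1))
  cells <- data.frame(cell = sprintf("cell%02d", seq_len(n_cells)),
                      barcode_index = seq_len(n_cells),
                      maternal_fraction = m, stringsAsFactors = FALSE)
  colnames(expression) <- cells$cell
  structure(list(anchor = anchor, tso_tail = tso_tail, barcodes = barcodes,
                 polyT_len = polyT_len, cells = cells,
                 expression = expression),
            class = "library_design")
}

#' Default simulated barcode set
#'
#' Deterministic 24-nt barcodes with pairwise edit distance >= 8, generated
#' by rejection sampling under a fixed internal seed.
#'
#' @param n number of barcodes (<= 48).
#' @return character vector of barcodes.
#' @export
default_barcodes <- function(n = 48) {
  stopifnot(n >= 1, n <= 48)
  with_seed(424242L, {
    out <- character(0)
    while (length(out) < 48) {
      cand <- paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE),
                    collapse = "")
      if (length(out) == 0 || min(utils::adist(cand, out)) >= 8)
        out <- c(out, cand)
    }
    out
  })[seq_len(n)]
}

#' Simulator error model
#'
#' Per-base substitution/insertion/deletion probabilities, the probability
#' that a read lacks its TSO end (5' truncation), and the quality rule:
#' error-free bases get Q20, error-injected bases Q7.
#'
#' @param p_sub,p_ins,p_del per-base event probabilities.
#' @param truncation_prob probability a read loses the TSO end.
#' @param q_good,q_bad Phred values for clean and error bases.
#' @return an `error_model` list.
#' @export
error_model <- function(p_sub = 0, p_ins = 0, p_del = 0,
                        truncation_prob = 0, q_good = 20L, q_bad = 7L) {
  stopifnot(p_sub >= 0, p_sub <= 1, p_ins >= 0, p_ins <= 1,
            p_del >= 0, p_del <= 1, truncation_prob >= 0,
            truncation_prob <= 1)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 truncation_prob = truncation_prob,
                 q_good = as.integer(q_good), q_bad = as.integer(q_bad)),
            class = "error_model")
}

#' Generate a toy reference: genome FASTA, GTF annotation, strain SNP VCF
#'
#' Lays multi-exon genes on both strands of one synthetic chromosome with
#' intergenic gaps; genes with >= 3 exons get a second, exon-skipping
#' transcript. Strain-specific SNPs are placed at exonic positions with
#' per-base probability `n_snps_per_kb / 1000` (ALT differs from the genome
#' base). Deterministic given `seed`. The last base of every transcript is
#' forced to a non-A so the genomic 3' end is distinguishable from the
#' simulated polyA tail.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene.
#' @param n_snps_per_kb expected SNPs per kb of exon.
#' @param seed RNG seed.
#' @param out_dir if non-NULL, writes ref.fa, ref.gtf, snps.vcf there.
#' @param exon_len,intron_len,gap_len length ranges (min, max) for exons,
#'   introns and intergenic gaps.
#' @return list with `genome` (DNAStringSet), `index` (annotation_index),
#'   `snps` (snp_table), `chrom_lengths`, and file `paths` when written.
#' @export
make_reference <- function(n_genes = 8, exons_per_gene = 3,
                           n_snps_per_kb = 10, seed = 1, out_dir = NULL,
                           exon_len = c(120, 360), intron_len = c(150, 400),
                           gap_len = c(400, 800)) {
  stopifnot(n_genes >= 1, exons_per_gene >= 1, n_snps_per_kb >= 0)
  with_seed(seed, {
    chrom <- "chrS"
    exon_rows <- list()
    pos <- sample(gap_len[1]:gap_len[2], 1)
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("G%03d", g)
      strand <- if (g %% 2 == 0) "-" else "+"
      starts <- numeric(0); ends <- numeric(0)
      for (e in seq_len(exons_per_gene)) {
        w <- sample(exon_len[1]:exon_len[2], 1)
        starts <- c(starts, pos); ends <- c(ends, pos + w)
        pos <- pos + w + sample(intron_len[1]:intron_len[2], 1)
      }
      pos <- max(ends) + sample(gap_len[1]:gap_len[2], 1)
      tx1 <- sprintf("%s.t1", gene_id)
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        gene_id = gene_id, transcript_id = tx1, chrom = chrom,
        strand = strand, start = starts, end = ends,
        stringsAsFactors = FALSE)
      if (exons_per_gene >= 3 && g %% 2 == 1) {
        # exon-skipping second isoform: drop the middle exon
        keep <- setdiff(seq_len(exons_per_gene),
                        ceiling(exons_per_gene / 2))
        tx2 <- sprintf("%s.t2", gene_id)
        exon_rows[[length(exon_rows) + 1]] <- data.frame(
          gene_id = gene_id, transcript_id = tx2, chrom = chrom,
          strand = strand, start = starts[keep], end = ends[keep],
          stringsAsFactors = FALSE)
      }
    }
    exons <- do.call(rbind, exon_rows)
    chrom_len <- pos + sample(gap_len[1]:gap_len[2], 1)
    genome_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)

    # terminal transcript base must not be A (polyA-tail ambiguity), and
    # SNPs keep away from it so both alleles share that property
    index0 <- annotation_index(exons)
    terminal_pos <- integer(0)
    for (tx in rownames(index0$transcripts)) {
      t <- index0$transcripts[tx, ]
      e <- index0$exons[index0$exons$transcript_id == tx, ]
      last_pos <- if (t$strand == "+") max(e$end) else min(e$start) + 1
      terminal_pos <- c(terminal_pos, last_pos)
      want_not <- if (t$strand == "+") "A" else "T"
      if (genome_chars[last_pos] == want_not)
        genome_chars[last_pos] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 want_not), 1)
    }

    exonic_pos <- sort(unique(unlist(
      lapply(seq_len(nrow(exons)),
             function(i) (exons$start[i] + 1):exons$end[i]))))  # 1-based
    exonic_pos <- setdiff(exonic_pos, terminal_pos)
    p_snp <- n_snps_per_kb / 1000
    hit <- exonic_pos[runif(length(exonic_pos)) < p_snp]
    if (p_snp > 0 && length(exonic_pos) * p_snp >= 1 && length(hit) == 0)
      hit <- sample(exonic_pos, 1)
    snps <- data.frame(chrom = rep(chrom, length(hit)), pos0 = hit - 1,
                       ref = genome_chars[hit],
                       alt = vapply(genome_chars[hit], function(b)
                         sample(setdiff(c("A", "C", "G", "T"), b), 1),
                         character(1)),
                       stringsAsFactors = FALSE)
    rownames(snps) <- NULL
    attr(snps, "n_skipped") <- 0L
    attr(snps, "strains") <- c(ref = "maternal", alt = "paternal")
    class(snps) <- c("snp_table", "data.frame")

    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- chrom
    ref <- list(genome = genome, index = annotation_index(exons),
                snps = snps, chrom_lengths = setNames(chrom_len, chrom))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(fasta = file.path(out_dir, "ref.fa"),
                    gtf = file.path(out_dir, "ref.gtf"),
                    vcf = file.path(out_dir, "snps.vcf"))
      Biostrings::writeXStringSet(genome, paths$fasta)
      write_gtf(ref$index, paths$gtf)
      write_vcf(snps, paths$vcf)
      ref$paths <- paths
    }
    ref
  })
}

# spliced transcript sequence in mRNA sense for one allele
transcript_sequence <- function(ref, tx, allele = c("maternal", "paternal")) {
  allele <- match.arg(allele)
  e <- ref$index$exons[ref$index$exons$transcript_id == tx, ]
  if (nrow(e) == 0) stop(sprintf("unknown transcript '%s'", tx))
  chrom_seq <- ref$genome[[e$chrom[1]]]
  parts <- vapply(seq_len(nrow(e)), function(i)
    as.character(Biostrings::subseq(chrom_seq, e$start[i] + 1, e$end[i])),
    character(1))
  s <- paste(parts, collapse = "")
  if (allele == "paternal" && nrow(ref$snps) > 0) {
    sn <- ref$snps[ref$snps$chrom == e$chrom[1], ]
    if (nrow(sn) > 0) {
      tx_pos <- genomic_to_transcript(sn$pos0, e)
      inside <- !is.na(tx_pos)
      if (any(inside)) {
        chars <- strsplit(s, "")[[1]]
        chars[tx_pos[inside] + 1] <- sn$alt[inside]
        s <- paste(chars, collapse = "")
      }
    }
  }
  strand <- e$strand[1]
  if (strand == "-") s <- revcomp(s)
  s
}

# map genomic pos0 vector into plus-strand spliced transcript coordinates
# (offset within concatenated exons); NA when outside exons
genomic_to_transcript <- function(pos0, exons) {
  offs <- cumsum(c(0, exons$end - exons$start))
  out <- rep(NA_real_, length(pos0))
  for (i in seq_len(nrow(exons))) {
    inside <- pos0 >= exons$start[i] & pos0 < exons$end[i]
    out[inside] <- offs[i] + pos0[inside] - exons$start[i]
  }
  out
}

# genomic blocks of a plus-strand transcript-coordinate interval [from, to)
transcript_interval_blocks <- function(from, to, exons) {
  offs <- cumsum(c(0, exons$end - exons$start))
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_len(nrow(exons))) {
    lo <- max(from, offs[i]); hi <- min(to, offs[i + 1])
    if (lo < hi) {
      starts <- c(starts, exons$start[i] + lo - offs[i])
      ends <- c(ends, exons$start[i] + hi - offs[i])
    }
  }
  cbind(start = starts, end = ends)
}

# apply substitution/insertion/deletion errors to one sequence; returns
# sequence, qualities and the number of injected events of each kind
apply_errors <- function(s, em) {
  n <- nchar(s)
  if (em$p_sub == 0 && em$p_ins == 0 && em$p_del == 0) {
    return(list(seq = s, qual = rep(em$q_good, n),
                n_sub = 0L, n_ins = 0L, n_del = 0L))
  }
  chars <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  del <- runif(n) < em$p_del
  sub <- !del & runif(n) < em$p_sub
  ins_after <- runif(n) < em$p_ins

  keep <- !del
  emit_cum <- cumsum(keep)
  base_out <- chars[keep]
  qual_out <- rep(em$q_good, sum(keep))
  subk <- sub[keep]
  if (any(subk)) {
    # substitute with a uniformly drawn different base
    idx <- match(base_out[subk], bases)
    base_out[subk] <- bases[((idx - 1 +
                              sample.int(3, sum(subk), replace = TRUE)) %%
                             4) + 1]
    qual_out[subk] <- em$q_bad
  }
  ins_pos <- which(ins_after)
  if (length(ins_pos) > 0) {
    ins_chars <- sample(bases, length(ins_pos), replace = TRUE)
    key <- c(seq_along(base_out), emit_cum[ins_pos] + 0.5)
    ord <- order(key)
    base_out <- c(base_out, ins_chars)[ord]
    qual_out <- c(qual_out, rep(em$q_bad, length(ins_pos)))[ord]
  }
  list(seq = paste(base_out, collapse = ""), qual = qual_out,
       n_sub = sum(subk), n_ins = length(ins_pos), n_del = sum(del))
}

#' Synthesize barcoded full-length cDNA reads with truth tables
#'
#' Each read is drawn by sampling a cell (uniform), a transcript (cell's
#' expression vector), an allele (cell's maternal fraction), an amplicon
#' strand (uniform) and an optional 5' truncation, then per-base errors are
#' applied. The truth table carries every latent label; truth alignments
#' give the error-free genomic blocks of the transcript portion.
#'
#' @param ref a reference from [make_reference()].
#' @param design a [library_design()].
#' @param em an [error_model()].
#' @param n_reads number of reads.
#' @param seed RNG seed.
#' @param out_dir if non-NULL, writes reads.fastq, truth.tsv, truth_aln.tsv.
#' @return list with `reads` (read_set), `truth` (data.frame),
#'   `alignments` (alignment_set of the truth blocks), and error-event
#'   totals in `stats`.
#' @export
synthesize_reads <- function(ref, design, em = error_model(), n_reads,
                             seed = 1, out_dir = NULL) {
  tx_ids <- rownames(design$expression)
  stopifnot(all(tx_ids %in% rownames(ref$index$transcripts)))
  with_seed(seed, {
    n_cells <- nrow(design$cells)
    # cache allele-specific transcript sequences
    tx_seq <- list(
      maternal = vapply(tx_ids, transcript_sequence, character(1),
                        ref = ref, allele = "maternal"),
      paternal = vapply(tx_ids, transcript_sequence, character(1),
                        ref = ref, allele = "paternal"))
    exons_of <- split(ref$index$exons, ref$index$exons$transcript_id)
    full_blocks <- vapply(tx_ids, function(tx) {
      e <- exons_of[[tx]]
      format_blocks(list(cbind(start = e$start, end = e$end)))
    }, character(1))
    rc_cache <- paste0(revcomp(design$barcodes[design$cells$barcode_index]),
                       revcomp(design$anchor))
    tso_prefix <- paste0(design$anchor, design$tso_tail)
    polyA <- strrep("A", design$polyT_len)

    v_cell <- character(n_reads); v_tx <- character(n_reads)
    v_allele <- character(n_reads); v_strand <- character(n_reads)
    v_trunc <- logical(n_reads); v_blocks <- character(n_reads)
    seqs <- character(n_reads); quals <- vector("list", n_reads)
    n_sub <- 0L; n_ins <- 0L; n_del <- 0L; n_base <- 0L
    for (i in seq_len(n_reads)) {
      ci <- sample.int(n_cells, 1)
      tx <- sample(tx_ids, 1, prob = design$expression[, ci])
      allele <- if (runif(1) < design$cells$maternal_fraction[ci])
        "maternal" else "paternal"
      t_seq <- tx_seq[[allele]][[tx]]
      truncated <- runif(1) < em$truncation_prob
      exons <- exons_of[[tx]]
      strand_tx <- exons$strand[1]
      tlen <- nchar(t_seq)
      if (truncated) {
        cut <- floor(runif(1, 0, 0.5) * tlen)
        t_seq <- substring(t_seq, cut + 1)
        # mRNA-sense truncation -> plus-strand transcript coords -> blocks
        blocks <- if (strand_tx == "+")
          transcript_interval_blocks(cut, tlen, exons)
        else transcript_interval_blocks(0, tlen - cut, exons)
        v_blocks[i] <- format_blocks(list(blocks))
      } else {
        v_blocks[i] <- full_blocks[[tx]]
      }
      amplicon <- paste0(if (!truncated) tso_prefix else "",
                         t_seq, polyA, rc_cache[ci])
      amp_strand <- if (runif(1) < 0.5) "+" else "-"
      if (amp_strand == "-") amplicon <- revcomp(amplicon)
      errd <- apply_errors(amplicon, em)
      n_sub <- n_sub + errd$n_sub; n_ins <- n_ins + errd$n_ins
      n_del <- n_del + errd$n_del; n_base <- n_base + nchar(amplicon)
      seqs[i] <- errd$seq; quals[[i]] <- errd$qual
      v_cell[i] <- design$cells$cell[ci]; v_tx[i] <- tx
      v_allele[i] <- allele; v_strand[i] <- amp_strand
      v_trunc[i] <- truncated
    }
    chrom_of <- vapply(exons_of, function(e) e$chrom[1], character(1))
    strand_of <- vapply(exons_of, function(e) e$strand[1], character(1))
    truth <- data.frame(
      read_id = sprintf("read%06d", seq_len(n_reads)), cell = v_cell,
      transcript = v_tx, allele = v_allele, strand = v_strand,
      truncated = v_trunc,
      chrom = unname(chrom_of[v_tx]), tx_strand = unname(strand_of[v_tx]),
      blocks = v_blocks, stringsAsFactors = FALSE)
    reads <- read_set(truth$read_id, seqs, quals)
    aln <- data.frame(read_id = truth$read_id, chrom = truth$chrom,
                      strand = truth$tx_strand, blocks = truth$blocks,
                      aligned_base_fraction = rep(1, nrow(truth)),
                      secondary = rep(FALSE, nrow(truth)),
                      cell = truth$cell, stringsAsFactors = FALSE)
    class(aln) <- c("alignment_set", "data.frame")
    out <- list(reads = reads, truth = truth, alignments = aln,
                stats = c(n_sub = n_sub, n_ins = n_ins, n_del = n_del,
                          n_base = n_base))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      out$paths <- list(fastq = file.path(out_dir, "reads.fastq"),
                        truth = file.path(out_dir, "truth.tsv"),
                        truth_aln = file.path(out_dir, "truth_aln.tsv"))
      write_fastq(reads, out$paths$fastq)
      write_truth_tsv(truth, out$paths$truth)
      write_truth_tsv(truth, out$paths$truth_aln)
    }
    out
  })
}

#' Reference with planted novel isoforms, one per structural category
#'
#' Builds a deterministic toy genome whose annotation is laid out so that
#' one unannotated transcript of each category (CJ, CS, ME, IR, MIR) can be
#' transcribed by the simulator: the `index` (used for synthesis) contains
#' both the annotated transcripts and the planted ones; `base_index` (what
#' discovery should be given) contains the annotated transcripts only. An
#' additional multi-exon gene is left out of `base_index` entirely so its
#' reads are intergenic, serving as a planted lncRNA.
#'
#' Layout per host gene (100-bp exons and introns): CJ lives in a five-exon
#' gene with two annotated exon-skipping isoforms and combines the two skip
#' junctions; CS skips the middle exon of a three-exon gene (both splice
#' edges annotated, pairing novel); ME is a mono-exon model inside an
#' annotated exon; IR fuses two exons across their intron; MIR is the same
#' fusion as a single-exon model.
#'
#' @param seed RNG seed for the genome sequence.
#' @param out_dir optional output directory (ref.fa, ref.gtf for the base
#'   annotation).
#' @return list like [make_reference()] (with `index` = augmented) plus
#'   `base_index`, `lnc_index`, and `novel_truth` (data.frame
#'   transcript_id, category, host_gene).
#' @export
make_planted_reference <- function(seed = 1, out_dir = NULL) {
  u <- 100  # exon/intron unit length
  gene_layout <- function(gene_id, offset, n_exons) {
    starts <- offset + (seq_len(n_exons) - 1) * 2 * u
    data.frame(gene_id = gene_id, chrom = "chrP", strand = "+",
               start = starts, end = starts + u, stringsAsFactors = FALSE)
  }
  ex <- function(layout, transcript_id, which_exons) {
    cbind(layout[which_exons, c("gene_id", "chrom", "strand", "start",
                                "end")],
          transcript_id = transcript_id)
  }
  g_cj <- gene_layout("G_CJ", 200, 5)
  g_cs <- gene_layout("G_CS", 2400, 3)
  g_me <- gene_layout("G_ME", 3800, 3)
  g_ir <- gene_layout("G_IR", 5200, 3)
  g_mir <- gene_layout("G_MIR", 6600, 3)
  g_lnc <- gene_layout("G_LNC", 8000, 3)

  base_rows <- rbind(
    ex(g_cj, "G_CJ.t1", 1:5), ex(g_cj, "G_CJ.t2", c(1, 3, 4, 5)),
    ex(g_cj, "G_CJ.t3", c(1, 2, 3, 5)),
    ex(g_cs, "G_CS.t1", 1:3), ex(g_me, "G_ME.t1", 1:3),
    ex(g_ir, "G_IR.t1", 1:3), ex(g_mir, "G_MIR.t1", 1:3))
  lnc_rows <- ex(g_lnc, "G_LNC.t1", 1:3)

  fuse <- function(layout, i, j) {
    # exons i..j fused into one long exon across their introns
    data.frame(gene_id = layout$gene_id[1], chrom = "chrP", strand = "+",
               start = layout$start[i], end = layout$end[j],
               stringsAsFactors = FALSE)
  }
  novel_rows <- rbind(
    cbind(ex(g_cj, "nov_CJ", c(1, 3, 5))[, 1:5], transcript_id = "nov_CJ"),
    cbind(ex(g_cs, "nov_CS", c(1, 3))[, 1:5], transcript_id = "nov_CS"),
    data.frame(gene_id = "G_ME", chrom = "chrP", strand = "+",
               start = g_me$start[2] + 20, end = g_me$end[2] - 20,
               transcript_id = "nov_ME", stringsAsFactors = FALSE),
    rbind(cbind(g_ir[1, c("gene_id", "chrom", "strand", "start", "end")],
                transcript_id = "nov_IR"),
          cbind(fuse(g_ir, 2, 3), transcript_id = "nov_IR")),
    cbind(fuse(g_mir, 2, 3), transcript_id = "nov_MIR"))

  keep_cols <- c("gene_id", "transcript_id", "chrom", "strand", "start",
                 "end")
  base_rows <- base_rows[, keep_cols]
  novel_rows <- novel_rows[, keep_cols]
  lnc_rows <- lnc_rows[, keep_cols]

  chrom_len <- max(g_lnc$end) + 500
  with_seed(seed, {
    genome_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    all_rows <- rbind(base_rows, novel_rows, lnc_rows)
    index <- annotation_index(all_rows)
    # terminal transcript base must not be A (polyA-tail ambiguity)
    for (tx in rownames(index$transcripts)) {
      e <- index$exons[index$exons$transcript_id == tx, ]
      last_pos <- max(e$end)
      if (genome_chars[last_pos] == "A")
        genome_chars[last_pos] <- sample(c("C", "G", "T"), 1)
    }
    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- "chrP"
    snps <- data.frame(chrom = character(0), pos0 = numeric(0),
                       ref = character(0), alt = character(0),
                       stringsAsFactors = FALSE)
    class(snps) <- c("snp_table", "data.frame")
    ref <- list(genome = genome, index = annotation_index(all_rows),
                base_index = annotation_index(base_rows),
                lnc_index = annotation_index(lnc_rows),
                snps = snps, chrom_lengths = c(chrP = chrom_len),
                novel_truth = data.frame(
                  transcript_id = c("nov_CJ", "nov_CS", "nov_ME",
                                    "nov_IR", "nov_MIR"),
                  category = c("CJ", "CS", "ME", "IR", "MIR"),
                  host_gene = c("G_CJ", "G_CS", "G_ME", "G_IR", "G_MIR"),
                  stringsAsFactors = FALSE))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      ref$paths <- list(fasta = file.path(out_dir, "ref.fa"),
                        gtf = file.path(out_dir, "ref.gtf"))
      Biostrings::writeXStringSet(genome, ref$paths$fasta)
      write_gtf(ref$base_index, ref$paths$gtf)
    }
    ref
  })
}

#' Force all cells of a design to a single strain
#'
#' Sets every cell's maternal fraction to 1 ("maternal") or 0 ("paternal");
#' used for assignment-error estimation with known-truth cells.
#'
#' @param design a `library_design`.
#' @param strain "maternal" or "paternal".
#' @return the modified design.
#' @export
make_pure_strain_cells <- function(design, strain = c("maternal",
                                                      "paternal")) {
  strain <- match.arg(strain)
  design$cells$maternal_fraction <- if (strain == "maternal") 1 else 0
  design
}
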