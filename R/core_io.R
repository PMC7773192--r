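#' Read sequences from FASTQ or FASTA
#'
#' Reads a FASTQ (or FASTA) file into a read set: parallel vectors of read
#' ids, sequences, per-base Phred qualities and the Phred-scaled mean error
#' probability per read. FASTA records carry no qualities and an undefined
#' (NA) mean qscore.
#'
#' @param path file path.
#' @param format "auto" (by extension), "fastq" or "fasta".
#' @return an object of class `read_set`: a list with character vectors
#'   `read_id` and `sequence`, a list `qualities` of integer vectors (NULL
#'   elements for FASTA), and numeric `mean_q`.
#' @export
read_sequences <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "fastq"
  }
  if (format == "fastq") {
    # structural pre-check (the parser silently truncates mismatched
    # quality strings): canonical 4-line records, equal seq/qual lengths
    lines <- readLines(path)
    if (length(lines) %% 4 != 0)
      stop(sprintf("truncated FASTQ record near line %d",
                   4 * (length(lines) %/% 4) + 1))
    if (length(lines) > 0) {
      slen0 <- nchar(lines[seq(2, length(lines), by = 4)])
      qlen0 <- nchar(lines[seq(4, length(lines), by = 4)])
      bad <- which(slen0 != qlen0)
      if (length(bad) > 0)
        stop(sprintf(
          "FASTQ record at line %d: %d bases but %d quality symbols",
          (bad[1] - 1) * 4 + 1, slen0[bad[1]], qlen0[bad[1]]))
    }
    seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
    quals_raw <- S4Vectors::mcols(seqs)$qualities
    quals <- as.list(as(Biostrings::PhredQuality(quals_raw), "IntegerList"))
    mean_q <- vapply(quals, function(q) {
      if (length(q) == 0) NA_real_ else mean_qscore(q)
    }, numeric(1))
  } else {
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    quals <- vector("list", length(seqs))
    mean_q <- rep(NA_real_, length(seqs))
  }
  ids <- sub("[ \t].*$", "", names(seqs))
  read_set(ids, as.character(seqs), quals, mean_q)
}

#' Construct a read set
#'
#' @param read_id,sequence character vectors of equal length.
#' @param qualities list of integer Phred vectors (or NULL elements).
#' @param mean_q optional precomputed mean qscores; computed when missing.
#' @return a `read_set`.
#' @export
read_set <- function(read_id, sequence, qualities = NULL, mean_q = NULL) {
  n <- length(read_id)
  stopifnot(length(sequence) == n)
  if (is.null(qualities)) qualities <- vector("list", n)
  lens_ok <- vapply(seq_len(n), function(i) {
    is.null(qualities[[i]]) || length(qualities[[i]]) == nchar(sequence[i])
  }, logical(1))
  if (!all(lens_ok)) {
    stop(sprintf("read '%s': sequence and quality lengths differ",
                 read_id[which(!lens_ok)[1]]))
  }
  if (is.null(mean_q)) {
    mean_q <- vapply(seq_len(n), function(i) {
      q <- qualities[[i]]
      if (is.null(q) || length(q) == 0) NA_real_ else mean_qscore(q)
    }, numeric(1))
  }
  structure(list(read_id = as.character(read_id),
                 sequence = as.character(sequence),
                 qualities = qualities, mean_q = mean_q),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$read_id)

#' Subset a read set
#' @param x a `read_set`.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.read_set` <- function(x, i, ...) {
  read_set(x$read_id[i], x$sequence[i], x$qualities[i], x$mean_q[i])
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d reads\n", length(x)))
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' Inverse of [read_sequences()]: writes canonical 4-line FASTQ records
#' (Phred+33). Reads without qualities are refused.
#'
#' @param reads a `read_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  if (n > 0 && any(vapply(reads$qualities, is.null, logical(1))))
    stop("cannot write FASTQ: some reads carry no qualities")
  con <- file(path, "wb")
  on.exit(close(con))
  if (n == 0) return(invisible(path))
  qual_str <- vapply(reads$qualities, function(q)
    rawToChar(as.raw(pmin(q, 93L) + 33L)), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual_str))
  writeLines(lines, con)
  invisible(path)
}

#' Phred-scaled mean error probability of a quality vector
#'
#' Converts per-base Phred scores to error probabilities, averages them and
#' transforms back: `-10 * log10(mean(10^(-q/10)))`. This is the standard
#' long-read "qscore" (the Phred of the mean error, not the mean Phred).
#'
#' @param qualities integer/numeric vector of per-base Phred scores.
#' @return a single Phred value.
#' @export
mean_qscore <- function(qualities) {
  if (length(qualities) == 0) stop("mean_qscore: empty quality vector")
  -10 * log10(mean(10^(-qualities / 10)))
}

#' Build an annotation index from an exon table
#'
#' The exon table uses internal 0-based half-open coordinates. Exons within
#' a transcript must be disjoint, non-abutting and are sorted by start.
#' Derived lookups: per-transcript junction chains, per-(chrom,strand)
#' annotated splice-edge sets, junction ownership, exon and gene-span
#' interval trees.
#'
#' @param exons data.frame with columns gene_id, transcript_id, chrom,
#'   strand, start, end (0-based half-open).
#' @return an `annotation_index`.
#' @export
annotation_index <- function(exons) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(exons)))
  exons <- exons[order(exons$transcript_id, exons$start), need]
  if (nrow(exons) == 0) {
    empty_tx <- data.frame(transcript_id = character(0),
                           gene_id = character(0), chrom = character(0),
                           strand = character(0), start = numeric(0),
                           end = numeric(0), n_exons = integer(0),
                           spliced_length = numeric(0))
    empty_genes <- empty_tx[c("gene_id", "chrom", "strand", "start", "end")]
    empty_jx <- data.frame(chrom = character(0), strand = character(0),
                           donor = numeric(0), acceptor = numeric(0),
                           transcript_id = character(0),
                           gene_id = character(0))
    return(structure(list(exons = exons, transcripts = empty_tx,
                          genes = empty_genes, chains = list(),
                          junctions = empty_jx,
                          splice_left = character(0),
                          splice_right = character(0),
                          junction_keys = character(0),
                          exon_gr = GenomicRanges::GRanges(),
                          gene_gr = GenomicRanges::GRanges()),
                     class = "annotation_index"))
  }
  if (any(is.na(exons$transcript_id)) || any(exons$transcript_id == ""))
    stop("exon without transcript_id")
  if (any(exons$end <= exons$start)) stop("exon with non-positive width")

  ex_by_tx <- split(exons, exons$transcript_id)
  for (tx in names(ex_by_tx)) {
    e <- ex_by_tx[[tx]]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop(sprintf("transcript '%s': overlapping or abutting exons", tx))
  }

  transcripts <- do.call(rbind, lapply(ex_by_tx, function(e) {
    data.frame(transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
               chrom = e$chrom[1], strand = e$strand[1],
               start = min(e$start), end = max(e$end),
               n_exons = nrow(e),
               spliced_length = sum(e$end - e$start),
               stringsAsFactors = FALSE)
  }))
  rownames(transcripts) <- transcripts$transcript_id

  chains <- lapply(ex_by_tx, function(e)
    blocks_to_chain(cbind(start = e$start, end = e$end)))

  junctions <- do.call(rbind, lapply(names(chains), function(tx) {
    ch <- chains[[tx]]
    if (nrow(ch) == 0) return(NULL)
    data.frame(chrom = transcripts[tx, "chrom"],
               strand = transcripts[tx, "strand"],
               donor = ch[, 1], acceptor = ch[, 2], transcript_id = tx,
               gene_id = transcripts[tx, "gene_id"], stringsAsFactors = FALSE)
  }))
  if (is.null(junctions))
    junctions <- data.frame(chrom = character(0), strand = character(0),
                            donor = numeric(0), acceptor = numeric(0),
                            transcript_id = character(0),
                            gene_id = character(0))

  genes <- do.call(rbind, lapply(split(transcripts, transcripts$gene_id),
    function(t) data.frame(gene_id = t$gene_id[1], chrom = t$chrom[1],
                           strand = t$strand[1], start = min(t$start),
                           end = max(t$end), stringsAsFactors = FALSE)))
  rownames(genes) <- genes$gene_id

  # splice edges keyed genomically: left edge = block end, right edge = start
  ss_key <- function(chrom, strand, pos) paste(chrom, strand, pos, sep = ":")
  splice_left <- unique(ss_key(junctions$chrom, junctions$strand,
                               junctions$donor))
  splice_right <- unique(ss_key(junctions$chrom, junctions$strand,
                                junctions$acceptor))
  junction_keys <- unique(paste(junctions$chrom, junctions$strand,
                                junctions$donor, junctions$acceptor,
                                sep = ":"))

  exon_gr <- GenomicRanges::GRanges(
    exons$chrom,
    IRanges::IRanges(exons$start + 1, exons$end), strand = exons$strand,
    gene_id = exons$gene_id, transcript_id = exons$transcript_id)
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end),
    strand = genes$strand, gene_id = genes$gene_id)

  structure(list(exons = exons, transcripts = transcripts, genes = genes,
                 chains = chains, junctions = junctions,
                 splice_left = splice_left, splice_right = splice_right,
                 junction_keys = junction_keys,
                 exon_gr = exon_gr, gene_gr = gene_gr),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Load a GTF annotation into an annotation index
#'
#' GTF coordinates (1-based inclusive) are shifted to the internal 0-based
#' half-open convention: start0 = start - 1, end0 = end.
#'
#' @param gtf_path path to a GTF file with gene_id/transcript_id attributes.
#' @return an `annotation_index`.
#' @export
load_annotation <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("GTF contains no exon records")
  if (any(is.na(gr$transcript_id))) stop("exon without transcript_id")
  annotation_index(data.frame(
    gene_id = gr$gene_id, transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1, end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Write an annotation index (or model table) as GTF
#'
#' @param index an `annotation_index`.
#' @param path output path.
#' @param source source field for the GTF records.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(index, path, source = "scanlong") {
  e <- index$exons
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                      e$gene_id, e$transcript_id)
  lines <- paste(e$chrom, source, "exon", e$start + 1, e$end, ".",
                 e$strand, ".", attr_str, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Intergenic intervals of an annotation index
#'
#' Complement of the gene spans, per chromosome, over `[0, chrom_length)`.
#'
#' @param index an `annotation_index`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data.frame chrom/start/end (0-based half-open).
#' @export
intergenic_intervals <- function(index, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(ch) {
    g <- index$genes[index$genes$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1, chrom_lengths[[ch]]), ir)
    if (length(gaps) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(gaps) - 1,
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  out
}

#' Load spliced alignments
#'
#' Supported dialects: BAM/SAM (CIGAR N ops define the spliced blocks), PAF
#' (cg:Z CIGAR tag when present), and the simulator's truth TSV. Returns one
#' record per alignment with blocks in 0-based half-open coordinates;
#' secondary and supplementary records are flagged and excluded by default.
#'
#' @param path input file.
#' @param dialect "auto" (by extension), "bam", "sam", "paf" or "tsv".
#' @param keep_secondary keep secondary/supplementary alignments
#'   (flagged in the `secondary` column) instead of dropping them.
#' @return an `alignment_set` data.frame: read_id, chrom, strand, blocks
#'   (encoded "start-end;..."), aligned_base_fraction, secondary; plus a
#'   `stats` attribute with unmapped/secondary counts.
#' @export
load_alignments <- function(path, dialect = c("auto", "bam", "sam", "paf",
                                              "tsv"),
                            keep_secondary = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
                      bam = "bam", sam = "sam", paf = "paf", "tsv")
  }
  if (dialect == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    return(load_alignments(bam, "bam", keep_secondary))
  }
  if (dialect == "bam") {
    ga <- GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
    flag <- S4Vectors::mcols(ga)$flag
    secondary <- bitwAnd(flag, 256L) > 0 | bitwAnd(flag, 2048L) > 0
    grl <- GenomicAlignments::grglist(ga)
    blocks <- format_blocks(lapply(seq_along(grl), function(i) {
      r <- grl[[i]]
      cbind(start = GenomicRanges::start(r) - 1, end = GenomicRanges::end(r))
    }))
    qlen <- GenomicAlignments::qwidth(ga) +
      GenomicAlignments::cigarOpTable(
        GenomicAlignments::cigar(ga))[, "H", drop = TRUE]
    aligned <- GenomicAlignments::cigarOpTable(
      GenomicAlignments::cigar(ga))[, "M", drop = TRUE]
    count <- Rsamtools::countBam(path)
    df <- data.frame(read_id = S4Vectors::mcols(ga)$qname,
                     chrom = as.character(GenomicAlignments::seqnames(ga)),
                     strand = as.character(GenomicAlignments::strand(ga)),
                     blocks = blocks,
                     aligned_base_fraction = pmin(aligned / qlen, 1),
                     secondary = secondary, stringsAsFactors = FALSE)
    stats <- c(total = count$records, mapped = nrow(df),
               unmapped = count$records - nrow(df),
               secondary = sum(secondary))
  } else if (dialect == "paf") {
    raw <- readLines(path)
    if (length(raw) == 0) {
      df <- empty_alignment_df()
      stats <- c(total = 0, mapped = 0, unmapped = 0, secondary = 0)
    } else {
      fields <- strsplit(raw, "\t", fixed = TRUE)
      df <- do.call(rbind, lapply(fields, function(f) {
        tstart <- as.numeric(f[8])
        cg <- grep("^cg:Z:", f, value = TRUE)
        blocks <- if (length(cg) == 1) {
          cigar_blocks(sub("^cg:Z:", "", cg[1]), tstart)
        } else cbind(start = tstart, end = as.numeric(f[9]))
        tp <- grep("^tp:A:", f, value = TRUE)
        data.frame(read_id = f[1], chrom = f[6], strand = f[5],
                   blocks = format_blocks(list(blocks)),
                   aligned_base_fraction =
                     (as.numeric(f[4]) - as.numeric(f[3])) / as.numeric(f[2]),
                   secondary = length(tp) == 1 &&
                     sub("^tp:A:", "", tp[1]) != "P",
                   stringsAsFactors = FALSE)
      }))
      stats <- c(total = nrow(df), mapped = nrow(df), unmapped = 0,
                 secondary = sum(df$secondary))
    }
  } else {  # truth TSV
    df <- read_truth_tsv(path)
    # the transcript strand is the alignment strand; the `strand` column
    # records which amplicon strand was sequenced
    aln_strand <- if ("tx_strand" %in% names(df)) df$tx_strand
    else df$strand
    df <- data.frame(read_id = df$read_id, chrom = df$chrom,
                     strand = aln_strand, blocks = df$blocks,
                     aligned_base_fraction = 1, secondary = FALSE,
                     cell = df$cell, stringsAsFactors = FALSE)
    stats <- c(total = nrow(df), mapped = nrow(df), unmapped = 0,
               secondary = 0)
  }
  if (!keep_secondary) df <- df[!df$secondary, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "stats") <- stats
  class(df) <- c("alignment_set", "data.frame")
  df
}

empty_alignment_df <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             strand = character(0), blocks = character(0),
             aligned_base_fraction = numeric(0), secondary = logical(0),
             stringsAsFactors = FALSE)
}

# reference-space blocks from a CIGAR string; N splits blocks,
# M/D/=/X consume reference within a block.
cigar_blocks <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.numeric(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  starts <- numeric(0); ends <- numeric(0)
  cur_start <- pos0; cur <- pos0
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "D", "=", "X")) {
      cur <- cur + n[i]
    } else if (op[i] == "N") {
      starts <- c(starts, cur_start); ends <- c(ends, cur)
      cur <- cur + n[i]; cur_start <- cur
    }
  }
  starts <- c(starts, cur_start); ends <- c(ends, cur)
  cbind(start = starts, end = ends)
}

#' Load biallelic substitution SNPs from a VCF
#'
#' Keeps single-base substitutions only; indels and multiallelic records are
#' skipped and counted. Positions are shifted to 0-based. Unsorted input is
#' sorted with a message; duplicated positions are an error.
#'
#' @param vcf_path path to a VCF file.
#' @param strains length-2 character vector naming the ref- and alt-carrying
#'   strains.
#' @return a `snp_table` data.frame: chrom, pos0, ref, alt; attribute
#'   `n_skipped` counts dropped records.
#' @export
load_snps <- function(vcf_path, strains = c(ref = "strainA", alt = "strainB")) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    df <- data.frame(chrom = character(0), pos0 = numeric(0),
                     ref = character(0), alt = character(0),
                     stringsAsFactors = FALSE)
    attr(df, "n_skipped") <- 0L
    attr(df, "strains") <- strains
    class(df) <- c("snp_table", "data.frame")
    return(df)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, character(1), 1)
  pos <- as.numeric(vapply(f, `[`, character(1), 2))
  ref <- vapply(f, `[`, character(1), 4)
  alt <- vapply(f, `[`, character(1), 5)
  keep <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  df <- data.frame(chrom = chrom[keep], pos0 = pos[keep] - 1,
                   ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$pos0)
  if (is.unsorted(ord)) {
    message("load_snps: input not coordinate-sorted; sorting")
  }
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(paste(df$chrom, df$pos0))
  if (any(dup)) {
    stop(sprintf("duplicate SNP position %s:%d", df$chrom[dup][1],
                 df$pos0[dup][1] + 1))
  }
  rownames(df) <- NULL
  attr(df, "n_skipped") <- n_skipped
  attr(df, "strains") <- strains
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Write a SNP table as a minimal VCF
#'
#' @param snps a `snp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path) {
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps) == 0) character(0) else
    paste(snps$chrom, snps$pos0 + 1, ".", snps$ref, snps$alt, ".", "PASS",
          ".", sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write/read the simulator truth table
#'
#' Tab-separated columns: read_id, cell, transcript, allele, strand,
#' truncated, chrom, blocks ("start-end;...", 0-based half-open).
#'
#' @param truth data.frame of truth rows.
#' @param path file path.
#' @return `path` (writer) or the truth data.frame (reader).
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE)
}
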