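#' Semi-global barcode alignment score
#'
#' Scores a 24-nt barcode against a read-end window: the barcode is aligned
#' end-to-end, the window contributes free overhangs (semi-global). Scoring:
#' match +2, mismatch -2, gap open -3, gap extend -1 (gap of length k costs
#' open + (k-1)*extend). The reported score is the maximum over the window
#' and its reverse complement, so an exact barcode hit scores 48 and each
#' substitution costs 4; the assignment cutoff of 31 therefore tolerates
#' about 4 substitutions.
#'
#' @param window DNA string (read end window), or character vector.
#' @param barcode 24-nt DNA string.
#' @param scoring list with match, mismatch, gap_open, gap_extend.
#' @return integer score(s), one per window.
#' @export
score_barcode <- function(window, barcode,
                          scoring = list(match = 2, mismatch = -2,
                                         gap_open = 3, gap_extend = 1)) {
  if (nchar(barcode) != 24) stop("barcode must be 24 nt")
  if (any(nchar(window) == 0)) stop("window must be non-empty")
  fw <- cpp_semiglobal_scores(window, c(barcode, revcomp(barcode)),
                              scoring$match, scoring$mismatch,
                              scoring$gap_open, scoring$gap_extend)
  as.integer(pmax(fw[, 1], fw[, 2]))
}

#' Demultiplex reads by barcode alignment scoring
#'
#' Extracts the first and last `window` bases of each read (the whole read
#' when shorter), scores every barcode against both windows on both strands,
#' and assigns each read to the cell with the highest score when that score
#' is at least `cutoff` and uniquely the maximum. Ties and sub-cutoff bests
#' are left unassigned with a reason.
#'
#' @param reads a `read_set`.
#' @param barcodes character vector of 24-nt barcodes.
#' @param cutoff minimum acceptable best score (default 31; a best score of
#'   exactly 31 is assigned, scores below 31 are discarded).
#' @param window window size taken from each read end (default 150).
#' @param scoring see [score_barcode()].
#' @return data.frame: read_id, barcode_index (NA if unassigned),
#'   best_score, runner_up_score, reason (assigned/below_cutoff/tie).
#' @export
demultiplex <- function(reads, barcodes, cutoff = 31, window = 150,
                        scoring = list(match = 2, mismatch = -2,
                                       gap_open = 3, gap_extend = 1)) {
  stopifnot(length(barcodes) >= 1)
  if (any(nchar(barcodes) != 24)) stop("barcodes must be 24 nt")
  n <- length(reads)
  if (n == 0) {
    return(data.frame(read_id = character(0), barcode_index = integer(0),
                      best_score = integer(0), runner_up_score = integer(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  len <- nchar(reads$sequence)
  w <- pmin(window, len)
  head_w <- substr(reads$sequence, 1, w)
  tail_w <- substr(reads$sequence, len - w + 1, len)
  # scoring is strand-symmetric: score(bc, rc(win)) == score(rc(bc), win),
  # so scoring both barcode orientations covers both window strands
  pats <- c(barcodes, revcomp(barcodes))
  sc <- pmax(
    cpp_semiglobal_scores(head_w, pats, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend),
    cpp_semiglobal_scores(tail_w, pats, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend))
  nb <- length(barcodes)
  per_bc <- pmax(sc[, seq_len(nb), drop = FALSE],
                 sc[, nb + seq_len(nb), drop = FALSE])
  best_idx <- max.col(per_bc, ties.method = "first")
  best <- per_bc[cbind(seq_len(n), best_idx)]
  runner <- vapply(seq_len(n), function(i) {
    if (nb == 1) return(-Inf)
    max(per_bc[i, -best_idx[i]])
  }, numeric(1))
  tie <- runner == best
  reason <- ifelse(best < cutoff, "below_cutoff",
                   ifelse(tie, "tie", "assigned"))
  data.frame(read_id = reads$read_id,
             barcode_index = ifelse(reason == "assigned", best_idx,
                                    NA_integer_),
             best_score = as.integer(best),
             runner_up_score = ifelse(is.finite(runner),
                                      as.integer(runner), NA_integer_),
             reason = reason, stringsAsFactors = FALSE)
}

#' Quality and length read filters
#'
#' Discards reads with mean qscore below `min_q` or length below `min_len`;
#' both thresholds are strict "less than" exclusions, so equality passes.
#'
#' @param reads a `read_set`.
#' @param min_q minimum mean qscore (default 7).
#' @param min_len minimum read length in bases (default 100).
#' @return list with `kept` (read_set) and `stats` (named counts: input,
#'   kept, low_quality, short).
#' @export
filter_reads <- function(reads, min_q = 7, min_len = 100) {
  len <- nchar(reads$sequence)
  q <- reads$mean_q
  low_q <- !is.na(q) & q < min_q
  short <- !low_q & len < min_len
  keep <- !low_q & !short
  list(kept = reads[keep],
       stats = c(input = length(reads), kept = sum(keep),
                 low_quality = sum(low_q), short = sum(short)))
}

# find anchor hits (edit distance <= max_edits) in both orientations.
# Returns data.frame start/end (1-based inclusive within the read) and
# orientation ("F" = anchor as given, "R" = its reverse complement).
anchor_hits <- function(sequence, anchor, max_edits = 5) {
  subj <- Biostrings::DNAString(sequence)
  out <- list()
  for (orient in c("F", "R")) {
    pat <- if (orient == "F") anchor else revcomp(anchor)
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_edits,
                                  with.indels = TRUE)
    if (length(m) > 0) {
      out[[orient]] <- data.frame(start = Biostrings::start(m),
                                  end = Biostrings::end(m),
                                  orientation = orient,
                                  stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(start = integer(0), end = integer(0),
                     orientation = character(0), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(df$start), , drop = FALSE]
}

# longest pure run of `base` inside a window; returns start/length or NULL
find_run <- function(sequence, base, min_len) {
  pat <- sprintf("%s{%d,}", base, min_len)
  m <- gregexpr(pat, sequence)[[1]]
  if (m[1] == -1) return(NULL)
  len <- attr(m, "match.length")
  i <- which.max(len)
  list(start = as.integer(m[i]), length = as.integer(len[i]))
}

# error-tolerant homopolymer signal: start positions of every sliding
# window of `win` bases with `base` content >= min_frac (empty if none)
find_tail_signal <- function(sequence, base, win = 15, min_frac = 0.75) {
  n <- nchar(sequence)
  if (n < win) return(integer(0))
  is_b <- as.integer(strsplit(sequence, "")[[1]] == base)
  cs <- cumsum(c(0, is_b))
  frac <- (cs[(win + 1):(n + 1)] - cs[1:(n - win + 1)]) / win
  which(frac >= min_frac)
}

#' Locate the full-length cDNA architecture within a read
#'
#' Finds ISPCR anchor occurrences (alignment with at most `max_edits` edits
#' over the 25-nt anchor) in both orientations, then decides which read end
#' is the TSO (mRNA 5') end and which is the RT end. The RT end requires a
#' polyT (read starts with anchor+barcode+polyT) or polyA (read ends with
#' polyA+rc(barcode)+rc(anchor)) run of at least `min_tail_run` bases near
#' the barcode position; the anchor+ATGGG TSO tail is treated as optional
#' evidence. Reads with anchor hits away from both ends are chimeric.
#'
#' @param read a single-read `read_set` slice or a list with `sequence`.
#' @param design a `library_design` (anchor, tso_tail, polyT_len).
#' @param max_edits edit threshold for an anchor hit (default 5).
#' @param end_margin how far from a read end an anchor hit may start and
#'   still count as terminal (default 100).
#' @param min_tail_run minimum polyA/polyT run length (default 15).
#' @param tail_gap max distance between the run and the barcode (default 10).
#' @return a `read_structure` list: tso_end, rt_end (NULL or list(side,
#'   anchor_start, anchor_end)), internal_anchor_hits, klass in
#'   {full_length, tso_only, polyT_only, none, chimeric}.
#' @export
find_structure <- function(read, design, max_edits = 5, end_margin = 100,
                           min_tail_run = 15, tail_gap = 10) {
  s <- if (is.character(read)) read else read$sequence[1]
  L <- nchar(s)
  hits <- anchor_hits(s, design$anchor, max_edits)
  alen <- nchar(design$anchor)
  bc_len <- 24
  at_start <- hits$start <= end_margin
  at_end <- hits$end >= L - end_margin + 1
  internal <- sum(!at_start & !at_end)

  start_hit <- hits[at_start & hits$orientation == "F", , drop = FALSE]
  end_hit <- hits[at_end & hits$orientation == "R", , drop = FALSE]

  tso_end <- NULL; rt_end <- NULL
  if (nrow(start_hit) > 0) {
    h <- start_hit[1, ]
    # RT at start (antisense read): anchor + barcode + polyT
    zone <- substr(s, h$end + 1,
                   min(L, h$end + bc_len + tail_gap + min_tail_run + 10))
    hits_t <- find_tail_signal(zone, "T", min_tail_run)
    if (any(hits_t <= bc_len + tail_gap + 1)) {
      rt_end <- list(side = "start", anchor_start = h$start,
                     anchor_end = h$end)
    } else {
      tso_end <- list(side = "start", anchor_start = h$start,
                      anchor_end = h$end)
    }
  }
  if (nrow(end_hit) > 0) {
    h <- end_hit[nrow(end_hit), ]
    # RT at end (sense read): polyA + rc(barcode) + rc(anchor)
    zone_start <- max(1, h$start - bc_len - tail_gap - min_tail_run - 10)
    zone <- substr(s, zone_start, h$start - 1)
    hits_a <- find_tail_signal(zone, "A", min_tail_run)
    has_rt <- any((nchar(zone) - (hits_a + min_tail_run - 1)) <=
                    bc_len + tail_gap)
    if (has_rt && is.null(rt_end)) {
      rt_end <- list(side = "end", anchor_start = h$start,
                     anchor_end = h$end)
    } else if (is.null(tso_end)) {
      tso_end <- list(side = "end", anchor_start = h$start,
                      anchor_end = h$end)
    }
  }
  klass <- if (internal >= 1) "chimeric"
  else if (!is.null(tso_end) && !is.null(rt_end) &&
           tso_end$side != rt_end$side) "full_length"
  else if (!is.null(tso_end)) "tso_only"
  else if (!is.null(rt_end)) "polyT_only"
  else "none"
  structure(list(tso_end = tso_end, rt_end = rt_end,
                 internal_anchor_hits = internal, klass = klass),
            class = "read_structure")
}

#' Orient and trim a full-length read to mRNA sense
#'
#' Reverse-complements the read if needed so the TSO end is 5', then strips
#' the 5' anchor (+ATGGG tail when present) and everything from the start
#' of the 3' polyA tract onwards (tail, reverse-complemented barcode and
#' anchor). The transcribed strand records the orientation of the original
#' read: "+" when no flip was needed.
#'
#' @param read single-read `read_set` slice.
#' @param structure result of [find_structure()] for this read.
#' @param design a `library_design`.
#' @param cell optional cell label to attach.
#' @return list: read_id, cell, sequence (mRNA sense, trimmed), qualities,
#'   transcribed_strand.
#' @export
orient_and_trim <- function(read, structure, design, cell = NA_character_) {
  if (structure$klass != "full_length")
    stop("orient_and_trim requires a full_length read")
  s <- read$sequence[1]
  q <- read$qualities[[1]]
  flipped <- structure$rt_end$side == "start"
  if (flipped) {
    L0 <- nchar(s)
    s <- revcomp(s)
    if (!is.null(q)) q <- rev(q)
    flip_end <- function(e) list(
      side = if (e$side == "start") "end" else "start",
      anchor_start = L0 - e$anchor_end + 1,
      anchor_end = L0 - e$anchor_start + 1)
    structure$tso_end <- flip_end(structure$tso_end)
    structure$rt_end <- flip_end(structure$rt_end)
  }
  L <- nchar(s)
  # 5' trim: anchor end, plus the TSO tail when it follows within 1 edit
  cut5 <- structure$tso_end$anchor_end
  tail_len <- nchar(design$tso_tail)
  cand <- substr(s, cut5 + 1, cut5 + tail_len)
  if (nchar(cand) == tail_len &&
      utils::adist(cand, design$tso_tail) <= 1) cut5 <- cut5 + tail_len
  # 3' trim: start of the longest polyA run preceding rc(barcode)+rc(anchor);
  # under sequencing errors the run may be interrupted, leaving tail remnants
  zone_start <- max(1, structure$rt_end$anchor_start - 24 - 60)
  zone <- substr(s, zone_start, structure$rt_end$anchor_start - 1)
  run <- find_run(zone, "A", 8)
  cut3 <- if (is.null(run)) max(structure$rt_end$anchor_start - 25, cut5 + 1)
  else zone_start + run$start - 2
  if (cut3 < cut5 + 1) stop("degenerate full-length read: empty insert")
  list(read_id = read$read_id[1], cell = cell,
       sequence = substr(s, cut5 + 1, cut3),
       qualities = if (!is.null(q)) q[(cut5 + 1):cut3],
       transcribed_strand = if (flipped) "-" else "+")
}

#' Per-cell quality control
#'
#' A cell passes when it has at least `min_reads` full-length reads, a base
#' mapping ratio of at least `min_ratio`, and at least `min_genes` detected
#' genes. All three paper thresholds are strict "less than" exclusions, so
#' equality passes.
#'
#' @param n_full_length_reads number of full-length reads in the cell.
#' @param alignments the cell's `alignment_set` (aligned_base_fraction is
#'   averaged weight-free over records), or a precomputed ratio via
#'   `base_mapping_ratio`.
#' @param gene_counts named numeric vector of per-gene raw counts.
#' @param min_reads,min_ratio,min_genes thresholds (defaults 100000, 0.85,
#'   3000).
#' @param base_mapping_ratio optional precomputed aligned-bases ratio.
#' @return data.frame row: n_full_length_reads, base_mapping_ratio,
#'   n_detected_genes, pass.
#' @export
compute_cell_qc <- function(n_full_length_reads, alignments = NULL,
                            gene_counts = numeric(0), min_reads = 100000,
                            min_ratio = 0.85, min_genes = 3000,
                            base_mapping_ratio = NULL) {
  if (is.null(base_mapping_ratio)) {
    base_mapping_ratio <- if (is.null(alignments) || nrow(alignments) == 0)
      0 else mean(alignments$aligned_base_fraction)
  }
  n_genes <- sum(gene_counts > 0)
  data.frame(n_full_length_reads = n_full_length_reads,
             base_mapping_ratio = base_mapping_ratio,
             n_detected_genes = n_genes,
             pass = n_full_length_reads >= min_reads &
               base_mapping_ratio >= min_ratio & n_genes >= min_genes)
}

#' Binned read-length histogram
#'
#' @param reads a `read_set` or numeric vector of lengths.
#' @param width bin width in bases (default 100).
#' @return data.frame bin_start, bin_end, count (empty bins omitted).
#' @export
length_histogram <- function(reads, width = 100) {
  len <- if (is.numeric(reads)) reads else nchar(reads$sequence)
  if (length(len) == 0)
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0)))
  bin <- floor(len / width)
  tab <- table(bin)
  data.frame(bin_start = as.numeric(names(tab)) * width,
             bin_end = (as.numeric(names(tab)) + 1) * width,
             count = as.integer(tab))
}

#' Run demultiplexing, filtering and full-length extraction on a read set
#'
#' Convenience pipeline: read filters, barcode assignment, structure
#' detection and orientation/trimming, returning per-cell full-length
#' reads plus per-read bookkeeping.
#'
#' @param reads a `read_set`.
#' @param design a `library_design`.
#' @param cutoff,window demultiplexing parameters.
#' @param min_q,min_len read filter parameters.
#' @return list: `full_length` (data.frame read_id, cell, sequence,
#'   transcribed_strand), `assignments`, `structures` (klass per read),
#'   `filter_stats`.
#' @export
extract_full_length <- function(reads, design, cutoff = 31, window = 150,
                                min_q = 7, min_len = 100) {
  flt <- filter_reads(reads, min_q, min_len)
  kept <- flt$kept
  asg <- demultiplex(kept, design$barcodes, cutoff, window)
  klass <- character(length(kept))
  rows <- list()
  for (i in seq_len(length(kept))) {
    st <- find_structure(kept$sequence[i], design)
    klass[i] <- st$klass
    if (st$klass == "full_length" && asg$reason[i] == "assigned") {
      cell <- design$cells$cell[match(asg$barcode_index[i],
                                      design$cells$barcode_index)]
      if (is.na(cell)) next
      ot <- orient_and_trim(kept[i], st, design, cell)
      rows[[length(rows) + 1]] <- data.frame(
        read_id = ot$read_id, cell = ot$cell, sequence = ot$sequence,
        transcribed_strand = ot$transcribed_strand,
        stringsAsFactors = FALSE)
    }
  }
  fl <- do.call(rbind, rows)
  if (is.null(fl))
    fl <- data.frame(read_id = character(0), cell = character(0),
                     sequence = character(0),
                     transcribed_strand = character(0),
                     stringsAsFactors = FALSE)
  list(full_length = fl, assignments = asg,
       structures = data.frame(read_id = kept$read_id, klass = klass,
                               stringsAsFactors = FALSE),
       filter_stats = flt$stats)
}
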