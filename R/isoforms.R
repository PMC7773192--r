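# nearest annotated splice edge within tol, else the observed value (NA in
# `snapped_to` marks an unannotated edge)
snap_edge <- function(values, sites, tol) {
  if (length(sites) == 0)
    return(list(pos = values, annotated = rep(FALSE, length(values))))
  sites <- sort(sites)
  idx <- findInterval(values, sites)
  lo <- pmax(idx, 1); hi <- pmin(idx + 1, length(sites))
  d_lo <- abs(values - sites[lo]); d_hi <- abs(values - sites[hi])
  best <- ifelse(d_lo <= d_hi, sites[lo], sites[hi])
  ok <- abs(values - best) <= tol
  list(pos = ifelse(ok, best, values), annotated = ok)
}

# host gene by maximal exonic overlap, falling back to gene-span overlap
host_gene_of <- function(chrom, strand, exons, index) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(exons[, 1] + 1, exons[, 2]),
                               strand = strand)
  ov <- GenomicRanges::findOverlaps(gr, index$exon_gr)
  if (length(ov) > 0) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(index$exon_gr)[S4Vectors::subjectHits(ov)]))
    genes <- S4Vectors::mcols(index$exon_gr)$gene_id[
      S4Vectors::subjectHits(ov)]
    agg <- tapply(w, genes, sum)
    return(names(agg)[which.max(agg)])
  }
  ov <- GenomicRanges::findOverlaps(gr, index$gene_gr)
  if (length(ov) > 0) {
    return(S4Vectors::mcols(index$gene_gr)$gene_id[
      S4Vectors::subjectHits(ov)[1]])
  }
  NA_character_
}

#' Cluster one cell's spliced alignments into candidate transcript models
#'
#' Reads are grouped by (chrom, strand, snapped junction chain): each
#' junction edge is snapped to the nearest annotated splice edge within
#' `tol` bases; unannotated edges are clustered greedily within `tol` and
#' rounded to the cluster median. Mono-exon reads cluster by >= 50%
#' reciprocal overlap. Each cluster carries a representative exon set:
#' chain-internal edges fixed by the chain, terminal ends the median of the
#' supporting read ends.
#'
#' @param alignments `alignment_set` of one cell.
#' @param index an `annotation_index`.
#' @param tol snapping / clustering tolerance in bases (default 5).
#' @return list of `transcript_model` lists: chrom, strand, exons, chain,
#'   read_ids, any_unannotated_edge, host_gene.
#' @export
cluster_reads <- function(alignments, index, tol = 5) {
  if (nrow(alignments) == 0) return(list())
  blocks <- parse_blocks(alignments$blocks)
  jx <- index$junctions
  models <- list()

  multi <- which(vapply(blocks, nrow, integer(1)) > 1)
  mono <- which(vapply(blocks, nrow, integer(1)) == 1)

  if (length(multi) > 0) {
    info <- lapply(multi, function(i) {
      ch <- blocks_to_chain(blocks[[i]])
      sel <- jx$chrom == alignments$chrom[i] &
        jx$strand == alignments$strand[i]
      d <- snap_edge(ch[, 1], unique(jx$donor[sel]), tol)
      a <- snap_edge(ch[, 2], unique(jx$acceptor[sel]), tol)
      list(i = i, chrom = alignments$chrom[i],
           strand = alignments$strand[i],
           chain = cbind(donor = d$pos, acceptor = a$pos),
           annotated = c(d$annotated, a$annotated))
    })
    grp_key <- vapply(info, function(x)
      paste(x$chrom, x$strand, nrow(x$chain)), character(1))
    for (g in split(info, grp_key)) {
      taken <- rep(FALSE, length(g))
      for (s in seq_along(g)) {
        if (taken[s]) next
        members <- s
        for (t in seq_along(g)) {
          if (t == s || taken[t]) next
          if (all(abs(g[[s]]$chain - g[[t]]$chain) <= tol)) {
            members <- c(members, t); taken[t] <- TRUE
          }
        }
        taken[s] <- TRUE
        mm <- g[members]
        chain <- apply(simplify2array(lapply(mm, `[[`, "chain")),
                       c(1, 2), median)
        if (!is.matrix(chain)) chain <- matrix(chain, ncol = 2)
        colnames(chain) <- c("donor", "acceptor")
        idxs <- vapply(mm, `[[`, integer(1), "i")
        starts <- vapply(idxs, function(i) blocks[[i]][1, 1], numeric(1))
        ends <- vapply(idxs, function(i) {
          b <- blocks[[i]]; b[nrow(b), 2]
        }, numeric(1))
        exons <- cbind(start = c(median(starts), chain[, 2]),
                       end = c(chain[, 1], median(ends)))
        models[[length(models) + 1]] <- transcript_model(
          chrom = mm[[1]]$chrom, strand = mm[[1]]$strand, exons = exons,
          read_ids = alignments$read_id[idxs],
          any_unannotated_edge = !all(unlist(lapply(mm, `[[`,
                                                    "annotated"))),
          index = index)
      }
    }
  }

  if (length(mono) > 0) {
    key <- paste(alignments$chrom[mono], alignments$strand[mono])
    for (g in split(mono, key)) {
      iv <- cbind(start = vapply(g, function(i) blocks[[i]][1, 1],
                                 numeric(1)),
                  end = vapply(g, function(i) blocks[[i]][1, 2],
                               numeric(1)))
      ord <- order(iv[, 1])
      cluster_id <- integer(length(g))
      reps <- list()
      for (k in ord) {
        placed <- FALSE
        for (cl in seq_along(reps)) {
          r <- reps[[cl]]
          inter <- min(r[2], iv[k, 2]) - max(r[1], iv[k, 1])
          if (inter > 0 && inter >= 0.5 * (iv[k, 2] - iv[k, 1]) &&
              inter >= 0.5 * (r[2] - r[1])) {
            cluster_id[k] <- cl
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          reps[[length(reps) + 1]] <- iv[k, ]
          cluster_id[k] <- length(reps)
        }
      }
      for (cl in seq_along(reps)) {
        sel <- which(cluster_id == cl)
        exons <- cbind(start = median(iv[sel, 1]),
                       end = median(iv[sel, 2]))
        models[[length(models) + 1]] <- transcript_model(
          chrom = alignments$chrom[g[sel][1]],
          strand = alignments$strand[g[sel][1]], exons = exons,
          read_ids = alignments$read_id[g[sel]],
          any_unannotated_edge = FALSE, index = index)
      }
    }
  }
  models
}

#' Construct a transcript model
#'
#' @param chrom,strand location.
#' @param exons numeric matrix (start, end), 0-based half-open, sorted.
#' @param read_ids supporting read ids.
#' @param any_unannotated_edge TRUE when a junction edge failed to snap to
#'   an annotated splice edge.
#' @param index optional `annotation_index` for host-gene assignment.
#' @return a `transcript_model` list.
#' @export
transcript_model <- function(chrom, strand, exons, read_ids,
                             any_unannotated_edge = FALSE, index = NULL) {
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  stopifnot(nrow(exons) >= 1, length(read_ids) >= 1)
  host <- if (!is.null(index))
    host_gene_of(chrom, strand, exons, index) else NA_character_
  structure(list(chrom = chrom, strand = strand, exons = exons,
                 chain = blocks_to_chain(exons), read_ids = read_ids,
                 any_unannotated_edge = any_unannotated_edge,
                 host_gene = host),
            class = "transcript_model")
}

#' Depth-filter read clusters
#'
#' Clusters whose splice edges are all annotated and whose exons lie fully
#' within annotated exons need at least `min_known` supporting reads;
#' clusters with any unannotated splice edge or any exonic stretch not
#' covered by annotated exons (a retained intron, a novel exon, an
#' intergenic model) need at least `min_novel` reads. Both thresholds are
#' strict "less than" exclusions.
#'
#' @param clusters list of `transcript_model`s from [cluster_reads()].
#' @param index an `annotation_index`.
#' @param min_known,min_novel depth thresholds (defaults 2 and 5).
#' @return the kept clusters.
#' @export
filter_clusters <- function(clusters, index, min_known = 2, min_novel = 5) {
  keep <- vapply(clusters, function(m) {
    n <- length(m$read_ids)
    gr <- GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(m$exons[, 1] + 1, m$exons[, 2]))
    uncovered <- GenomicRanges::setdiff(
      gr, index$exon_gr[GenomicRanges::seqnames(index$exon_gr) == m$chrom],
      ignore.strand = TRUE)
    novel_region <- m$any_unannotated_edge || length(uncovered) > 0
    if (novel_region) n >= min_novel else n >= min_known
  }, logical(1))
  clusters[keep]
}

#' Collapse clusters into non-redundant transcript models
#'
#' Clusters with identical (chrom, strand, chain) merge with pooled
#' supports. A multi-exon model whose chain is a contiguous 5'-truncated
#' fragment of another model's chain sharing the 3' end (a genomic suffix
#' on "+", a genomic prefix on "-") merges into the longer model.
#'
#' @param clusters kept clusters from [filter_clusters()].
#' @param index optional `annotation_index` for host-gene reassignment.
#' @return list of collapsed `transcript_model`s.
#' @export
collapse_models <- function(clusters, index = NULL) {
  if (length(clusters) == 0) return(list())
  key <- vapply(clusters, function(m) {
    ck <- if (nrow(m$chain) == 0)
      paste("mono", m$exons[1, 1], m$exons[1, 2]) else chain_key(m$chain)
    paste(m$chrom, m$strand, ck, sep = "|")
  }, character(1))
  merged <- lapply(split(seq_along(clusters), key), function(sel) {
    base <- clusters[[sel[1]]]
    base$read_ids <- unlist(lapply(clusters[sel], `[[`, "read_ids"))
    base$any_unannotated_edge <-
      any(vapply(clusters[sel], `[[`, logical(1), "any_unannotated_edge"))
    base
  })
  merged <- unname(merged)

  n_j <- vapply(merged, function(m) nrow(m$chain), integer(1))
  drop <- rep(FALSE, length(merged))
  ord <- order(-n_j)
  for (small_i in rev(ord)) {
    if (n_j[small_i] == 0 || drop[small_i]) next
    sm <- merged[[small_i]]
    for (big_i in ord) {
      if (big_i == small_i || drop[big_i]) next
      bg <- merged[[big_i]]
      if (n_j[big_i] <= n_j[small_i] || bg$chrom != sm$chrom ||
          bg$strand != sm$strand) next
      k <- n_j[small_i]; mj <- n_j[big_i]
      seg <- if (sm$strand == "+")
        bg$chain[(mj - k + 1):mj, , drop = FALSE]
      else bg$chain[1:k, , drop = FALSE]
      if (all(seg == sm$chain)) {
        merged[[big_i]]$read_ids <- c(bg$read_ids, sm$read_ids)
        drop[small_i] <- TRUE
        break
      }
    }
  }
  out <- merged[!drop]
  lapply(seq_along(out), function(i) {
    m <- out[[i]]
    m$model_id <- sprintf("model%04d", i)
    if (!is.null(index))
      m$host_gene <- host_gene_of(m$chrom, m$strand, m$exons, index)
    m
  })
}

#' Classify a transcript model against the annotation
#'
#' Decision tree over the snapped model. Multi-exon models: an exact chain
#' match is known; a model exon containing a complete annotated intron of
#' the host gene (with flanking exonic bases on both sides) is intron
#' retention (IR); a chain that is a contiguous subchain of an annotated
#' chain is known (5' truncation, not novelty); all junctions annotated in
#' the host gene without matching any single transcript is a combination
#' of known junctions (CJ); all splice edges annotated in the host gene
#' with at least one novel pairing is a combination of known splice sites
#' (CS); anything with an unannotated splice edge is discarded. Mono-exon
#' models: inside one annotated exon is mono-exon (ME); containing at
#' least one complete annotated intron with both flanking exon edges is
#' mono-exon by intron retention (MIR); no gene overlap is intergenic;
#' remaining mono-exon models are discarded.
#'
#' @param model a `transcript_model` (snapped coordinates).
#' @param index an `annotation_index`.
#' @return category string: known, CJ, CS, ME, IR, MIR, intergenic,
#'   discarded.
#' @export
classify_model <- function(model, index) {
  ch <- model$chain
  jx <- index$junctions
  host <- model$host_gene

  if (nrow(model$exons) == 1) {
    s <- model$exons[1, 1]; e <- model$exons[1, 2]
    ex <- index$exons[index$exons$chrom == model$chrom &
                      index$exons$strand == model$strand, , drop = FALSE]
    if (any(ex$start <= s & ex$end >= e)) return("ME")
    sel <- jx$chrom == model$chrom & jx$strand == model$strand
    if (any(sel & jx$donor >= s + 1 & jx$acceptor <= e - 1)) return("MIR")
    gr <- GenomicRanges::GRanges(model$chrom, IRanges::IRanges(s + 1, e),
                                 strand = model$strand)
    if (!IRanges::overlapsAny(gr, index$gene_gr)) return("intergenic")
    return("discarded")
  }

  if (is.na(host)) {
    gr <- GenomicRanges::GRanges(
      model$chrom, IRanges::IRanges(model$exons[1, 1] + 1,
                                    model$exons[nrow(model$exons), 2]))
    if (!IRanges::overlapsAny(gr, index$gene_gr, ignore.strand = TRUE))
      return("intergenic")
    # overlaps annotation only on the opposite strand: not assignable to
    # any host gene, so it cannot be one of the five categories
    return("discarded")
  }

  same_tx <- names(index$chains)[
    index$transcripts$chrom == model$chrom &
    index$transcripts$strand == model$strand]
  model_key <- chain_key(ch)
  tx_keys <- vapply(index$chains[same_tx], chain_key, character(1))
  if (model_key %in% tx_keys) return("known")

  # intron retention: a complete annotated host intron strictly inside a
  # model exon, with flanking exonic bases on both sides
  host_jx <- jx[jx$gene_id == host & jx$chrom == model$chrom &
                jx$strand == model$strand, , drop = FALSE]
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1]; e <- model$exons[i, 2]
    if (any(host_jx$donor >= s + 1 & host_jx$acceptor <= e - 1))
      return("IR")
  }

  # 5'-truncated contiguous subchain of an annotated transcript -> known
  for (t in same_tx) {
    if (chain_contains(index$chains[[t]], ch, tol = 0)) return("known")
  }

  host_j_keys <- paste(host_jx$donor, host_jx$acceptor)
  if (all(paste(ch[, 1], ch[, 2]) %in% host_j_keys)) return("CJ")

  if (all(ch[, 1] %in% host_jx$donor) &&
      all(ch[, 2] %in% host_jx$acceptor)) return("CS")

  "discarded"
}

#' Expression filters for novel transcripts
#'
#' Per cell, a novel transcript counts as detected when its RPT10k is at
#' least `min_rpt10k` and its share of the host gene's total transcript
#' expression is at least `min_share`; a transcript is retained when
#' detected in at least `min_cells` cells. All three thresholds follow the
#' strict "less than" exclusion reading, so equality passes.
#'
#' @param novel_rpt matrix (novel transcripts x cells) of RPT10k computed
#'   jointly over known + novel transcripts.
#' @param host_rpt matrix of the same shape: the host gene's total RPT10k
#'   (all of its transcripts, known and novel) per cell.
#' @param min_rpt10k expression floor (default 0.1; below it the value is
#'   treated as 0).
#' @param min_share minimum host-gene share (default 0.05).
#' @param min_cells minimum number of detecting cells (default 3).
#' @return data.frame: model (rowname), n_cells_detected, retained; plus
#'   attribute `detected` (logical matrix).
#' @export
filter_novel <- function(novel_rpt, host_rpt, min_rpt10k = 0.1,
                         min_share = 0.05, min_cells = 3) {
  stopifnot(all(dim(novel_rpt) == dim(host_rpt)))
  if (any(host_rpt == 0 & novel_rpt > 0))
    stop("host gene expression 0 with transcript expression > 0")
  expressed <- novel_rpt * (novel_rpt >= min_rpt10k)
  share <- ifelse(host_rpt > 0, expressed / host_rpt, 0)
  detected <- expressed > 0 & share >= min_share
  n_cells <- rowSums(detected)
  out <- data.frame(model = rownames(novel_rpt),
                    n_cells_detected = as.integer(n_cells),
                    retained = n_cells >= min_cells,
                    stringsAsFactors = FALSE)
  attr(out, "detected") <- detected
  out
}

#' Merge per-cell transcript models into a unified catalogue
#'
#' Models are equal when (chrom, strand, chain) are equal; mono-exon models
#' merge by >= 50% reciprocal overlap. Representative terminal ends are the
#' median across cells.
#'
#' @param per_cell named list (cell -> list of `transcript_model`s).
#' @return list with `catalogue` (list of models, each with
#'   `cells` = detecting cells) and `table` (data.frame model_id, chrom,
#'   strand, n_exons, n_cells).
#' @export
merge_across_cells <- function(per_cell) {
  entries <- list()
  for (cell in names(per_cell)) {
    for (m in per_cell[[cell]]) {
      m$cell <- cell
      entries[[length(entries) + 1]] <- m
    }
  }
  if (length(entries) == 0)
    return(list(catalogue = list(),
                table = data.frame(model_id = character(0),
                                   chrom = character(0),
                                   strand = character(0),
                                   n_exons = integer(0),
                                   n_cells = integer(0))))
  multi <- vapply(entries, function(m) nrow(m$exons) > 1, logical(1))
  groups <- list()
  key <- vapply(entries, function(m)
    paste(m$chrom, m$strand, chain_key(m$chain), sep = "|"), character(1))
  for (g in split(which(multi), key[multi])) groups[[length(groups) + 1]] <- g
  # mono-exon: greedy reciprocal-overlap grouping
  mono_idx <- which(!multi)
  if (length(mono_idx) > 0) {
    mkey <- vapply(entries[mono_idx], function(m)
      paste(m$chrom, m$strand), character(1))
    for (sub in split(mono_idx, mkey)) {
      reps <- list(); assign_to <- integer(length(sub))
      for (k in seq_along(sub)) {
        iv <- entries[[sub[k]]]$exons[1, ]
        placed <- FALSE
        for (cl in seq_along(reps)) {
          r <- reps[[cl]]
          inter <- min(r[2], iv[2]) - max(r[1], iv[1])
          if (inter > 0 && inter >= 0.5 * (iv[2] - iv[1]) &&
              inter >= 0.5 * (r[2] - r[1])) {
            assign_to[k] <- cl; placed <- TRUE; break
          }
        }
        if (!placed) {
          reps[[length(reps) + 1]] <- iv
          assign_to[k] <- length(reps)
        }
      }
      for (cl in seq_along(reps))
        groups[[length(groups) + 1]] <- sub[assign_to == cl]
    }
  }
  catalogue <- lapply(seq_along(groups), function(gi) {
    ms <- entries[groups[[gi]]]
    base <- ms[[1]]
    ne <- nrow(base$exons)
    starts <- vapply(ms, function(m) m$exons[1, 1], numeric(1))
    ends <- vapply(ms, function(m) m$exons[nrow(m$exons), 2], numeric(1))
    base$exons[1, 1] <- median(starts)
    base$exons[ne, 2] <- median(ends)
    base$read_ids <- unlist(lapply(ms, `[[`, "read_ids"))
    base$cells <- unique(vapply(ms, `[[`, character(1), "cell"))
    base$model_id <- sprintf("novel%04d", gi)
    base$cell <- NULL
    base
  })
  table <- data.frame(
    model_id = vapply(catalogue, `[[`, character(1), "model_id"),
    chrom = vapply(catalogue, `[[`, character(1), "chrom"),
    strand = vapply(catalogue, `[[`, character(1), "strand"),
    n_exons = vapply(catalogue, function(m) nrow(m$exons), integer(1)),
    n_cells = vapply(catalogue, function(m) length(m$cells), integer(1)),
    stringsAsFactors = FALSE)
  list(catalogue = catalogue, table = table)
}

#' Full isoform-discovery pipeline over per-cell alignments
#'
#' Per cell: cluster, depth-filter and collapse the cell's alignments, then
#' classify each model. Novel models (CJ, CS, ME, IR, MIR) are merged
#' across cells, added to the annotation as transcripts of their host gene
#' (intergenic models get their own gene), the whole read set is
#' re-assigned jointly over known + novel transcripts, and the expression
#' filters are applied.
#'
#' @param alignments `alignment_set` with a `cell` column.
#' @param index an `annotation_index`.
#' @param tol junction tolerance (default 5).
#' @param min_rpt10k,min_share,min_cells expression filters (defaults 0.1,
#'   0.05, 3).
#' @param min_known,min_novel cluster depth filters.
#' @return list: `catalogue` (novel models with categories), `calls`
#'   (data.frame model_id, category, host_gene, n_cells_detected,
#'   retained), `expression` (joint `scan_expr`).
#' @export
discover_isoforms <- function(alignments, index, tol = 5, min_rpt10k = 0.1,
                              min_share = 0.05, min_cells = 3,
                              min_known = 2, min_novel = 5) {
  stopifnot("cell" %in% names(alignments))
  per_cell <- lapply(split(seq_len(nrow(alignments)), alignments$cell),
                     function(sel) {
    aln <- alignments[sel, , drop = FALSE]
    class(aln) <- c("alignment_set", "data.frame")
    cl <- cluster_reads(aln, index, tol)
    cl <- filter_clusters(cl, index, min_known, min_novel)
    models <- collapse_models(cl, index)
    cats <- vapply(models, classify_model, character(1), index = index)
    models[cats %in% c("CJ", "CS", "ME", "IR", "MIR")]
  })
  merged <- merge_across_cells(per_cell)
  catalogue <- merged$catalogue
  if (length(catalogue) == 0) {
    return(list(catalogue = list(),
                calls = data.frame(model_id = character(0),
                                   category = character(0),
                                   host_gene = character(0),
                                   n_cells_detected = integer(0),
                                   retained = logical(0)),
                expression = NULL))
  }
  cats <- vapply(catalogue, classify_model, character(1), index = index)
  for (i in seq_along(catalogue)) catalogue[[i]]$category <- cats[i]

  # joint quantification over known + novel transcripts
  novel_exons <- do.call(rbind, lapply(catalogue, function(m) {
    gene <- if (!is.na(m$host_gene)) m$host_gene
    else paste0("novelgene_", m$model_id)
    data.frame(gene_id = gene, transcript_id = m$model_id,
               chrom = m$chrom, strand = m$strand,
               start = m$exons[, 1], end = m$exons[, 2],
               stringsAsFactors = FALSE)
  }))
  joint_index <- annotation_index(rbind(index$exons, novel_exons))
  asg <- assign_to_transcripts(alignments, joint_index, tol)
  expr <- compute_matrix(asg)

  model_ids <- vapply(catalogue, `[[`, character(1), "model_id")
  present <- model_ids %in% rownames(expr$rpt10k)
  novel_rpt <- matrix(0, length(model_ids), ncol(expr$rpt10k),
                      dimnames = list(model_ids, colnames(expr$rpt10k)))
  novel_rpt[model_ids[present], ] <-
    expr$rpt10k[model_ids[present], , drop = FALSE]
  hosts <- novel_exons$gene_id[match(model_ids, novel_exons$transcript_id)]
  host_rpt <- matrix(0, length(model_ids), ncol(expr$rpg10k),
                     dimnames = list(model_ids, colnames(expr$rpg10k)))
  in_expr <- hosts %in% rownames(expr$rpg10k)
  host_rpt[in_expr, ] <- expr$rpg10k[hosts[in_expr], , drop = FALSE]
  flt <- filter_novel(novel_rpt, host_rpt, min_rpt10k, min_share,
                      min_cells)
  calls <- data.frame(model_id = model_ids,
                      category = cats,
                      host_gene = hosts,
                      n_cells_detected = flt$n_cells_detected,
                      retained = flt$retained, stringsAsFactors = FALSE)
  list(catalogue = catalogue, calls = calls, expression = expr)
}
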