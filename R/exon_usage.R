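# Exon-centric analysis: per-part read classification, novel-exon discovery,
# FL-weighted percent-spliced-in (PSI) and the candidate filter cascade.

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Classify one read against one exonic part
#'
#' A read is `matching` when a single aligned block covers the part with each
#' boundary missed by at most `boundary_slop` bases; `skipping` when the read
#' fully spans the part but splices it out (the part falls in a gap between
#' two blocks and no block overlaps it by more than `min_overlap`);
#' `non_informative` otherwise -- in particular when the read starts or ends
#' inside the part, as 3'-truncated internally-primed reads do.
#'
#' @param read A [consensus_read].
#' @param part_start,part_end Part interval, 0-based half-open.
#' @param chrom Part chromosome.
#' @param boundary_slop Tolerated boundary wobble in bases (default 10).
#' @param min_overlap Maximum residual overlap still counted as skipping
#'   (default 10).
#' @return `"matching"`, `"skipping"` or `"non_informative"`.
#' @export
classify_read_for_part <- function(read, part_start, part_end, chrom = NULL,
                                   boundary_slop = 10, min_overlap = 10) {
  if (!is.null(chrom) && !identical(read$chrom, chrom)) return("non_informative")
  b <- read$blocks
  ov <- overlap_len(b[, 1], b[, 2], part_start, part_end)
  covering <- b[, 1] <= part_start + boundary_slop &
    b[, 2] >= part_end - boundary_slop & ov > 0
  if (any(covering)) return("matching")
  if (read$span[1] <= part_start && read$span[2] >= part_end &&
      all(ov <= min_overlap) && nrow(b) > 1) {
    gap_ok <- b[-nrow(b), 2] <= part_start + min_overlap &
      b[-1, 1] >= part_end - min_overlap
    if (any(gap_ok)) return("skipping")
  }
  "non_informative"
}

interval_subtract <- function(start, end, sub) {
  # subtract the (sorted, disjoint) intervals in `sub` from [start, end)
  pieces <- data.frame(start = integer(0), end = integer(0))
  cur <- start
  if (nrow(sub)) {
    sub <- sub[order(sub$start), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (sub$end[i] <= cur || sub$start[i] >= end) next
      if (sub$start[i] > cur)
        pieces <- rbind(pieces, data.frame(start = cur, end = sub$start[i]))
      cur <- max(cur, sub$end[i])
    }
  }
  if (cur < end) pieces <- rbind(pieces, data.frame(start = cur, end = end))
  pieces
}

stat_mode <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])  # ties resolve to the smallest value
}

#' Discover unannotated exonic parts from read alignments
#'
#' Screens read blocks for maximal sub-intervals not covered by any annotated
#' part, clusters the candidates by overlap, and for every cluster supported
#' by at least `min_support_reads` distinct reads emits one novel part whose
#' boundaries are the modal observed start and end. Novel parts are inserted
#' into the gene's part list and all parts renumbered by coordinate.
#'
#' @param reads Reads overlapping the gene (list of [consensus_read]).
#' @param flat A `flattened_gene`.
#' @param min_support_reads Minimum distinct supporting reads (default 5).
#' @param min_length Minimum candidate length in bases (default 10).
#' @return A new `flattened_gene` with novel parts (`source = "novel"`)
#'   merged in; unchanged if no cluster qualifies.
#' @export
discover_novel_exons <- function(reads, flat, min_support_reads = 5,
                                 min_length = 10) {
  ann <- flat$parts[, c("start", "end")]
  cand <- do.call(rbind, lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    if (!identical(r$chrom, flat$chrom)) return(NULL)
    p <- do.call(rbind, lapply(seq_len(nrow(r$blocks)), function(k)
      interval_subtract(r$blocks[k, 1], r$blocks[k, 2], ann)))
    p <- p[p$end - p$start >= min_length, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    p$read <- i
    p
  }))
  if (is.null(cand) || nrow(cand) == 0) return(flat)
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  # single-linkage clustering by any-overlap
  cluster <- cumsum(c(1L, as.integer(cand$start[-1] >= cummax(cand$end)[-nrow(cand)])))
  novel <- do.call(rbind, lapply(split(cand, cluster), function(g) {
    if (length(unique(g$read)) < min_support_reads) return(NULL)
    data.frame(start = stat_mode(g$start), end = stat_mode(g$end))
  }))
  if (is.null(novel) || nrow(novel) == 0) return(flat)
  parts <- rbind(
    data.frame(start = flat$parts$start, end = flat$parts$end,
               source = flat$parts$source),
    data.frame(start = novel$start, end = novel$end, source = "novel"))
  labels <- c(flat$parts$exon_labels, rep(list(character(0)), nrow(novel)))
  ord <- order(parts$start, parts$end)
  parts <- parts[ord, , drop = FALSE]
  parts$part_index <- seq_len(nrow(parts))
  parts$exon_labels <- labels[ord]
  new_flattened_gene(flat$gene_id, flat$gene_name, flat$chrom, flat$strand,
                     parts[, c("part_index", "start", "end", "source", "exon_labels")],
                     gene = flat$gene)
}

#' Per-sample FL-weighted PSI for every exonic part
#'
#' For each (sample, part), counts reads whose classification is `matching`
#' or `skipping` (reads that fully span the part); `non_informative` reads
#' are excluded from both numerator and denominator. Consensus counts tally
#' reads; FL counts sum their full-length multiplicities. PSI is
#' `100 * matching_fl / total_fl`, `NA` when no read spans the part.
#'
#' @param reads_by_sample Named list: sample label -> list of
#'   [consensus_read] objects.
#' @param flat A `flattened_gene` (novel parts already injected if desired).
#' @param boundary_slop,min_overlap Passed to [classify_read_for_part()].
#' @return data.frame with one row per (part, sample): `gene_id`,
#'   `part_index`, `part_id`, `start`, `end`, `source`, `sample`,
#'   `matching_consensus`, `total_consensus`, `matching_fl`, `total_fl`,
#'   `psi`; sorted by part then sample.
#' @export
psi_table <- function(reads_by_sample, flat, boundary_slop = 10,
                      min_overlap = 10) {
  stopifnot(!is.null(names(reads_by_sample)))
  out <- list()
  for (sample in names(reads_by_sample)) {
    reads <- reads_by_sample[[sample]]
    for (i in seq_len(nrow(flat$parts))) {
      ps <- flat$parts$start[i]; pe <- flat$parts$end[i]
      mc <- tc <- mf <- tf <- 0L
      for (r in reads) {
        cls <- classify_read_for_part(r, ps, pe, chrom = flat$chrom,
                                      boundary_slop = boundary_slop,
                                      min_overlap = min_overlap)
        if (cls == "non_informative") next
        tc <- tc + 1L; tf <- tf + r$fl_count
        if (cls == "matching") { mc <- mc + 1L; mf <- mf + r$fl_count }
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = flat$gene_id, part_index = flat$parts$part_index[i],
        part_id = format_part_number(flat$parts$part_index[i]),
        start = ps, end = pe, source = flat$parts$source[i], sample = sample,
        matching_consensus = mc, total_consensus = tc,
        matching_fl = mf, total_fl = tf,
        psi = if (tf > 0) 100 * mf / tf else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$part_index, res$sample), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count consensus reads overlapping each gene
#'
#' Used for the gene-level coverage filter: a read overlaps the gene when any
#' aligned block intersects the gene span.
#'
#' @param reads_by_sample Named list of read lists.
#' @param flats List of `flattened_gene` objects.
#' @return Named integer vector keyed by `gene_id` (summed over samples).
#' @export
gene_read_counts <- function(reads_by_sample, flats) {
  counts <- stats::setNames(integer(length(flats)),
                            vapply(flats, `[[`, "", "gene_id"))
  for (reads in reads_by_sample) {
    for (r in reads) {
      for (fl in flats) {
        if (identical(r$chrom, fl$chrom) &&
            any(overlap_len(r$blocks[, 1], r$blocks[, 2],
                            fl$span[1], fl$span[2]) > 0))
          counts[fl$gene_id] <- counts[fl$gene_id] + 1L
      }
    }
  }
  counts
}

#' Apply the candidate filter cascade
#'
#' Mirrors the study design for nominating differentially used exons: genes
#' need at least `min_gene_consensus` consensus reads overall; a part is
#' coverage-eligible when at least two samples span it with
#' `min_part_consensus` consensus reads; it passes when the maximum pairwise
#' PSI difference among coverage-eligible samples reaches `min_psi_delta`
#' percentage points (computed on unrounded PSI).
#'
#' @param records PSI table from [psi_table()] (possibly several genes,
#'   row-bound).
#' @param gene_consensus Optional named vector from [gene_read_counts()];
#'   when absent, a per-gene lower bound is derived from `records` (the
#'   maximum part coverage per sample, summed over samples).
#' @param min_gene_consensus,min_part_consensus,min_psi_delta Thresholds
#'   (defaults 10, 30, 20).
#' @return data.frame with one row per part of every eligible gene with >= 2
#'   coverage-eligible samples: `gene_id`, `part_index`, `part_id`,
#'   `source`, `n_covered_samples`, `max_psi_delta`, `passes`; sorted by
#'   gene then part.
#' @export
filter_candidates <- function(records, gene_consensus = NULL,
                              min_gene_consensus = 10,
                              min_part_consensus = 30, min_psi_delta = 20) {
  if (is.null(gene_consensus)) {
    per <- lapply(split(records, list(records$gene_id, records$sample), drop = TRUE),
                  function(g) data.frame(gene_id = g$gene_id[1],
                                         n = max(g$total_consensus)))
    per <- do.call(rbind, per)
    gene_consensus <- vapply(split(per$n, per$gene_id), sum, numeric(1))
  }
  eligible_genes <- names(gene_consensus)[gene_consensus >= min_gene_consensus]
  recs <- records[records$gene_id %in% eligible_genes, , drop = FALSE]
  if (nrow(recs) == 0)
    return(data.frame(gene_id = character(0), part_index = integer(0),
                      part_id = character(0), source = character(0),
                      n_covered_samples = integer(0),
                      max_psi_delta = numeric(0), passes = logical(0)))
  out <- lapply(split(recs, list(recs$gene_id, recs$part_index), drop = TRUE),
                function(g) {
    cov <- g[g$total_consensus >= min_part_consensus & !is.na(g$psi), , drop = FALSE]
    if (nrow(cov) < 2) return(NULL)
    delta <- max(stats::dist(cov$psi))
    data.frame(gene_id = g$gene_id[1], part_index = g$part_index[1],
               part_id = g$part_id[1], source = g$source[1],
               n_covered_samples = nrow(cov), max_psi_delta = delta,
               passes = delta >= min_psi_delta)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(gene_id = character(0), part_index = integer(0),
                      part_id = character(0), source = character(0),
                      n_covered_samples = integer(0),
                      max_psi_delta = numeric(0), passes = logical(0)))
  out <- out[order(out$gene_id, out$part_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the per-part coverage/PSI report
#'
#' One row per (gene, part, sample) with all PSI-record fields in a
#' deterministic column and row order; PSI is rendered to one decimal place
#' (`NA` when undefined). This table is the substrate for exon coverage
#' plots.
#'
#' @param records PSI table from [psi_table()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
coverage_report <- function(records, path) {
  cols <- c("gene_id", "part_index", "part_id", "start", "end", "source",
            "sample", "matching_consensus", "total_consensus", "matching_fl",
            "total_fl", "psi")
  rec <- records[order(records$gene_id, records$part_index, records$sample),
                 cols, drop = FALSE]
  rec$psi <- ifelse(is.na(rec$psi), "NA", sprintf("%.1f", rec$psi))
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export novel exonic parts as BED
#'
#' @param flat A `flattened_gene` (after [discover_novel_exons()]).
#' @param path Output BED file (0-based half-open).
#' @return `path`, invisibly.
#' @export
write_novel_bed <- function(flat, path) {
  nov <- flat$parts[flat$parts$source == "novel", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t%s", flat$chrom, nov$start, nov$end,
                   flat$gene_id, format_part_number(nov$part_index), flat$strand)
  writeLines(lines, path)
  invisible(path)
}
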