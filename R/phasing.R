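# Cassette-exon phasing: joint inclusion/exclusion of a set of target exons
# within single reads, FL-weighted pattern tallies, and pattern-to-transcript
# matching.

#' Define a set of target cassette exons
#'
#' @param chrom Chromosome shared by all target exons.
#' @param starts,ends 0-based half-open exon intervals, sorted by coordinate.
#' @param labels Unique display labels, one per exon (e.g. exon numbers).
#' @param gene_id Optional gene identifier carried into reports.
#' @return Object of class `target_exon_set`; `region` spans min start to
#'   max end.
#' @export
target_exon_set <- function(chrom, starts, ends, labels, gene_id = NA_character_) {
  stopifnot(length(starts) == length(ends), length(labels) == length(starts),
            all(starts < ends), !anyDuplicated(labels))
  ord <- order(starts, ends)
  structure(list(chrom = chrom, starts = as.integer(starts[ord]),
                 ends = as.integer(ends[ord]), labels = as.character(labels[ord]),
                 gene_id = gene_id,
                 region = c(min(starts), max(ends))),
            class = "target_exon_set")
}

#' Read target exons from a BED file
#'
#' Plain BED (0-based half-open) with the exon label in the name column; all
#' rows must share one chromosome.
#'
#' @param path BED file.
#' @param gene_id Optional gene identifier.
#' @return A [target_exon_set].
#' @export
read_target_bed <- function(path, gene_id = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character"))[, 1:4]
  names(df) <- c("chrom", "start", "end", "name")
  if (length(unique(df$chrom)) != 1)
    stop("target exons must be on a single chromosome: ", path)
  if (anyDuplicated(df$name)) stop("duplicate target exon labels in ", path)
  target_exon_set(df$chrom[1], df$start, df$end, df$name, gene_id = gene_id)
}

#' Determine the splicing pattern of the target exons within one read
#'
#' The read must span the whole target region so that every target exon is
#' phased simultaneously; otherwise it is rejected. Each exon is then scored
#' 1 (`matching`) or 0 (`skipping`) via [classify_read_for_part()]; any
#' `non_informative` exon rejects the read.
#'
#' @param read A [consensus_read].
#' @param targets A [target_exon_set].
#' @param boundary_slop,min_overlap Passed to [classify_read_for_part()].
#' @return Integer 0/1 vector named by exon label, or `NULL` (reject).
#' @export
read_pattern <- function(read, targets, boundary_slop = 10, min_overlap = 10) {
  if (!identical(read$chrom, targets$chrom)) return(NULL)
  if (read$span[1] > targets$region[1] || read$span[2] < targets$region[2])
    return(NULL)
  v <- integer(length(targets$labels))
  for (i in seq_along(v)) {
    cls <- classify_read_for_part(read, targets$starts[i], targets$ends[i],
                                  chrom = targets$chrom,
                                  boundary_slop = boundary_slop,
                                  min_overlap = min_overlap)
    if (cls == "non_informative") return(NULL)
    v[i] <- if (cls == "matching") 1L else 0L
  }
  stats::setNames(v, targets$labels)
}

#' Splicing pattern of an annotated transcript over the target exons
#'
#' Transcripts whose span does not enclose the target region are not
#' applicable (they could not have produced a phaseable read). Otherwise an
#' exon scores 1 when some transcript exon covers it with each boundary
#' missed by at most `boundary_slop` bases.
#'
#' @param exons data.frame of transcript exons (`start`, `end`, 0-based
#'   half-open).
#' @param targets A [target_exon_set].
#' @param boundary_slop Boundary tolerance (default 10).
#' @return Integer 0/1 vector named by exon label, or `NULL` (not
#'   applicable).
#' @export
transcript_pattern <- function(exons, targets, boundary_slop = 10) {
  if (min(exons$start) > targets$region[1] || max(exons$end) < targets$region[2])
    return(NULL)
  v <- integer(length(targets$labels))
  for (i in seq_along(v)) {
    cov <- exons$start <= targets$starts[i] + boundary_slop &
      exons$end >= targets$ends[i] - boundary_slop &
      overlap_len(exons$start, exons$end, targets$starts[i], targets$ends[i]) > 0
    v[i] <- as.integer(any(cov))
  }
  stats::setNames(v, targets$labels)
}

pattern_string <- function(v) paste(v, collapse = "-")

#' Phase target exons across samples and match patterns to annotation
#'
#' Aggregates the splicing patterns of all phaseable reads per sample with
#' consensus and FL-weighted tallies, computes each pattern's share of the
#' sample's phaseable FL reads, and lists every annotated transcript whose
#' pattern over the target exons is identical (several transcripts may be
#' indistinguishable over the chosen exons; none means the structure is
#' unannotated).
#'
#' @param reads_by_sample Named list: sample -> list of [consensus_read].
#' @param targets A [target_exon_set].
#' @param annotation Named list of [gene_model] objects, or `NULL` to skip
#'   transcript matching.
#' @param boundary_slop,min_overlap Passed to the classifiers.
#' @return data.frame with columns `sample`, `pattern` (like `"1-0-1"`),
#'   `consensus_count`, `fl_count`, `percent`, `matched_transcripts`
#'   (comma-joined, `"unannotated"` when empty); within each sample sorted by
#'   descending `fl_count`, ties by pattern string. Samples with no
#'   phaseable read contribute no rows. The target labels are attached as
#'   attribute `"labels"`.
#' @export
phase <- function(reads_by_sample, targets, annotation = NULL,
                  boundary_slop = 10, min_overlap = 10) {
  stopifnot(!is.null(names(reads_by_sample)))
  tx_patterns <- character(0)
  if (!is.null(annotation)) {
    for (g in annotation) {
      for (tx in names(g$transcripts)) {
        if (!identical(g$chrom, targets$chrom)) next
        p <- transcript_pattern(g$transcripts[[tx]], targets,
                                boundary_slop = boundary_slop)
        if (!is.null(p)) tx_patterns[tx] <- pattern_string(p)
      }
    }
  }
  out <- list()
  for (sample in names(reads_by_sample)) {
    tally <- list()
    for (r in reads_by_sample[[sample]]) {
      v <- read_pattern(r, targets, boundary_slop = boundary_slop,
                        min_overlap = min_overlap)
      if (is.null(v)) next
      key <- pattern_string(v)
      if (is.null(tally[[key]])) tally[[key]] <- c(0L, 0L)
      tally[[key]] <- tally[[key]] + c(1L, r$fl_count)
    }
    if (length(tally) == 0) next
    df <- data.frame(sample = sample, pattern = names(tally),
                     consensus_count = vapply(tally, `[`, 0L, 1),
                     fl_count = vapply(tally, `[`, 0L, 2))
    df$percent <- 100 * df$fl_count / sum(df$fl_count)
    df$matched_transcripts <- vapply(df$pattern, function(p) {
      hits <- sort(names(tx_patterns)[tx_patterns == p])
      if (length(hits) == 0) "unannotated" else paste(hits, collapse = ",")
    }, "")
    df <- df[order(-df$fl_count, df$pattern), , drop = FALSE]
    out[[sample]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), pattern = character(0),
               consensus_count = integer(0), fl_count = integer(0),
               percent = numeric(0), matched_transcripts = character(0))
  rownames(res) <- NULL
  attr(res, "labels") <- targets$labels
  res
}

#' Write a phase report as TSV
#'
#' Percentages are rendered to one decimal place; counts are exact integers.
#'
#' @param report data.frame from [phase()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
phase_report_tsv <- function(report, path) {
  rep2 <- report
  rep2$percent <- sprintf("%.1f", rep2$percent)
  utils::write.table(rep2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
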