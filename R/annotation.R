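# Gene models and exonic-part flattening.
#
# Internal coordinates are 0-based half-open throughout the package; GTF/GFF
# I/O is 1-based inclusive and SAM POS is 1-based, converted at the edges.

#' Construct a gene model
#'
#' A gene model holds the annotated transcripts of one gene on one
#' chromosome/strand. Exons of each transcript must be non-overlapping and are
#' stored sorted by genomic coordinate.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param transcripts Named list; each element a two-column `data.frame` with
#'   columns `start`, `end` (0-based half-open exon intervals).
#' @param gene_name Display name; defaults to `gene_id`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts, gene_name = gene_id) {
  stopifnot(is.character(gene_id), nzchar(gene_id), nzchar(chrom),
            strand %in% c("+", "-", "*"), length(transcripts) >= 1)
  transcripts <- lapply(transcripts, function(ex) {
    ex <- as.data.frame(ex)[, c("start", "end")]
    if (any(ex$start >= ex$end)) stop("exon with start >= end in gene ", gene_id)
    ex <- ex[order(ex$start, ex$end), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("overlapping exons within one transcript of gene ", gene_id)
    rownames(ex) <- NULL
    ex
  })
  span <- c(min(vapply(transcripts, function(e) min(e$start), numeric(1))),
            max(vapply(transcripts, function(e) max(e$end), numeric(1))))
  structure(list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
                 strand = strand, transcripts = transcripts, span = span),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s], %d transcript(s)\n",
              x$gene_id, x$gene_name, x$chrom, x$span[1], x$span[2], x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' Load gene models from a GTF file
#'
#' Parses exon features of a GENCODE-dialect GTF (attributes `gene_id`,
#' `transcript_id`, optionally `gene_name`) into one [gene_model] per gene.
#' Coordinates are converted from GTF 1-based inclusive to internal 0-based
#' half-open. Zero-length and duplicated exon records are dropped with a
#' warning.
#'
#' @param path GTF file.
#' @param genes Optional character vector restricting output to these
#'   `gene_id`s (members absent from the file are silently ignored).
#' @return Named list of [gene_model] objects, keyed by `gene_id`.
#' @export
load_gtf <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0) stop("no exon features in GTF: ", path)
  if (is.null(df$gene_id) || anyNA(df$gene_id))
    stop("exon feature without gene_id attribute in ", path)
  if (is.null(df$transcript_id) || anyNA(df$transcript_id))
    stop("exon feature without transcript_id attribute in ", path)
  if (!is.null(genes)) df <- df[df$gene_id %in% genes, , drop = FALSE]
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  # GTF 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  bad <- df$start0 >= df$end0
  if (any(bad)) {
    warning(sum(bad), " zero-length exon record(s) dropped")
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df[, c("transcript_id", "start0", "end0")])
  if (any(dup)) {
    warning(sum(dup), " duplicate exon record(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  out <- lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$transcript_id),
                  function(t) data.frame(start = t$start0, end = t$end0))
    name <- if (!is.null(g$gene_name) && !is.na(g$gene_name[1])) g$gene_name[1] else g$gene_id[1]
    gene_model(g$gene_id[1], as.character(g$seqnames[1]),
               as.character(g$strand[1]), txs, gene_name = name)
  })
  out[order(names(out))]
}

#' Flatten a gene into disjoint exonic parts
#'
#' Collapses all transcripts of a gene into one metatranscript of disjoint
#' exonic parts: the exon-covered segments between consecutive distinct exon
#' boundary coordinates, numbered 1..k in increasing genomic coordinate.
#' Every transcript exon boundary coincides with a part boundary, so exon
#' usage can be counted per part independently of which transcript a read
#' came from.
#'
#' @param gene A [gene_model].
#' @return An object of class `flattened_gene`: the gene's identifiers plus a
#'   `parts` data.frame with columns `part_index`, `start`, `end`, `source`
#'   (`"annotated"` or `"novel"`), and list-column `exon_labels` of
#'   `"transcript_id:exon_ordinal"` strings contributing to the part.
#' @export
flatten_gene <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- do.call(rbind, lapply(names(gene$transcripts), function(tx) {
    e <- gene$transcripts[[tx]]
    data.frame(tx = tx, ordinal = seq_len(nrow(e)), start = e$start, end = e$end)
  }))
  bounds <- sort(unique(c(ex$start, ex$end)))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  labels <- vector("list", length(seg_start))
  covered <- logical(length(seg_start))
  for (i in seq_along(seg_start)) {
    hit <- ex$start <= seg_start[i] & ex$end >= seg_end[i]
    covered[i] <- any(hit)
    labels[[i]] <- sprintf("%s:%d", ex$tx[hit], ex$ordinal[hit])
  }
  parts <- data.frame(part_index = seq_len(sum(covered)),
                      start = seg_start[covered], end = seg_end[covered],
                      source = "annotated")
  parts$exon_labels <- labels[covered]
  new_flattened_gene(gene$gene_id, gene$gene_name, gene$chrom, gene$strand,
                     parts, gene = gene)
}

new_flattened_gene <- function(gene_id, gene_name, chrom, strand, parts,
                               gene = NULL) {
  stopifnot(all(c("part_index", "start", "end", "source") %in% names(parts)))
  if (is.null(parts$exon_labels)) parts$exon_labels <- rep(list(character(0)), nrow(parts))
  rownames(parts) <- NULL
  structure(list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
                 strand = strand, parts = parts,
                 span = if (nrow(parts)) c(min(parts$start), max(parts$end)) else c(NA, NA),
                 gene = gene),
            class = "flattened_gene")
}

#' @export
print.flattened_gene <- function(x, ...) {
  cat(sprintf("flattened_gene %s: %d exonic part(s) on %s [%s]\n",
              x$gene_id, nrow(x$parts), x$chrom, x$strand))
  invisible(x)
}

#' Flatten every gene of an annotation
#'
#' @param genes Named list of [gene_model] objects (e.g. from [load_gtf()]).
#' @return Named list of `flattened_gene` objects.
#' @export
flatten_annotation <- function(genes) {
  lapply(genes, flatten_gene)
}

#' Render an exonic part number
#'
#' Part ordinals are rendered zero-padded to (at least) three digits, the
#' convention used in flattened DEXSeq-style annotations ("EP 038").
#'
#' @param i Integer ordinal(s).
#' @return Character vector like `"038"`.
#' @export
format_part_number <- function(i) formatC(i, width = 3, flag = "0")

#' Write flattened genes as a DEXSeq-style GFF
#'
#' Emits one `aggregate_gene` feature per gene and one `exonic_part` feature
#' per part, with GTF-style attributes `gene_id`, `exonic_part_number`
#' (zero-padded) and `part_source`. Coordinates are written 1-based
#' inclusive; [read_flattened_gff()] reproduces the same parts.
#'
#' @param flats List of `flattened_gene` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flattened_gff <- function(flats, path) {
  lines <- character(0)
  for (fl in flats) {
    if (nrow(fl$parts) == 0) next
    lines <- c(lines, sprintf(
      "%s\tpsiphase\taggregate_gene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
      fl$chrom, fl$span[1] + 1L, fl$span[2], fl$strand, fl$gene_id, fl$gene_name))
    lines <- c(lines, sprintf(
      paste0("%s\tpsiphase\texonic_part\t%d\t%d\t.\t%s\t.\t",
             "gene_id \"%s\"; exonic_part_number \"%s\"; part_source \"%s\";"),
      fl$chrom, fl$parts$start + 1L, fl$parts$end, fl$strand, fl$gene_id,
      format_part_number(fl$parts$part_index), fl$parts$source))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a flattened GFF written by [write_flattened_gff()]
#'
#' @param path GFF file.
#' @return Named list of `flattened_gene` objects (without transcript models).
#' @export
read_flattened_gff <- function(path) {
  if (!file.exists(path)) stop("flattened GFF not found: ", path)
  df <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  agg <- df[df$type == "aggregate_gene", , drop = FALSE]
  parts <- df[df$type == "exonic_part", , drop = FALSE]
  out <- lapply(split(parts, parts$gene_id), function(p) {
    p <- p[order(p$start), , drop = FALSE]
    a <- agg[agg$gene_id == p$gene_id[1], , drop = FALSE]
    name <- if (nrow(a) && !is.null(a$gene_name) && !is.na(a$gene_name[1])) a$gene_name[1] else p$gene_id[1]
    new_flattened_gene(
      p$gene_id[1], name, as.character(p$seqnames[1]), as.character(p$strand[1]),
      data.frame(part_index = as.integer(p$exonic_part_number),
                 start = p$start - 1L, end = p$end, source = p$part_source))
  })
  out[order(names(out))]
}
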