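# Consuming aligned Iso-Seq consensus reads.
#
# Each SAM/BAM record is one consensus (cluster) read; its full-length (FL)
# read multiplicity -- the number of raw full-length reads the Iso-Seq
# pipeline collapsed into it -- weights all downstream quantification.

#' Construct a consensus read
#'
#' @param read_id Read name.
#' @param sample Sample label (barcode / file label).
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param blocks Two-column matrix or data.frame of aligned exonic segments
#'   (0-based half-open), sorted and non-overlapping.
#' @param fl_count Full-length read multiplicity (>= 0).
#' @return An object of class `consensus_read` with a `span` field covering
#'   first block start to last block end.
#' @export
consensus_read <- function(read_id, sample, chrom, strand, blocks, fl_count) {
  blocks <- as.matrix(blocks)
  dimnames(blocks) <- list(NULL, c("start", "end"))
  stopifnot(ncol(blocks) == 2, nrow(blocks) >= 1, all(blocks[, 1] < blocks[, 2]),
            fl_count >= 0)
  if (is.unsorted(blocks[, 1])) blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  if (nrow(blocks) > 1 && any(blocks[-1, 1] < blocks[-nrow(blocks), 2]))
    stop("overlapping aligned blocks in read ", read_id)
  structure(list(read_id = read_id, sample = sample, chrom = chrom,
                 strand = strand, blocks = blocks, fl_count = as.integer(fl_count),
                 span = c(blocks[1, 1], blocks[nrow(blocks), 2])),
            class = "consensus_read")
}

#' Reconstruct aligned reference blocks from a CIGAR string
#'
#' Walks the reference cursor: `M`, `=`, `X` and `D` consume reference within
#' the current block, `N` closes the block (a splice gap), and `I`, `S`, `H`
#' consume no reference.
#'
#' @param reference_start 0-based leftmost aligned reference position.
#' @param cigar CIGAR string using operations `M I D N S H = X`.
#' @return Two-column integer matrix (`start`, `end`) of 0-based half-open
#'   blocks in coordinate order.
#' @export
cigar_to_blocks <- function(reference_start, cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))[[1]]
  if (length(m) == 0 || sum(nchar(m)) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  len <- as.integer(sub(".$", "", m))
  op <- sub("^[0-9]+", "", m)
  bad <- setdiff(op, c("M", "I", "D", "N", "S", "H", "=", "X"))
  if (length(bad)) stop("unsupported CIGAR operation(s): ", paste(bad, collapse = ", "))
  pos <- reference_start
  block_start <- NA_integer_
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      if (is.na(block_start)) block_start <- pos
      pos <- pos + len[i]
    } else if (op[i] == "N") {
      if (!is.na(block_start)) { starts <- c(starts, block_start); ends <- c(ends, pos) }
      block_start <- NA_integer_
      pos <- pos + len[i]
    }
    # I, S, H consume no reference
  }
  if (!is.na(block_start)) { starts <- c(starts, block_start); ends <- c(ends, pos) }
  cbind(start = starts, end = ends)
}

#' Read a full-length-count sidecar table
#'
#' Two-column tab-separated file (`read_id`, `fl_count`), no header.
#'
#' @param path TSV file.
#' @return Named integer vector keyed by read id.
#' @export
read_fl_sidecar <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("read_id", "fl_count"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$read_id)) stop("duplicate read ids in FL sidecar ", path)
  if (any(df$fl_count < 0)) stop("negative FL count in sidecar ", path)
  stats::setNames(df$fl_count, df$read_id)
}

#' Extract a read's full-length multiplicity
#'
#' Resolution order: sidecar table, then Iso-Seq read-name grammar (a
#' path-separated token `f<k>p<j>` or an attribute
#' `full_length_coverage=<k>`), then a default of 1 with a warning.
#'
#' @param read_name Read name from the alignment.
#' @param sidecar Optional named integer vector from [read_fl_sidecar()].
#' @param warn Emit the fallback warning (callers batching many reads warn
#'   once themselves).
#' @return Integer FL count.
#' @export
parse_fl_count <- function(read_name, sidecar = NULL, warn = TRUE) {
  stopifnot(nzchar(read_name))
  if (!is.null(sidecar) && read_name %in% names(sidecar)) {
    v <- sidecar[[read_name]]
    if (v < 0) stop("negative FL count for read ", read_name)
    return(as.integer(v))
  }
  m <- regmatches(read_name, regexec("full_length_coverage=([0-9]+)", read_name))[[1]]
  if (length(m) == 2) return(as.integer(m[2]))
  m <- regmatches(read_name, regexec("(?:^|/)f([0-9]+)p[0-9]+(?:/|$)", read_name))[[1]]
  if (length(m) == 2) return(as.integer(m[2]))
  if (warn) warning("no FL count for read '", read_name, "'; defaulting to 1")
  1L
}

#' Load consensus reads from a SAM or BAM file
#'
#' Secondary, supplementary and unmapped records are excluded; each retained
#' primary alignment becomes one [consensus_read] with blocks reconstructed
#' by [cigar_to_blocks()] and FL multiplicity from [parse_fl_count()]. Plain
#' SAM text is converted on the fly with [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @param sample_label Sample name attached to every read.
#' @param fl_sidecar Optional sidecar TSV path or named vector of FL counts.
#' @param min_mapq Minimum mapping quality (default 0: consensus reads carry
#'   no meaningful MAPQ filter in this protocol).
#' @return List of [consensus_read] objects.
#' @export
load_reads <- function(path, sample_label, fl_sidecar = NULL, min_mapq = 0) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is.character(fl_sidecar) && length(fl_sidecar) == 1)
    fl_sidecar <- read_fl_sidecar(fl_sidecar)
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam")
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- which(is.na(rec$mapq) | rec$mapq >= min_mapq)
  defaulted <- 0L
  reads <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    fl <- tryCatch(parse_fl_count(rec$qname[i], fl_sidecar, warn = FALSE),
                   error = function(e) stop(e))
    if (!(!is.null(fl_sidecar) && rec$qname[i] %in% names(fl_sidecar)) &&
        !grepl("full_length_coverage=[0-9]+", rec$qname[i]) &&
        !grepl("(^|/)f[0-9]+p[0-9]+(/|$)", rec$qname[i]))
      defaulted <- defaulted + 1L
    reads[[j]] <- consensus_read(
      read_id = rec$qname[i], sample = sample_label,
      chrom = as.character(rec$rname[i]),
      strand = if (as.character(rec$strand[i]) == "-") "-" else "+",
      blocks = cigar_to_blocks(rec$pos[i] - 1L, rec$cigar[i]),
      fl_count = fl)
  }
  if (defaulted > 0)
    warning(defaulted, " read(s) without FL count information; defaulted to 1")
  reads
}

#' Tabulate splice junctions supported by consensus reads
#'
#' One row per distinct (chrom, donor_end, acceptor_start) junction, with the
#' number of supporting consensus reads and the sum of their FL
#' multiplicities. Junctions below `min_support` consensus reads are dropped
#' (the display convention used for sashimi plots).
#'
#' @param reads List of [consensus_read] objects.
#' @param min_support Minimum consensus-read support (default 5).
#' @return data.frame with columns `chrom`, `donor_end`, `acceptor_start`,
#'   `consensus_support`, `fl_support`, sorted by coordinate.
#' @export
junction_table <- function(reads, min_support = 5) {
  rows <- lapply(reads, function(r) {
    n <- nrow(r$blocks)
    if (n < 2) return(NULL)
    data.frame(chrom = r$chrom,
               donor_end = r$blocks[-n, 2],
               acceptor_start = r$blocks[-1, 1],
               fl = r$fl_count)
  })
  rows <- do.call(rbind, rows)
  empty <- data.frame(chrom = character(0), donor_end = integer(0),
                      acceptor_start = integer(0),
                      consensus_support = integer(0), fl_support = integer(0))
  if (is.null(rows)) return(empty)
  key <- paste(rows$chrom, rows$donor_end, rows$acceptor_start, sep = "\r")
  agg <- do.call(rbind, lapply(split(rows, key), function(g) {
    data.frame(chrom = g$chrom[1], donor_end = g$donor_end[1],
               acceptor_start = g$acceptor_start[1],
               consensus_support = nrow(g), fl_support = sum(g$fl))
  }))
  agg <- agg[agg$consensus_support >= min_support, , drop = FALSE]
  if (nrow(agg) == 0) return(empty)
  agg <- agg[order(agg$chrom, agg$donor_end, agg$acceptor_start), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write a junction table as TSV
#'
#' @param junctions data.frame from [junction_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_junction_tsv <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
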