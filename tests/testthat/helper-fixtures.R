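# In-code fixture builders shared by the suite. Everything is generated at
# test time; nothing binary is stored.

make_read <- function(blocks, fl = 1, chrom = "chrS", sample = "s",
                      strand = "+", id = NULL) {
  blocks <- matrix(unlist(blocks), ncol = 2, byrow = is.list(blocks))
  if (is.null(id)) id <- sprintf("r%04d", sample.int(1e6, 1))
  consensus_read(id, sample, chrom, strand, blocks, fl)
}

# Write a minimal GENCODE-dialect GTF; exons given 0-based half-open.
write_mini_gtf <- function(path, genes) {
  lines <- character(0)
  for (g in genes) {
    for (tx in names(g$transcripts)) {
      ex <- g$transcripts[[tx]]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                       g$gene_id, tx, if (is.null(g$gene_name)) g$gene_id else g$gene_name)
      lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, ex$start + 1L, ex$end, g$strand, attrs))
    }
  }
  writeLines(lines, path)
  path
}

# Write a minimal SAM file from (qname, flag, pos0, cigar) records.
write_mini_sam <- function(path, recs, chrom = "chrS", chrom_len = 100000) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(recs, function(r) {
    paste(r$qname, r$flag, chrom, r$pos0 + 1L, if (is.null(r$mapq)) 60L else r$mapq,
          r$cigar, "*", 0L, 0L,
          if (is.null(r$seq)) "*" else r$seq, "*", sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# Brute-force flattening oracle: label every base of the exon union with the
# set of (transcript, exon ordinal) pairs covering it, then group runs of
# identical non-empty label sets into parts.
flatten_oracle <- function(gene) {
  lo <- gene$span[1]; hi <- gene$span[2]
  labels <- vector("list", hi - lo)
  for (tx in names(gene$transcripts)) {
    e <- gene$transcripts[[tx]]
    for (k in seq_len(nrow(e))) {
      for (b in seq(e$start[k], e$end[k] - 1L)) {
        i <- b - lo + 1L
        labels[[i]] <- c(labels[[i]], sprintf("%s:%d", tx, k))
      }
    }
  }
  key <- vapply(labels, function(l) paste(sort(l), collapse = "|"), "")
  parts <- data.frame(start = integer(0), end = integer(0))
  run_start <- NA_integer_
  for (i in seq_along(key)) {
    new_run <- key[i] != "" && (i == 1 || key[i] != key[i - 1])
    if (new_run) {
      if (!is.na(run_start))
        parts <- rbind(parts, data.frame(start = run_start + lo - 1L, end = i + lo - 1L))
      run_start <- i
    } else if (key[i] == "" && !is.na(run_start)) {
      parts <- rbind(parts, data.frame(start = run_start + lo - 1L, end = i + lo - 1L))
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start))
    parts <- rbind(parts, data.frame(start = run_start + lo - 1L,
                                     end = length(key) + lo))
  parts
}

# Random small gene model for property tests.
random_gene <- function(seed, max_tx = 6, max_exons = 10) {
  set.seed(seed)
  n_tx <- sample(max_tx, 1)
  txs <- list()
  for (t in seq_len(n_tx)) {
    n_ex <- sample(max_exons, 1)
    bounds <- sort(sample(0:400, 2 * n_ex))
    # enforce strictly increasing so exons are non-empty and disjoint
    bounds <- bounds + seq_along(bounds)
    txs[[paste0("tx", t)]] <- data.frame(
      start = bounds[seq(1, length(bounds), 2)],
      end = bounds[seq(2, length(bounds), 2)])
  }
  gene_model("g", "chrR", "+", txs)
}

# Shared toy cassette-gene scenario used across module tests.
toy_cassette_scenario <- function() {
  g <- regular_gene("G1", n_exons = 8, exon_len = 800, intron_len = 300,
                    transcripts = list(TX_ALL = "all",
                                       TX_SKIP5 = list(exclude = 5)))
  scenario(list(g),
           samples = list(
             a = list(list(gene = "G1", transcript = "TX_ALL", consensus = 6,
                           fl_total = 60),
                      list(gene = "G1", transcript = "TX_SKIP5", consensus = 4,
                           fl_total = 20)),
             b = list(list(gene = "G1", transcript = "TX_SKIP5", consensus = 5,
                           fl_total = 35))),
           size_window = c(4000, 10000))
}
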