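# Deterministic synthetic fixtures: a declarative splicing scenario is
# rendered into a toy genome FASTA, a GTF annotation, per-sample aligned SAM
# files of consensus reads with FL multiplicities, and a closed-form truth
# table. Emulates the library design of the study: oligo(dT)-primed cDNA,
# 5-10 kb size selection, and 3' truncation at genomic A-rich internal
# priming sites for transcripts longer than the read-length window.

#' Declare a gene for a synthetic scenario
#'
#' @param gene_id,chrom,strand Gene identity and location.
#' @param exons data.frame with columns `start`, `end` (0-based half-open,
#'   pairwise disjoint, sorted) and optional logical `annotated` (default
#'   `TRUE`; unannotated exons appear in no transcript and exist only to be
#'   realized by read patterns, emulating exons missing from the
#'   annotation).
#' @param transcripts Named list defining each transcript as `"all"` (all
#'   annotated exons), `list(exclude = c(...))` (annotated exons minus these
#'   indices), or an explicit integer vector of exon indices.
#' @param gene_name Display name.
#' @return A `scenario_gene` list.
#' @export
scenario_gene <- function(gene_id, chrom, strand, exons, transcripts,
                          gene_name = gene_id) {
  exons <- as.data.frame(exons)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (is.null(exons$annotated)) exons$annotated <- TRUE
  stopifnot(all(exons$start < exons$end), !is.unsorted(exons$start),
            length(transcripts) >= 1, !is.null(names(transcripts)))
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("scenario gene ", gene_id, " has overlapping exons")
  ann_idx <- which(exons$annotated)
  transcripts <- lapply(transcripts, function(t) {
    idx <- if (identical(t, "all")) ann_idx
    else if (is.list(t) && !is.null(t$exclude)) setdiff(ann_idx, t$exclude)
    else as.integer(unlist(t))
    if (!all(idx %in% seq_len(nrow(exons))))
      stop("transcript references undefined exon index in gene ", gene_id)
    sort(idx)
  })
  list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
       strand = strand, exons = exons, transcripts = transcripts)
}

#' Convenience builder for a regular multi-exon gene
#'
#' Lays out `n_exons` equal-sized exons separated by equal introns, the toy
#' counterpart of a large repetitive muscle gene.
#'
#' @param gene_id Gene id.
#' @param n_exons Number of exons.
#' @param exon_len,intron_len Sizes in bases.
#' @param offset Genomic start of the first exon.
#' @param chrom,strand Location.
#' @param transcripts As in [scenario_gene()].
#' @param unannotated Integer indices of exons to mark unannotated.
#' @return A `scenario_gene`.
#' @export
regular_gene <- function(gene_id, n_exons, exon_len, intron_len, offset = 1000,
                         chrom = "chrS", strand = "+",
                         transcripts = list(TX_ALL = "all"),
                         unannotated = integer(0)) {
  starts <- offset + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  exons <- data.frame(start = starts, end = starts + exon_len,
                      annotated = !(seq_len(n_exons) %in% unannotated))
  scenario_gene(gene_id, chrom, strand, exons, transcripts)
}

resolve_pattern_exons <- function(gene, pat) {
  if (!is.null(pat$transcript)) {
    if (is.null(gene$transcripts[[pat$transcript]]))
      stop("pattern references undefined transcript ", pat$transcript)
    gene$transcripts[[pat$transcript]]
  } else sort(as.integer(unlist(pat$exons)))
}

pattern_fl_counts <- function(pat) {
  n <- as.integer(pat$consensus)
  if (!is.null(pat$fl_total)) {
    base <- as.integer(pat$fl_total) %/% n
    extra <- as.integer(pat$fl_total) %% n
    base + as.integer(seq_len(n) <= extra)
  } else rep(as.integer(if (is.null(pat$fl_per_read)) 1L else pat$fl_per_read), n)
}

#' Assemble and validate a synthetic scenario
#'
#' @param genes List of [scenario_gene()] objects.
#' @param samples Named list: sample -> list of pattern specs, each a list
#'   with `gene`, either `transcript` or `exons` (indices), `consensus`
#'   (reads), and `fl_total` (distributed as evenly as possible across the
#'   consensus reads) or `fl_per_read`.
#' @param priming_sites data.frame (`chrom`, `pos`) of genomic A-run
#'   positions, or `NULL`.
#' @param size_window Size-selection window in bases (default `c(5000,
#'   10000)`).
#' @param internal_priming_prob Probability that an over-window transcript is
#'   3'-anchored at an internal priming site instead of the poly(A) end.
#' @param noise Per-base substitution rate (default 0; CIGARs stay exact).
#' @param chrom_lengths Optional named lengths; otherwise derived.
#' @param name Scenario name.
#' @return Object of class `sim_scenario`.
#' @export
scenario <- function(genes, samples, priming_sites = NULL,
                     size_window = c(5000, 10000),
                     internal_priming_prob = 0.5, noise = 0,
                     chrom_lengths = NULL, name = "scenario") {
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  stopifnot(length(samples) >= 1, !is.null(names(samples)))
  for (s in names(samples)) {
    for (pat in samples[[s]]) {
      if (is.null(pat$gene) || is.null(genes[[pat$gene]]))
        stop("sample ", s, ": pattern references undefined gene")
      idx <- resolve_pattern_exons(genes[[pat$gene]], pat)
      if (length(idx) == 0) stop("sample ", s, ": empty exon pattern")
      if (is.null(pat$consensus) || pat$consensus < 0)
        stop("sample ", s, ": pattern needs a consensus read count")
    }
  }
  if (!is.null(priming_sites)) priming_sites <- as.data.frame(priming_sites)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- integer(0)
    for (g in genes) {
      need <- max(g$exons$end) + 1000L
      chrom_lengths[g$chrom] <- max(need, chrom_lengths[g$chrom], na.rm = TRUE)
    }
    if (!is.null(priming_sites)) {
      for (i in seq_len(nrow(priming_sites))) {
        ch <- priming_sites$chrom[i]
        chrom_lengths[ch] <- max(priming_sites$pos[i] + 100L,
                                 chrom_lengths[ch], na.rm = TRUE)
      }
    }
  }
  structure(list(name = name, genes = genes, samples = samples,
                 priming_sites = priming_sites,
                 size_window = as.integer(size_window),
                 internal_priming_prob = internal_priming_prob, noise = noise,
                 chrom_lengths = chrom_lengths),
            class = "sim_scenario")
}

#' Load a scenario from a YAML file
#'
#' The YAML mirrors the [scenario()] arguments; gene exons are given as
#' `[start, end]` pairs or `{start:, end:, annotated:}` maps.
#'
#' @param path YAML file.
#' @return A `sim_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$genes) || is.null(y$samples))
    stop("scenario file must define 'genes' and 'samples': ", path)
  genes <- lapply(names(y$genes), function(gid) {
    g <- y$genes[[gid]]
    ex <- do.call(rbind, lapply(g$exons, function(e) {
      if (is.null(names(e))) data.frame(start = e[[1]], end = e[[2]], annotated = TRUE)
      else data.frame(start = e$start, end = e$end,
                      annotated = !isFALSE(e$annotated))
    }))
    scenario_gene(gid, g$chrom, if (is.null(g$strand)) "+" else g$strand, ex,
                  g$transcripts,
                  gene_name = if (is.null(g$gene_name)) gid else g$gene_name)
  })
  priming <- if (!is.null(y$priming_sites))
    do.call(rbind, lapply(y$priming_sites, as.data.frame)) else NULL
  scenario(genes, y$samples, priming_sites = priming,
           size_window = if (is.null(y$size_window)) c(5000, 10000) else unlist(y$size_window),
           internal_priming_prob = if (is.null(y$internal_priming_prob)) 0.5 else y$internal_priming_prob,
           noise = if (is.null(y$noise)) 0 else y$noise,
           chrom_lengths = if (is.null(y$chrom_lengths)) NULL else unlist(y$chrom_lengths),
           name = if (is.null(y$name)) "scenario" else y$name)
}

scrub_a_runs <- function(chars) {
  # break every accidental run of >= 8 A's by substituting each 8th A
  r <- rle(chars == "A")
  pos <- cumsum(r$lengths)
  for (i in which(r$values & r$lengths >= 8)) {
    run_start <- pos[i] - r$lengths[i] + 1L
    hit <- seq(run_start + 7L, pos[i], by = 8L)
    chars[hit] <- "C"
  }
  chars
}

#' Build the toy genome for a scenario
#'
#' Seeded random background sequence with >= 8-base A-runs planted at the
#' scenario's internal priming sites and accidental A-runs scrubbed
#' everywhere else, so oligo(dT) priming can only anchor where the scenario
#' says it can.
#'
#' @param scn A `sim_scenario`.
#' @param seed Integer seed; the same seed yields byte-identical sequence.
#' @param a_run_length Length of each planted A-run (default 12).
#' @return A [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
build_genome <- function(scn, seed = 1, a_run_length = 12) {
  set.seed(seed)
  seqs <- lapply(sort(names(scn$chrom_lengths)), function(ch) {
    n <- scn$chrom_lengths[[ch]]
    chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    chars <- scrub_a_runs(chars)
    sites <- scn$priming_sites
    if (!is.null(sites)) {
      sites <- sites[sites$chrom == ch, , drop = FALSE]
      if (nrow(sites) > 1) {
        d <- diff(sort(sites$pos))
        if (any(d < a_run_length))
          stop("planted A-runs overlap on ", ch)
      }
      for (p in sites$pos) {
        if (p + a_run_length > n) stop("priming site beyond chromosome end: ", p)
        chars[(p + 1):(p + a_run_length)] <- "A"  # pos is 0-based
      }
    }
    paste(chars, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- sort(names(scn$chrom_lengths))
  genome
}

#' Write the scenario annotation as GTF
#'
#' Gene, transcript and exon features with GENCODE-style attributes;
#' unannotated exons are omitted (they are what novel-exon discovery must
#' find). Coordinates are written 1-based inclusive.
#'
#' @param scn A `sim_scenario`.
#' @param path Output GTF.
#' @return `path`, invisibly.
#' @export
write_scenario_gtf <- function(scn, path) {
  lines <- character(0)
  for (g in scn$genes) {
    ann <- g$exons[g$exons$annotated, , drop = FALSE]
    gl <- sprintf(
      "%s\tpsiphase_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
      g$chrom, min(ann$start) + 1L, max(ann$end), g$strand, g$gene_id, g$gene_name)
    lines <- c(lines, gl)
    for (tx in names(g$transcripts)) {
      idx <- g$transcripts[[tx]]
      ex <- g$exons[idx, , drop = FALSE]
      attr_str <- sprintf("gene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
                          g$gene_id, tx, g$gene_name)
      lines <- c(lines, sprintf(
        "%s\tpsiphase_sim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        g$chrom, min(ex$start) + 1L, max(ex$end), g$strand, attr_str))
      lines <- c(lines, sprintf(
        "%s\tpsiphase_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
        g$chrom, ex$start + 1L, ex$end, g$strand, attr_str))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

truncate_blocks <- function(blocks, strand, size_window, sites,
                            internal_priming_prob) {
  total <- sum(blocks[, 2] - blocks[, 1])
  truncated <- FALSE
  if (total > size_window[2]) {
    # 3' anchoring: poly(A) end, or an internal A-run within 0-20 bases
    # downstream of the new 3' read end
    usable <- if (is.null(sites)) integer(0) else sites$pos
    if (strand == "+") usable <- usable[usable > blocks[1, 1] & usable < blocks[nrow(blocks), 2]]
    else usable <- usable[usable > blocks[1, 1] & usable < blocks[nrow(blocks), 2]]
    if (length(usable) && stats::runif(1) < internal_priming_prob) {
      site <- if (length(usable) == 1) usable else sample(usable, 1)
      offset <- sample(0:20, 1)
      if (strand == "+") {
        cut <- site - offset
        blocks <- blocks[blocks[, 1] < cut, , drop = FALSE]
        if (nrow(blocks)) blocks[nrow(blocks), 2] <- min(blocks[nrow(blocks), 2], cut)
      } else {
        cut <- site + offset
        blocks <- blocks[blocks[, 2] > cut, , drop = FALSE]
        if (nrow(blocks)) blocks[1, 1] <- max(blocks[1, 1], cut)
      }
      truncated <- TRUE
    }
    # 5'-trim into the size window, anchored at the 3' end
    if (nrow(blocks)) {
      lens <- blocks[, 2] - blocks[, 1]
      if (sum(lens) > size_window[2]) {
        if (strand == "+") {
          # keep the largest 3'-anchored suffix, partially trimming its
          # 5'-most block so the read is exactly window-sized
          suffix <- rev(cumsum(rev(lens)))
          first <- max(which(suffix > size_window[2]))
          blocks <- blocks[first:nrow(blocks), , drop = FALSE]
          excess <- sum(blocks[, 2] - blocks[, 1]) - size_window[2]
          blocks[1, 1] <- blocks[1, 1] + excess
        } else {
          prefix <- cumsum(lens)
          last <- min(which(prefix > size_window[2]))
          blocks <- blocks[1:last, , drop = FALSE]
          excess <- sum(blocks[, 2] - blocks[, 1]) - size_window[2]
          blocks[nrow(blocks), 2] <- blocks[nrow(blocks), 2] - excess
        }
        truncated <- TRUE
      }
      blocks <- blocks[blocks[, 1] < blocks[, 2], , drop = FALSE]
    }
  }
  list(blocks = blocks, truncated = truncated)
}

blocks_to_cigar <- function(blocks) {
  n <- nrow(blocks)
  ops <- sprintf("%dM", blocks[, 2] - blocks[, 1])
  if (n > 1) {
    gaps <- sprintf("%dN", blocks[-1, 1] - blocks[-n, 2])
    paste0(paste0(ops[-n], gaps, collapse = ""), ops[n])
  } else ops
}

#' Simulate aligned consensus reads for every sample
#'
#' Each pattern spec is rendered as `consensus` SAM records whose aligned
#' blocks realize the pattern's exon chain (M/N CIGARs, exact at `noise =
#' 0`), with FL multiplicities written to a per-sample sidecar TSV and
#' encoded in the read names (`f<k>p0`). Mature transcripts longer than the
#' size window are 3'-anchored at the poly(A) end or, with the scenario's
#' internal-priming probability, 0-20 bases upstream of a planted genomic
#' A-run, then 5'-trimmed into the window.
#'
#' @param scn A `sim_scenario`.
#' @param genome [Biostrings::DNAStringSet] from [build_genome()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return Named list with `sam` and `sidecar` path vectors keyed by sample.
#' @export
simulate_reads <- function(scn, genome, out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
  sam_paths <- sidecar_paths <- character(0)
  short_warned <- FALSE
  for (sample in names(scn$samples)) {
    recs <- character(0)
    sidecar <- character(0)
    idx <- 0L
    for (pat in scn$samples[[sample]]) {
      g <- scn$genes[[pat$gene]]
      exon_idx <- resolve_pattern_exons(g, pat)
      chain <- as.matrix(g$exons[exon_idx, c("start", "end")])
      fls <- pattern_fl_counts(pat)
      sites <- scn$priming_sites
      if (!is.null(sites)) sites <- sites[sites$chrom == g$chrom, , drop = FALSE]
      for (k in seq_len(pat$consensus)) {
        idx <- idx + 1L
        tb <- truncate_blocks(chain, g$strand, scn$size_window, sites,
                              scn$internal_priming_prob)
        blocks <- tb$blocks
        if (nrow(blocks) == 0) { blocks <- chain; }
        rlen <- sum(blocks[, 2] - blocks[, 1])
        if (!tb$truncated && rlen < scn$size_window[1] && !short_warned) {
          warning("scenario emits full-length reads shorter than the size window")
          short_warned <- TRUE
        }
        seq <- paste(vapply(seq_len(nrow(blocks)), function(b)
          as.character(Biostrings::subseq(genome[[g$chrom]],
                                          blocks[b, 1] + 1L, blocks[b, 2])), ""),
          collapse = "")
        if (scn$noise > 0) {
          nmut <- stats::rbinom(1, nchar(seq), scn$noise)
          if (nmut > 0) {
            at <- sample(nchar(seq), nmut)
            ch <- strsplit(seq, "")[[1]]
            ch[at] <- vapply(ch[at], function(x)
              sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
            seq <- paste(ch, collapse = "")
          }
        }
        qname <- sprintf("%s/%s/c%05d/f%dp0/%d", sample, g$gene_id, idx,
                         fls[k], rlen)
        flag <- if (g$strand == "-") 16L else 0L
        recs <- c(recs, paste(qname, flag, g$chrom, blocks[1, 1] + 1L, 60L,
                              blocks_to_cigar(blocks), "*", 0L, 0L, seq, "*",
                              sep = "\t"))
        sidecar <- c(sidecar, sprintf("%s\t%d", qname, fls[k]))
      }
    }
    sam <- file.path(out_dir, paste0(sample, ".sam"))
    writeLines(c(header, recs), sam)
    sc <- file.path(out_dir, paste0(sample, ".fl.tsv"))
    writeLines(sidecar, sc)
    sam_paths[sample] <- sam
    sidecar_paths[sample] <- sc
  }
  list(sam = sam_paths, sidecar = sidecar_paths)
}

scenario_part_table <- function(g) {
  # every scenario exon (annotated or not) is disjoint, so the flattened
  # metatranscript over the full exon set has one part per exon
  data.frame(part_index = seq_len(nrow(g$exons)), start = g$exons$start,
             end = g$exons$end,
             source = ifelse(g$exons$annotated, "annotated", "novel"))
}

#' Expected PSI and phase tables for a scenario, by exact arithmetic
#'
#' Computes, without touching any read, what the pipeline must report on the
#' scenario's noise-free reads: per (sample, exonic part) matching/total
#' consensus and FL counts with PSI, and, when `targets` is given, per-sample
#' phase pattern counts and percentages. A pattern contains a part when the
#' part interval lies within one of its exons, and spans it when the
#' pattern's genomic extent encloses it. Only valid when every pattern's
#' mature transcript fits the size window (no stochastic truncation); errors
#' otherwise.
#'
#' @param scn A `sim_scenario`.
#' @param targets Optional [target_exon_set] for the phase truth.
#' @return List with data.frames `psi` and (if requested) `phase`.
#' @export
truth_table <- function(scn, targets = NULL) {
  for (s in names(scn$samples)) for (pat in scn$samples[[s]]) {
    g <- scn$genes[[pat$gene]]
    ex <- g$exons[resolve_pattern_exons(g, pat), , drop = FALSE]
    if (sum(ex$end - ex$start) > scn$size_window[2])
      stop("truth_table requires all transcripts within the size window ",
           "(pattern in sample ", s, " exceeds it)")
  }
  psi_rows <- list()
  for (sample in names(scn$samples)) {
    pats <- scn$samples[[sample]]
    for (gid in names(scn$genes)) {
      g <- scn$genes[[gid]]
      parts <- scenario_part_table(g)
      for (i in seq_len(nrow(parts))) {
        mc <- tc <- mf <- tf <- 0L
        for (pat in pats) {
          if (!identical(pat$gene, gid)) next
          idx <- resolve_pattern_exons(g, pat)
          fl <- sum(pattern_fl_counts(pat))
          contains <- i %in% idx
          spans <- min(g$exons$start[idx]) <= parts$start[i] &&
            max(g$exons$end[idx]) >= parts$end[i]
          if (!spans) next
          tc <- tc + as.integer(pat$consensus); tf <- tf + fl
          if (contains) { mc <- mc + as.integer(pat$consensus); mf <- mf + fl }
        }
        psi_rows[[length(psi_rows) + 1L]] <- data.frame(
          gene_id = gid, part_index = parts$part_index[i],
          part_id = format_part_number(parts$part_index[i]),
          start = parts$start[i], end = parts$end[i], source = parts$source[i],
          sample = sample, matching_consensus = mc, total_consensus = tc,
          matching_fl = mf, total_fl = tf,
          psi = if (tf > 0) 100 * mf / tf else NA_real_)
      }
    }
  }
  psi <- do.call(rbind, psi_rows)
  psi <- psi[order(psi$gene_id, psi$part_index, psi$sample), , drop = FALSE]
  rownames(psi) <- NULL
  out <- list(psi = psi)
  if (!is.null(targets)) {
    ph_rows <- list()
    for (sample in names(scn$samples)) {
      tally <- list()
      for (pat in scn$samples[[sample]]) {
        g <- scn$genes[[pat$gene]]
        if (!identical(g$chrom, targets$chrom)) next
        idx <- resolve_pattern_exons(g, pat)
        ex <- g$exons[idx, , drop = FALSE]
        if (min(ex$start) > targets$region[1] || max(ex$end) < targets$region[2])
          next
        v <- vapply(seq_along(targets$labels), function(i)
          as.integer(any(ex$start <= targets$starts[i] & ex$end >= targets$ends[i])),
          integer(1))
        key <- pattern_string(v)
        if (is.null(tally[[key]])) tally[[key]] <- c(0L, 0L)
        tally[[key]] <- tally[[key]] + c(as.integer(pat$consensus),
                                         sum(pattern_fl_counts(pat)))
      }
      if (length(tally) == 0) next
      df <- data.frame(sample = sample, pattern = names(tally),
                       consensus_count = vapply(tally, `[`, 0L, 1),
                       fl_count = vapply(tally, `[`, 0L, 2))
      df$percent <- 100 * df$fl_count / sum(df$fl_count)
      df <- df[order(-df$fl_count, df$pattern), , drop = FALSE]
      ph_rows[[sample]] <- df
    }
    ph <- if (length(ph_rows)) do.call(rbind, ph_rows) else
      data.frame(sample = character(0), pattern = character(0),
                 consensus_count = integer(0), fl_count = integer(0),
                 percent = numeric(0))
    rownames(ph) <- NULL
    out$phase <- ph
  }
  out
}

#' Render a scenario into a complete on-disk fixture
#'
#' Writes the genome FASTA, GTF annotation, one SAM and one FL sidecar per
#' sample, and the truth tables.
#'
#' @param scn A `sim_scenario`.
#' @param out_dir Output directory.
#' @param seed Integer seed for genome and reads.
#' @param targets Optional [target_exon_set] for the phase truth.
#' @return Named list of paths (`fasta`, `gtf`, `sam`, `sidecar`,
#'   `truth_psi`, optionally `truth_phase`) plus the in-memory `truth` list.
#' @export
simulate_fixture <- function(scn, out_dir, seed = 1, targets = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- build_genome(scn, seed = seed)
  fasta <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta)
  gtf <- file.path(out_dir, "annotation.gtf")
  write_scenario_gtf(scn, gtf)
  reads <- simulate_reads(scn, genome, out_dir, seed = seed + 1L)
  truth <- truth_table(scn, targets = targets)
  tp <- file.path(out_dir, "truth_psi.tsv")
  utils::write.table(truth$psi, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- list(fasta = fasta, gtf = gtf, sam = reads$sam,
                sidecar = reads$sidecar, truth_psi = tp, truth = truth)
  if (!is.null(targets)) {
    tph <- file.path(out_dir, "truth_phase.tsv")
    utils::write.table(truth$phase, tph, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truth_phase <- tph
  }
  paths
}
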