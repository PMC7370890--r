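# The scenario simulator: determinism, priming-site planting, read geometry,
# truncation behaviour and truth-table closure.

test_that("genome building is seed-deterministic and controls A-runs", {
  g <- regular_gene("G", n_exons = 3, exon_len = 200, intron_len = 100)
  scn <- scenario(list(g), samples = list(
    s = list(list(gene = "G", transcript = "TX_ALL", consensus = 1))),
    priming_sites = data.frame(chrom = "chrS", pos = 5000),
    chrom_lengths = c(chrS = 8000))
  g1 <- build_genome(scn, seed = 11)
  g2 <- build_genome(scn, seed = 11)
  expect_equal(as.character(g1), as.character(g2))
  seq <- as.character(g1[["chrS"]])
  # planted run begins exactly at the stated 0-based position
  expect_equal(substr(seq, 5001, 5012), strrep("A", 12))
  # and is the only run of >= 8 A's
  runs <- gregexpr("A{8,}", seq)[[1]]
  expect_equal(as.integer(runs), 5001)
  g3 <- build_genome(scn, seed = 12)
  expect_false(identical(as.character(g1), as.character(g3)))
  # without priming sites there is no long A-run anywhere
  scn0 <- scenario(list(g), samples = scn$samples,
                   chrom_lengths = c(chrS = 8000))
  seq0 <- as.character(build_genome(scn0, seed = 11)[["chrS"]])
  expect_equal(gregexpr("A{8,}", seq0)[[1]][1], -1L)
})

test_that("simulated SAM records reproduce the requested exon chains exactly", {
  scn <- toy_cassette_scenario()
  dir <- withr::local_tempdir()
  fx <- simulate_fixture(scn, dir, seed = 5)
  # fixture is byte-deterministic under a fixed seed
  dir2 <- withr::local_tempdir()
  fx2 <- simulate_fixture(scn, dir2, seed = 5)
  for (f in c("fasta", "gtf")) {
    expect_equal(readLines(fx[[f]]), readLines(fx2[[f]]))
  }
  expect_equal(readLines(fx$sam[["a"]]), readLines(fx2$sam[["a"]]))

  reads <- load_reads(fx$sam[["a"]], "a", fl_sidecar = fx$sidecar[["a"]])
  expect_length(reads, 10)
  g <- scn$genes$G1
  chain_all <- as.matrix(g$exons[g$transcripts$TX_ALL, c("start", "end")])
  chain_skip <- as.matrix(g$exons[g$transcripts$TX_SKIP5, c("start", "end")])
  for (r in reads) {
    expect_true(identical(unname(r$blocks), unname(chain_all)) ||
                  identical(unname(r$blocks), unname(chain_skip)))
  }
  # FL counts distributed to the requested totals via the sidecar
  expect_equal(sum(vapply(reads, `[[`, 0L, "fl_count")), 80)
  # read names carry the same FL multiplicity as the sidecar
  for (r in reads) expect_equal(parse_fl_count(r$read_id), r$fl_count)
  # aligned sequence matches the genome at the aligned blocks (noise 0)
  genome <- Biostrings::readDNAStringSet(fx$fasta)
  names(genome) <- sub(" .*", "", names(genome))
  sam_lines <- grep("^[^@]", readLines(fx$sam[["a"]]), value = TRUE)
  f1 <- strsplit(sam_lines[1], "\t")[[1]]
  blocks <- cigar_to_blocks(as.integer(f1[4]) - 1L, f1[6])
  ref <- paste(vapply(seq_len(nrow(blocks)), function(i)
    as.character(Biostrings::subseq(genome[[f1[3]]], blocks[i, 1] + 1,
                                    blocks[i, 2])), ""), collapse = "")
  expect_equal(f1[10], ref)
})

test_that("the pipeline recovers the truth table exactly on noise-free fixtures", {
  scn <- toy_cassette_scenario()
  dir <- withr::local_tempdir()
  targets <- target_exon_set("chrS", scn$genes$G1$exons$start[c(3, 5)],
                             scn$genes$G1$exons$end[c(3, 5)], c("3", "5"))
  fx <- simulate_fixture(scn, dir, seed = 21, targets = targets)
  genes <- load_gtf(fx$gtf)
  flat <- flatten_gene(genes$G1)
  rbs <- lapply(stats::setNames(nm = names(fx$sam)), function(s)
    load_reads(fx$sam[[s]], s, fl_sidecar = fx$sidecar[[s]]))
  psi <- psi_table(rbs, flat)
  expect_equal(psi, fx$truth$psi)
  rep <- phase(rbs, targets)
  expect_equal(rep[, c("sample", "pattern", "consensus_count", "fl_count", "percent")],
               fx$truth$phase[, c("sample", "pattern", "consensus_count",
                                  "fl_count", "percent")],
               ignore_attr = TRUE)
})

test_that("unannotated scenario exons are found by discovery and restore truth indexing", {
  g <- scenario_gene("G", "chrS", "+",
                     data.frame(start = c(1000, 2000, 3000), end = c(1800, 2600, 3800),
                                annotated = c(TRUE, FALSE, TRUE)),
                     transcripts = list(TX = "all"))
  scn <- scenario(list(g), samples = list(
    s = list(list(gene = "G", exons = 1:3, consensus = 6, fl_total = 30),
             list(gene = "G", exons = c(1, 3), consensus = 4, fl_total = 10))),
    size_window = c(1000, 10000))
  dir <- withr::local_tempdir()
  fx <- simulate_fixture(scn, dir, seed = 3)
  genes <- load_gtf(fx$gtf)
  # the unannotated exon is absent from the GTF
  expect_equal(nrow(genes$G$transcripts$TX), 2)
  flat <- flatten_gene(genes$G)
  reads <- load_reads(fx$sam[["s"]], "s", fl_sidecar = fx$sidecar[["s"]])
  flat2 <- discover_novel_exons(reads, flat, min_support_reads = 5)
  expect_equal(flat2$parts$source, c("annotated", "novel", "annotated"))
  expect_equal(flat2$parts$start, c(1000, 2000, 3000))
  psi <- psi_table(list(s = reads), flat2)
  expect_equal(psi, fx$truth$psi)
  # the novel part's PSI reflects 30 of 40 FL reads including it
  expect_equal(psi$psi[psi$part_index == 2], 75)
})

test_that("oversized transcripts are truncated at priming sites within 20 bases", {
  # one 30 kb-spanning gene, window max 6 kb, priming site in intron 5
  g <- regular_gene("BIG", n_exons = 12, exon_len = 1000, intron_len = 1500,
                    offset = 1000)
  site <- g$exons$start[5] + 700  # A-rich stretch inside exon 5
  scn <- scenario(list(g), samples = list(
    s = list(list(gene = "BIG", transcript = "TX_ALL", consensus = 30))),
    priming_sites = data.frame(chrom = "chrS", pos = site),
    size_window = c(5000, 6000), internal_priming_prob = 0.5)
  genome <- build_genome(scn, seed = 2)
  dir <- withr::local_tempdir()
  paths <- simulate_reads(scn, genome, dir, seed = 2)
  reads <- load_reads(paths$sam[["s"]], "s", fl_sidecar = paths$sidecar[["s"]])
  ends <- vapply(reads, function(r) r$span[2], numeric(1))
  primed <- reads[ends < max(g$exons$end)]
  full3p <- reads[ends == max(g$exons$end)]
  expect_gt(length(primed), 0)
  expect_gt(length(full3p), 0)
  # internally primed reads stop 0-20 bases upstream of the A-run
  for (r in primed) {
    expect_lte(r$span[2], site)
    expect_gte(r$span[2], site - 20)
  }
  # every read obeys the size-selection maximum
  lens <- vapply(reads, function(r) sum(r$blocks[, 2] - r$blocks[, 1]), numeric(1))
  expect_true(all(lens <= 6000))
  # truncated reads are non-informative for parts downstream of the cut and
  # are rejected when phasing a region they do not cover
  r <- primed[[1]]
  expect_equal(classify_read_for_part(r, g$exons$start[6], g$exons$end[6]),
               "non_informative")
  targets <- target_exon_set("chrS", g$exons$start[c(1, 12)],
                             g$exons$end[c(1, 12)], c("1", "12"))
  expect_null(read_pattern(r, targets))
  # adding truncated reads does not change pattern counts over regions they
  # cannot span
  base_reads <- list(make_read(as.matrix(g$exons[, c("start", "end")]),
                               fl = 4, id = "full"))
  rep0 <- phase(list(s = base_reads), targets)
  rep1 <- phase(list(s = c(base_reads, primed)), targets)
  expect_equal(rep0[, c("pattern", "fl_count")], rep1[, c("pattern", "fl_count")])
})

test_that("truth_table refuses scenarios with stochastic truncation", {
  g <- regular_gene("BIG", n_exons = 12, exon_len = 1000, intron_len = 1500)
  scn <- scenario(list(g), samples = list(
    s = list(list(gene = "BIG", transcript = "TX_ALL", consensus = 2))),
    size_window = c(5000, 6000))
  expect_error(truth_table(scn), "size window")
})

test_that("scenarios round-trip through YAML", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: demo",
    "size_window: [4000, 10000]",
    "genes:",
    "  G1:",
    "    chrom: chrS",
    "    strand: '+'",
    "    exons:",
    "      - [1000, 1800]",
    "      - {start: 2500, end: 3300}",
    "      - {start: 4000, end: 4800, annotated: false}",
    "      - [5500, 6300]",
    "    transcripts:",
    "      TX_ALL: all",
    "      TX_NO2: {exclude: [2]}",
    "samples:",
    "  heart:",
    "    - {gene: G1, transcript: TX_NO2, consensus: 3, fl_total: 12}",
    "    - {gene: G1, exons: [1, 2, 3, 4], consensus: 2, fl_per_read: 4}",
    "priming_sites:",
    "  - {chrom: chrS, pos: 7000}"), yml)
  scn <- read_scenario(yml)
  expect_s3_class(scn, "sim_scenario")
  expect_equal(scn$genes$G1$transcripts$TX_NO2, c(1L, 4L))
  expect_false(scn$genes$G1$exons$annotated[3])
  tr <- truth_table(scn)
  # exon 2 is matched only by the explicit pattern (8 of 20 FL reads)
  expect_equal(tr$psi$psi[tr$psi$part_index == 2], 100 * 8 / 20)
  expect_error(suppressWarnings(
    read_scenario(withr::local_tempfile(fileext = ".yaml"))),
    "cannot")  # unreadable/missing file errors out
})
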