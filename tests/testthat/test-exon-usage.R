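# Read-vs-part classification, novel-exon discovery, PSI and the filter
# cascade.

test_that("classification separates matching, skipping and non-informative reads", {
  part <- c(200, 300)
  # block covers the part exactly
  expect_equal(classify_read_for_part(
    make_read(rbind(c(0, 100), c(200, 300))), part[1], part[2]), "matching")
  # part sits in the read's intron
  expect_equal(classify_read_for_part(
    make_read(rbind(c(0, 100), c(400, 500))), part[1], part[2]), "skipping")
  # read truncates inside the part: neither containment nor a clean skip
  expect_equal(classify_read_for_part(
    make_read(rbind(c(0, 250))), part[1], part[2]), "non_informative")
  # read entirely upstream of the part
  expect_equal(classify_read_for_part(
    make_read(rbind(c(0, 100))), part[1], part[2]), "non_informative")
  # boundary wobble within the slop still matches
  expect_equal(classify_read_for_part(
    make_read(rbind(c(205, 296))), part[1], part[2], boundary_slop = 10),
    "matching")
  expect_equal(classify_read_for_part(
    make_read(rbind(c(215, 300))), part[1], part[2], boundary_slop = 10),
    "non_informative")
  # different chromosome is never informative
  expect_equal(classify_read_for_part(
    make_read(rbind(c(200, 300)), chrom = "other"), part[1], part[2],
    chrom = "chrS"), "non_informative")
})

test_that("novel exons are recovered at modal boundaries above the support threshold", {
  g <- gene_model("g", "chrS", "+", list(
    t1 = data.frame(start = c(0, 300), end = c(100, 400))))
  flat <- flatten_gene(g)
  mk_extra <- function(s, id) make_read(rbind(c(0, 100), c(s, 180), c(300, 400)),
                                        id = id)
  # 6 supporting reads, unanimous boundaries
  reads <- lapply(1:6, function(i) mk_extra(150, paste0("r", i)))
  out <- discover_novel_exons(reads, flat, min_support_reads = 5)
  nov <- out$parts[out$parts$source == "novel", ]
  expect_equal(nrow(nov), 1)
  expect_equal(c(nov$start, nov$end), c(150, 180))
  # parts renumbered by coordinate: novel part is number 2 of 3
  expect_equal(nov$part_index, 2)
  expect_equal(nrow(out$parts), 3)

  # below support: unchanged
  out2 <- discover_novel_exons(reads[1:3], flat, min_support_reads = 5)
  expect_equal(out2$parts, flat$parts)

  # modal start wins 4:2
  reads3 <- c(lapply(1:4, function(i) mk_extra(150, paste0("a", i))),
              lapply(1:2, function(i) mk_extra(152, paste0("b", i))))
  out3 <- discover_novel_exons(reads3, flat, min_support_reads = 5)
  nov3 <- out3$parts[out3$parts$source == "novel", ]
  expect_equal(c(nov3$start, nov3$end), c(150, 180))
})

test_that("PSI is the FL-weighted matching fraction over spanning reads", {
  g <- gene_model("g", "chrS", "+", list(
    t1 = data.frame(start = c(0, 200, 400), end = c(100, 300, 500)),
    t2 = data.frame(start = c(0, 400), end = c(100, 500))))
  flat <- flatten_gene(g)
  incl <- rbind(c(0, 100), c(200, 300), c(400, 500))
  skip <- rbind(c(0, 100), c(400, 500))
  # the printed middle-exon example: 576 matching FL vs 286 skipping FL
  reads <- c(
    lapply(1:4, function(i) make_read(incl, fl = 144, id = paste0("m", i))),
    lapply(1:2, function(i) make_read(skip, fl = 143, id = paste0("s", i))))
  psi <- psi_table(list(edl = reads), flat)
  mid <- psi[psi$part_index == 2, ]
  expect_equal(mid$matching_fl, 576)
  expect_equal(mid$total_fl, 862)
  expect_equal(round(mid$psi), 67)
  expect_equal(mid$matching_consensus, 4)
  expect_equal(mid$total_consensus, 6)
  # zero inclusion gives PSI 0, not NA
  psi0 <- psi_table(list(heart = lapply(1:3, function(i)
    make_read(skip, fl = 189, id = paste0("h", i)))), flat)
  expect_equal(psi0$psi[psi0$part_index == 2], 0)
  expect_equal(psi0$total_fl[psi0$part_index == 2], 567)
  # constitutive flanking exons sit at PSI 100
  expect_equal(psi$psi[psi$part_index %in% c(1, 3)], c(100, 100))
  # no informative reads at all -> NA
  far <- list(s = list(make_read(rbind(c(5000, 5100)), id = "far")))
  expect_true(all(is.na(psi_table(far, flat)$psi)))
})

test_that("PSI is bounded and monotone under added reads", {
  g <- gene_model("g", "chrS", "+", list(
    t1 = data.frame(start = c(0, 200, 400), end = c(100, 300, 500)),
    t2 = data.frame(start = c(0, 400), end = c(100, 500))))
  flat <- flatten_gene(g)
  incl <- rbind(c(0, 100), c(200, 300), c(400, 500))
  skip <- rbind(c(0, 100), c(400, 500))
  set.seed(99)
  reads <- list()
  included <- logical(0)
  for (i in 1:40) {
    included[i] <- runif(1) < 0.5
    blocks <- if (included[i]) incl else skip
    reads[[i]] <- make_read(blocks, fl = sample(1:20, 1), id = paste0("r", i))
    psi <- psi_table(list(s = reads), flat)
    expect_true(all(psi$psi >= 0 & psi$psi <= 100, na.rm = TRUE))
    expect_true(all(psi$matching_fl <= psi$total_fl))
    expect_true(all(psi$matching_consensus <= psi$total_consensus))
    if (i > 1) {
      prev <- psi_table(list(s = reads[-i]), flat)
      d <- psi$psi[psi$part_index == 2] - prev$psi[prev$part_index == 2]
      if (included[i]) expect_gte(d, 0) else expect_lte(d, 0)
    }
  }
})

test_that("the candidate filter cascade reproduces the study thresholds", {
  mk_rec <- function(gene, part, sample, total, psi)
    data.frame(gene_id = gene, part_index = part,
               part_id = format_part_number(part), start = 0, end = 1,
               source = "annotated", sample = sample,
               matching_consensus = 0, total_consensus = total,
               matching_fl = round(psi), total_fl = 100, psi = psi)
  recs <- rbind(
    mk_rec("gPass", 1, "edl", 61, 66.8), mk_rec("gPass", 1, "sol", 90, 14.4),
    mk_rec("gSmall", 1, "edl", 50, 10), mk_rec("gSmall", 1, "sol", 50, 90),
    mk_rec("gFlat", 1, "edl", 40, 50), mk_rec("gFlat", 1, "sol", 40, 40),
    mk_rec("gThin", 1, "edl", 29, 0), mk_rec("gThin", 1, "sol", 35, 100))
  gene_cov <- c(gPass = 151, gSmall = 9, gFlat = 80, gThin = 64)
  cand <- filter_candidates(recs, gene_consensus = gene_cov)
  # gene below 10 consensus reads is excluded outright
  expect_false("gSmall" %in% cand$gene_id)
  # part needs >= 30x consensus in at least two samples
  expect_false("gThin" %in% cand$gene_id)
  # PSI 66.8 vs 14.4 passes the 20-point delta; 50 vs 40 fails
  expect_true(cand$passes[cand$gene_id == "gPass"])
  expect_equal(cand$max_psi_delta[cand$gene_id == "gPass"], 66.8 - 14.4)
  expect_false(cand$passes[cand$gene_id == "gFlat"])
})

test_that("the coverage report is deterministic and renders NA PSI", {
  g <- gene_model("g", "chrS", "+", list(
    t1 = data.frame(start = c(0, 200), end = c(100, 300))))
  flat <- flatten_gene(g)
  reads <- list(b = list(make_read(rbind(c(0, 100), c(200, 300)), fl = 3, id = "r1")),
                a = list(make_read(rbind(c(150, 260)), id = "r2")))
  psi <- psi_table(reads, flat)
  path <- withr::local_tempfile(fileext = ".tsv")
  coverage_report(psi, path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(psi = "character"), na.strings = "")
  expect_equal(names(tab)[1:3], c("gene_id", "part_index", "part_id"))
  # rows sorted by (gene, part, sample)
  expect_equal(tab$sample, c("a", "b", "a", "b"))
  expect_true("NA" %in% tab$psi)
  expect_true("100.0" %in% tab$psi)
  # empty input still writes a header-only file
  coverage_report(psi[0, ], path)
  expect_equal(length(readLines(path)), 1)
})
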