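# Packaged demonstration scenarios: desk-scale reconstructions of the three
# muscle-gene worked examples (a medium Nrap-like gene, a titin-like gene
# with a deep cassette exon, and a nebulin-like 3' region), with per-sample
# FL read totals chosen to match the published figures so every headline
# ratio can be recomputed end to end without sequencing data. Genes are laid
# out at toy scale (short exons/introns) but keep the real exon counts where
# the part numbering matters (EP 038, EP 129).

#' Built-in demonstration scenarios
#'
#' Returns a ready-to-simulate scenario (and, for phasing demos, its target
#' exon set) reproducing one of the study-style worked examples across
#' fast-twitch (EDL), slow-twitch (soleus) and cardiac muscle samples:
#'
#' * `"nrap_usage"` — 45-exon gene with cassette exon 38; exon-level PSI of
#'   the cassette is 576/862 FL reads in EDL, 377/2621 in soleus and 0/567
#'   in heart.
#' * `"nrap_phase"` — the same gene phased over its seven cassette exons;
#'   the exon-12-skipping isoform carries 541/555 FL reads in heart (97.5%),
#'   2177/2544 in soleus (85.6%), and the all-exon isoform 557/837 in EDL
#'   (66.5%).
#' * `"ttn_usage"` — 135-exon gene whose cassette exonic part 129 is
#'   included in 34/35 (soleus), 357/361 (EDL) and 84/232 (heart) FL reads.
#' * `"ttn_phase191"` — focused phasing of that cassette with its flanking
#'   exons: 64/198 FL reads include it in heart, 281/281 in EDL.
#' * `"ttn_phase312"` — a penultimate cassette exon spliced out of 249/997
#'   EDL and 25/2061 soleus FL reads but retained in all 375 cardiac reads.
#' * `"neb_phase"` — sixteen contiguous cassette exons (labelled 137-152);
#'   all sixteen are retained in 14/155 EDL and 733/817 soleus FL reads.
#'
#' @param name One of the scenario names above.
#' @return List with elements `scenario` (a `sim_scenario`) and `targets`
#'   (a [target_exon_set], or `NULL` for the exon-usage demos).
#' @export
demo_scenario <- function(name) {
  switch(
    name,
    nrap_usage = {
      g <- regular_gene("NrapD", n_exons = 45, exon_len = 120, intron_len = 200,
                        transcripts = list(NRAP_FULL = "all",
                                           NRAP_NO38 = list(exclude = 38)))
      list(scenario = scenario(list(g), samples = list(
        edl = list(
          list(gene = "NrapD", transcript = "NRAP_FULL", consensus = 36, fl_total = 576),
          list(gene = "NrapD", transcript = "NRAP_NO38", consensus = 25, fl_total = 286)),
        soleus = list(
          list(gene = "NrapD", transcript = "NRAP_FULL", consensus = 30, fl_total = 377),
          list(gene = "NrapD", transcript = "NRAP_NO38", consensus = 60, fl_total = 2244)),
        heart = list(
          list(gene = "NrapD", transcript = "NRAP_NO38", consensus = 35, fl_total = 567))),
        name = "nrap_usage"), targets = NULL)
    },
    nrap_phase = {
      g <- regular_gene("NrapD", n_exons = 45, exon_len = 120, intron_len = 200,
                        transcripts = list(
                          NRAP_FULL = "all",
                          NRAP_NO12 = list(exclude = 12),
                          NRAP_NO2_12 = list(exclude = c(2, 12))))
      cassettes <- c(2, 12, 17, 37, 38, 39, 40)
      targets <- target_exon_set(g$chrom, g$exons$start[cassettes],
                                 g$exons$end[cassettes], as.character(cassettes),
                                 gene_id = "NrapD")
      list(scenario = scenario(list(g), samples = list(
        heart = list(
          list(gene = "NrapD", transcript = "NRAP_NO12", consensus = 30, fl_total = 541),
          list(gene = "NrapD", transcript = "NRAP_NO2_12", consensus = 3, fl_total = 14)),
        soleus = list(
          list(gene = "NrapD", transcript = "NRAP_NO12", consensus = 60, fl_total = 2177),
          list(gene = "NrapD", transcript = "NRAP_NO2_12", consensus = 5, fl_total = 26),
          list(gene = "NrapD", transcript = "NRAP_FULL", consensus = 20, fl_total = 341)),
        edl = list(
          list(gene = "NrapD", transcript = "NRAP_FULL", consensus = 35, fl_total = 557),
          list(gene = "NrapD", transcript = "NRAP_NO12", consensus = 20, fl_total = 280))),
        name = "nrap_phase"), targets = targets)
    },
    ttn_usage = {
      g <- regular_gene("TtnD", n_exons = 135, exon_len = 60, intron_len = 100,
                        transcripts = list(TTN_FULL = "all",
                                           TTN_NO129 = list(exclude = 129)))
      list(scenario = scenario(list(g), samples = list(
        soleus = list(
          list(gene = "TtnD", transcript = "TTN_FULL", consensus = 20, fl_total = 34),
          list(gene = "TtnD", transcript = "TTN_NO129", consensus = 1, fl_total = 1)),
        edl = list(
          list(gene = "TtnD", transcript = "TTN_FULL", consensus = 30, fl_total = 357),
          list(gene = "TtnD", transcript = "TTN_NO129", consensus = 4, fl_total = 4)),
        heart = list(
          list(gene = "TtnD", transcript = "TTN_FULL", consensus = 30, fl_total = 84),
          list(gene = "TtnD", transcript = "TTN_NO129", consensus = 40, fl_total = 148))),
        name = "ttn_usage"), targets = NULL)
    },
    ttn_phase191 = {
      g <- regular_gene("TtnD", n_exons = 135, exon_len = 60, intron_len = 100,
                        transcripts = list(TTN_FULL = "all",
                                           TTN_NO129 = list(exclude = 129)))
      flank <- c(128, 129, 130)
      targets <- target_exon_set(g$chrom, g$exons$start[flank],
                                 g$exons$end[flank],
                                 c("190", "191", "192"), gene_id = "TtnD")
      list(scenario = scenario(list(g), samples = list(
        heart = list(
          list(gene = "TtnD", transcript = "TTN_FULL", consensus = 25, fl_total = 64),
          list(gene = "TtnD", transcript = "TTN_NO129", consensus = 40, fl_total = 134)),
        edl = list(
          list(gene = "TtnD", transcript = "TTN_FULL", consensus = 40, fl_total = 281)),
        soleus = list(
          list(gene = "TtnD", transcript = "TTN_FULL", consensus = 15, fl_total = 21))),
        name = "ttn_phase191"), targets = targets)
    },
    ttn_phase312 = {
      g <- regular_gene("TtnD3p", n_exons = 10, exon_len = 600, intron_len = 300,
                        transcripts = list(TTN3_FULL = "all",
                                           TTN3_NO9 = list(exclude = 9)))
      targets <- target_exon_set(g$chrom, g$exons$start[8:10], g$exons$end[8:10],
                                 c("311", "312", "313"), gene_id = "TtnD3p")
      list(scenario = scenario(list(g), samples = list(
        heart = list(
          list(gene = "TtnD3p", transcript = "TTN3_FULL", consensus = 30, fl_total = 375)),
        edl = list(
          list(gene = "TtnD3p", transcript = "TTN3_FULL", consensus = 30, fl_total = 748),
          list(gene = "TtnD3p", transcript = "TTN3_NO9", consensus = 20, fl_total = 249)),
        soleus = list(
          list(gene = "TtnD3p", transcript = "TTN3_FULL", consensus = 60, fl_total = 2036),
          list(gene = "TtnD3p", transcript = "TTN3_NO9", consensus = 5, fl_total = 25))),
        name = "ttn_phase312"), targets = targets)
    },
    neb_phase = {
      # exon index i carries display label 134 + i for the 16 targets 137-152
      g <- regular_gene("NebD", n_exons = 20, exon_len = 350, intron_len = 150,
                        transcripts = list(
                          NEB_FULL = "all",
                          NEB_SKIP_A = list(exclude = c(138, 140, 143) - 134L),
                          NEB_SKIP_B = list(exclude = c(146, 147) - 134L)))
      idx <- 3:18
      targets <- target_exon_set(g$chrom, g$exons$start[idx], g$exons$end[idx],
                                 as.character(134L + idx), gene_id = "NebD")
      list(scenario = scenario(list(g), samples = list(
        edl = list(
          list(gene = "NebD", transcript = "NEB_FULL", consensus = 2, fl_total = 14),
          list(gene = "NebD", transcript = "NEB_SKIP_A", consensus = 10, fl_total = 80),
          list(gene = "NebD", transcript = "NEB_SKIP_B", consensus = 8, fl_total = 61)),
        soleus = list(
          list(gene = "NebD", transcript = "NEB_FULL", consensus = 40, fl_total = 733),
          list(gene = "NebD", transcript = "NEB_SKIP_A", consensus = 8, fl_total = 84))),
        name = "neb_phase"), targets = targets)
    },
    stop("unknown demo scenario: ", name)
  )
}

#' Simulate a demo scenario and run the matching pipeline stage
#'
#' Convenience wrapper: renders the scenario to `out_dir`, loads the
#' annotation and reads back through the standard I/O path, and returns the
#' PSI table (exon-usage demos) or the phase report (phasing demos).
#'
#' @param name Demo scenario name (see [demo_scenario()]).
#' @param out_dir Directory for the fixture files.
#' @param seed Integer seed.
#' @return For usage demos, the [psi_table()] data.frame; for phasing demos,
#'   the [phase()] report.
#' @export
run_demo <- function(name, out_dir = tempfile("demo_"), seed = 1) {
  demo <- demo_scenario(name)
  fx <- simulate_fixture(demo$scenario, out_dir, seed = seed,
                         targets = demo$targets)
  genes <- load_gtf(fx$gtf)
  rbs <- lapply(stats::setNames(nm = names(fx$sam)), function(s)
    load_reads(fx$sam[[s]], s, fl_sidecar = fx$sidecar[[s]]))
  if (is.null(demo$targets)) {
    flat <- flatten_gene(genes[[1]])
    psi_table(rbs, flat)
  } else {
    phase(rbs, demo$targets, annotation = genes)
  }
}
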