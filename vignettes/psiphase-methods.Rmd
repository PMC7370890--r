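---
title: "Quantifying splicing of very large genes from full-length long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splicing of very large genes from full-length long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiphase)
```

## The measurement model

`psiphase` quantifies alternative splicing from *aligned Iso-Seq consensus
reads*. The unit of evidence is not the aligned record itself but the number
of full-length (FL) reads — raw circular-consensus reads with both primers
and a poly(A) tail — that were clustered and polished into it. A consensus
read aligned with `N`-gapped CIGAR operations exposes its exon chain
directly; its FL multiplicity says how many independent full-length
molecules realized exactly that chain. All quantification in this package
is therefore FL-weighted, with plain consensus-read counts carried alongside
for coverage filters.

Two assumptions follow from the chemistry and are made explicit here:

1. **Consensus reads are near error-free.** HiFi consensus reads have error
   rates around 0.1%, so exon presence/absence can be read off alignment
   geometry with only a small boundary tolerance, and no realignment or
   error correction is attempted.
2. **Relative, not absolute, quantification.** FL counts are proportional
   to sampled cDNA molecules of a given transcript *within* a gene and
   sample. Ratios of FL counts for the same exon or pattern across samples
   are meaningful; comparisons across genes are not, and no normalization
   for gene length or expression is attempted.

## Exonic parts and PSI

Each gene's transcripts are collapsed into one metatranscript of disjoint
**exonic parts**: the exon-covered segments between consecutive distinct
exon-boundary coordinates of the union of all transcript exons. Every
transcript boundary coincides with a part boundary, so any read either
contains a part, splices it out, or is uninformative for it — there is no
"partial exon" ambiguity at the part level. Parts are numbered by increasing
genomic coordinate regardless of strand, rendered zero-padded
(`exonic_part_number "038"`), matching the flattened-annotation convention
popularized by DEXSeq so that part identifiers line up with what users of
that ecosystem expect. Genes are flattened independently; no cross-gene
aggregates are formed, since the analyses this package supports examine
named genes one at a time.

For a read and a part, classification is three-way:

* **matching** — one aligned block covers the part with each boundary
  missed by at most `boundary_slop` bases;
* **skipping** — the read's span encloses the part, the part lies inside
  one of the read's splice gaps, and no block overlaps it by more than
  `min_overlap` bases;
* **non-informative** — everything else, most importantly reads that start
  or end inside or short of the part.

$$\mathrm{PSI} = 100 \times \frac{\sum_{\text{matching}} \mathrm{FL}}
{\sum_{\text{matching} \cup \text{skipping}} \mathrm{FL}}$$

The denominator deliberately contains only reads that *fully span* the
part. Internally primed, 3′-truncated reads are abundant for very long
transcripts; counting a read that merely ends before a part as "skipping"
it would bias PSI downward for 5′ parts. Excluding non-informative reads
from both numerator and denominator makes PSI invariant to adding truncated
reads, which the test suite checks explicitly.

### Novel exon discovery

Reads are screened for block sub-intervals that no annotated part explains
(at least `novel_min_length` bases, default 10). Candidates are clustered by
overlap; a cluster supported by at least `novel_min_support` distinct reads
(default 5) becomes a novel part whose boundaries are the modal observed
start and end — the mode rather than the extremes, so a few wobbly
alignments cannot stretch the exon, with ties resolved to the smaller
coordinate for determinism. Novel parts are merged into the gene's part list
and all parts renumbered by coordinate before PSI is computed.

### The candidate filter cascade

Differentially used exon candidates are nominated, not tested: genes need at
least `min_gene_consensus` (10) consensus reads; a part must be spanned by
at least `min_part_consensus` (30) consensus reads in at least two samples;
and the maximum pairwise PSI difference among coverage-eligible samples must
reach `min_psi_delta` (20) percentage points, computed on unrounded PSI.
The two-of-three-samples wording of the original design generalizes here to
"any two coverage-eligible samples of any number". These thresholds are
deliberately conservative — manual inspection in the source study still
found roughly one artifact per seven candidates — and all of them are
arguments (and CLI flags).

## Cassette-exon phasing

PSI treats exons independently; phasing recovers their joint usage. Given an
ordered set of target exons, a read is phaseable only when its span encloses
the *entire* target region: partial reads cannot distinguish "exon absent"
from "exon not sequenced". Each phaseable read yields a binary inclusion
vector via the same three-way classifier, any non-informative target exon
rejecting the read. Patterns are tallied with consensus and FL weights, and
each pattern's percentage is its FL count over the sample's total phaseable
FL. Pattern identity is exact vector equality; near-miss tolerance would
conflate genuinely distinct isoforms of repetitive genes.

Patterns are matched against annotated transcripts by computing each
transcript's own inclusion vector over the targets. A transcript must span
the target region to be eligible at all (otherwise short transcripts would
spuriously "match" patterns they cannot produce); an exon scores 1 when a
transcript exon covers it within `boundary_slop` at each edge. Several
transcripts may be indistinguishable over the chosen exons — all are listed,
since distinguishing them would require exons outside the phased window.
Patterns matching nothing are reported as `unannotated`.

Exon sets wider than a read length cannot be phased in one pass; the
intended workflow is several focused runs over proximal exon groups, as in
the titin analyses that motivated this design. A 3′-terminal exon much
longer than its informative portion can be phased by supplying only a
sub-interval (e.g. the first 50 bp) as the target; the classifier then
behaves exactly as for a full exon whose reads cover that sub-interval.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `boundary_slop` | 10 | bases | alignment wobble tolerated at part/exon edges |
| `min_overlap` | 10 | bases | residual overlap still counted as a clean skip |
| `min_gene_consensus` | 10 | reads | gene admitted to analysis |
| `min_part_consensus` | 30 | reads | per-sample coverage for PSI comparisons |
| `min_psi_delta` | 20 | % points | candidate nomination threshold |
| `novel_min_support` | 5 | reads | novel-exon cluster support |
| `novel_min_length` | 10 | bases | minimal novel-exon candidate |
| `min_junction_support` | 5 | reads | junction-table display threshold |
| `min_mapq` | 0 | — | no MAPQ filter: consensus-read MAPQ is uninformative |

The slop/overlap defaults of 10 bp absorb splice-site wobble on noisy long
reads while staying far below any exon length of interest; both are exposed
on every function and CLI command. FL multiplicities are resolved sidecar
TSV first, then the Iso-Seq read-name grammar (`f<k>p<j>` or
`full_length_coverage=<k>`), then a warned default of 1 — SMRT Analysis
versions differ in naming, and the sidecar keeps the pipeline
self-contained. Only primary alignments are consumed; how multi-mapped
consensus reads ought to be weighted is an open question we resolve by
keeping the primary record only.

## The simulator: what it does and does not emulate

The synthetic-data module exists so that every pipeline stage has a
closed-form expected answer. A scenario declares genes (disjoint exons, a
set of transcripts as exon-index subsets, optionally exons flagged
unannotated), per-sample read patterns with consensus counts and FL totals,
genomic A-run priming sites, a size-selection window (default 5–10 kb, the
library design this emulates), and a substitution rate (default 0).

It emulates, deterministically under a seed:

* exon chains realized as pure `M`/`N` CIGARs with sequence taken from the
  generated genome;
* FL totals distributed as evenly as possible over a pattern's consensus
  reads, written to sidecars and encoded in read names;
* size selection: transcripts longer than the window are 3′-anchored —
  at the poly(A) end, or with configurable probability at an internal
  priming site, ending 0–20 bases upstream of a planted ≥ 8-base A-run —
  and 5′-trimmed to the window maximum. Background sequence is scrubbed of
  accidental ≥ 8-base A-runs so priming can only occur where declared;
* optional uniform substitution noise at a rate mimicking HiFi consensus
  error (no indels, so CIGARs stay exact).

It does **not** emulate clustering/polishing itself, alignment error,
indels, strand-ambiguous cDNA, expression-level variation between genes, or
biological exon-boundary variation (alt donors/acceptors beyond what the
scenario declares). Passing the closure tests therefore demonstrates that
the pipeline's arithmetic and geometry are exact on clean data — not that it
is robust to aligner pathologies, which real data would have to probe.
Internal priming truncation is simulated only for transcripts exceeding the
size window, with the anchoring probability exposed as a parameter (default
0.5) since no measured value is available; truth tables refuse scenarios
that would truncate stochastically, and truncation behaviour is instead
verified as a property (truncated reads are non-informative downstream and
rejected by phasing regions they do not span).

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; GTF/GFF I/O is 1-based
  inclusive, BED 0-based half-open, SAM POS 1-based — conversions happen
  only at the I/O boundary so round-trips are bit-exact.
* PSI and percentages are computed in double precision from exact integer
  FL sums and rendered to one decimal only in reports; filters compare
  unrounded values.
* A part spanned by no read has undefined PSI, rendered `NA` (distinct from
  PSI 0, which means "spanned but never included").
* Zero-length or duplicated exon records are dropped with a warning;
  a single-exon gene flattens to one part; an empty alignment file yields
  empty (header-only) outputs rather than errors.
* Ties in pattern ordering are broken lexicographically after descending FL
  count; modal novel-exon boundaries break ties toward the smaller
  coordinate; both make outputs byte-reproducible.

## Problem sizes

The packaged demo scenarios are desk-scale reconstructions of the three
worked examples: a 45-exon medium gene (cassette part 038), a 135-exon gene
with a deep cassette part 129 at one-tenth real exon sizes, a 10-exon 3′
fragment, and a 20-exon region phased over 16 cassette targets. Each
simulates, loads and quantifies in a few seconds; the full property suite
uses random genes of up to 6 transcripts × 10 exons and read sets of tens
of reads, chosen so exhaustive base-by-base oracles remain feasible.

## Known limitations

* PSI and pattern percentages are relative within gene and sample; they say
  nothing about absolute transcript abundance.
* Genes without internal priming sites lose 5′ coverage for transcripts
  beyond the read-length window, exactly as in the underlying protocol —
  the simulator reproduces this, it cannot fix it.
* Pattern-to-transcript matching is only as sharp as the chosen exon set;
  adding discriminating exons (when read length allows) is the remedy for
  multi-transcript matches.
* No statistical test is attached to the candidate cascade; it is a
  screening filter, and downstream validation is expected.
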