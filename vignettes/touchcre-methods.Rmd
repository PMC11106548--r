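---
title: "Methods: cis-regulatory discovery and peak annotation in touchcre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-regulatory discovery and peak annotation in touchcre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis this package implements

Plants remodel their transcriptome within minutes of mechanical
stimulation (thigmomorphogenesis). A standard way to ask *which
regulatory sequences drive that response* is to take genes that are
differentially expressed after touch, split them into groups by
direction and timepoint, and test their promoters for enrichment of
candidate cis-regulatory elements (CREs) — both a library of known
elements written as IUPAC consensi and de novo k-mers. When the
transcription factor of interest has also been assayed by DAP-seq, its
binding peaks are annotated by genomic feature category and nearest
gene, and binding location is cross-tabulated against the direction of
differential expression.

touchcre implements that analysis track end to end: promoter
extraction, consensus scanning, exact enrichment statistics, a growing
k-mer discovery algorithm, motif-library comparison with an empirical
null, peak annotation, and a seeded synthetic-data generator that makes
every stage testable with no external data.

## Coordinates, promoters and gene models

All internal coordinates are 0-based half-open. GFF3 (1-based
inclusive) and BED (already 0-based half-open) are converted at the
boundary by `read_gff3()` and `read_bed()`, so no off-by-one arithmetic
appears anywhere downstream.

Gene models keep one *primary transcript* per gene: the first mRNA
child in file order. Annotation formats rarely say which transcript
defines "the" promoter; a fixed, documented rule keeps the pipeline
deterministic. Introns are derived as the gaps between consecutive
exons of the primary transcript, so exon plus intron lengths always sum
to the transcript span (a tested invariant).

Two promoter definitions coexist, as they do in the source analyses:

* **Enrichment promoters** (`extract_promoters()`, default
  `window_bp = 1000`, anchor `"tss"`): the 1 kb immediately upstream of
  the transcription start site, the substrate of all motif scans and
  k-mer discovery.
* **Peak-annotation promoters** (`annotate_peaks()`, default
  `promoter_bp = 5000`, anchored on the 5'UTR start with TSS fallback):
  the 5 kb window used to classify binding peaks.

For a minus-strand gene the upstream window lies to the genomic right
of the TSS and is reverse-complemented, so position 0 of every promoter
sequence is farthest from the anchor reading toward it. Windows clipped
at chromosome ends are flagged `truncated`. Promoters may contain `N`;
motif matching treats `N` in the subject as matching nothing, which
under-counts rather than over-counts sites.

## Scanning and the presence/absence convention

`scan_promoters()` scans both strands by default (the reverse strand
via the reverse-complemented consensus) and reports, per promoter, both
the match positions and a single presence flag. The *presence flag* —
not the occurrence count — feeds every enrichment test, because the
hypergeometric model draws genes, not sites. A palindromic site
matching both strands at the same start is counted once (deduplication
by start and length). Whether the original analyses counted occurrences
or gene-level presence is not stated anywhere we could check; presence
is this package's documented choice and the generator plants at most
one occurrence per promoter, where the distinction vanishes.

## Enrichment statistics

For a motif and a gene group, with `N` background genes of which `m`
carry the motif, and a group of `n` genes of which `k` carry it, the
p-value is the hypergeometric upper tail `P(X >= k)`
(`hypergeom_upper_tail()`, computed in log space via `stats::phyper`,
exact; the unit-test oracle is an independent `choose()`-based
enumeration). Enrichment only — depletion is available behind the
`lower` flag but is not part of any default output.

Gene-family enrichment among DE genes uses the two-sided Fisher exact
test (`family_enrichment()`), defined as the sum of probabilities of
all margin-fixed tables no more probable than the observed one. A
table with a zero margin carries no contrast and returns p = 1.

Multiple testing uses Benjamini–Hochberg throughout (`bh_adjust()`).
The BH *family* must be chosen somewhere, and the source analyses do
not state theirs, so touchcre fixes and documents:

* known-CRE scans: all motif × group tests of one run
  (`enrich_motifs()`);
* k-mer discovery: all collapsed maximal k-mers within one group's
  report (`growth_report()`);
* motif comparison: the library, per query (`best_match()`).

Default thresholds: DE significance `q < 0.1`; discovery `q < 0.05`;
motif matching FDR `< 0.01`. The discovery threshold deserves a note:
the 0.01 FDR that travels with this kind of analysis applies to motif
*matching* against a known library, not to k-mer discovery, which
prints no threshold of its own; 0.05 is this package's default.

## The growing k-mer algorithm

De novo discovery (`discover_kmers()`) evaluates all 4^6 = 4096
6-mers for gene-level presence enrichment, then repeatedly extends: each
kept k-mer proposes 8 children (one additional A/C/G/T on either end),
and a child is kept iff its p-value is *strictly* lower than its
parent's. Growth stops at 12-mers or when no child improves. Reported
"maximal" k-mers are kept nodes with no kept extension, collapsed to
the lexicographic minimum of k-mer and reverse complement (merging
duplicates, keeping the smaller p), then BH-adjusted.

Three points the algorithm's verbal description leaves open, resolved
here:

* **Extension end.** "One additional base" does not say which end;
  touchcre extends on both (8 candidates), which subsumes one-sided
  growth. Several children may be kept simultaneously.
* **Seed filtering.** All 4096 seeds enter growth regardless of seed
  significance; significance is assessed once, at reporting, over
  maximal nodes. Deferring the filter avoids order-dependent pruning.
* **Comparison baseline.** Each extension is compared against its
  immediate parent, not the 6-mer root.

The algorithm contains no randomness: identical inputs give identical
reports, and ties (a child reachable from several parents) resolve to
the lexicographically smallest qualifying parent.

Presence counting is the hot loop and is compiled (Rcpp): k-mers are
2-bit integer codes, and one pass over the promoters per level answers
all candidates of that level via a hash lookup per rolling window, on
both strands, deduplicated per promoter. The compiled path is
contract-identical to a naive per-promoter scan and to the recursive
reference implementation `grow()`; both identities are asserted in the
test suite.

## Motif comparison

Discovered k-mers are matched against a motif library
(`best_match()`): PFM columns are compared by Pearson correlation, the
per-offset score is the mean correlation over query columns (columns
hanging off the target pair with the uniform background and contribute
0 under the degenerate-column guard, so padding is a penalty, not a
bonus), and the score is maximised over all offsets with at least 4
overlapping columns and both orientations. Significance comes from an
empirical null that permutes the query columns (`n_shuffles = 999` by
default, +1 smoothing so p is never 0, same permutations for every
target, seed mandatory), BH across the library, matches reported at
`q < 0.01`. Tomtom offers several column scores and the source
analysis does not print which was used; mean per-column Pearson with a
column-shuffle null is this package's documented, testable choice — not
a claim of bit-compatibility with MEME Suite.

## Peak annotation

Each peak is reduced to an anchor (summit when present, else midpoint —
peak callers differ on what they export, so both are supported) and
assigned exactly one category in priority order
`five_utr > three_utr > exon > intron > promoter > intergenic`. UTRs
outrank the exons that contain them because they are drawn as separate
categories in feature-distribution figures; promoter ranks below all
genic categories so a peak inside one gene is never called the promoter
of a neighbour. The nearest gene minimises distance to the gene span
(ties: smaller start, then lexicographic id) and supplies the
strand-aware signed TSS distance (negative = upstream).
`tss_profile()` histograms those distances over
`[-flank, mean transcript length + flank]`, the mean transcript length
marking the expected TTS position on the axis.

`crosstab_targets()` counts genes (once per cell) by binding class ×
DE direction × timepoint. "Gene body" includes UTRs by default; a
stricter exon+intron definition (between the translational start and
stop) is available via `strict_gene_body = TRUE` because the
conventional definition is genuinely ambiguous — both are computed in
the tests.

## The synthetic-data generator

`simulation_config()` defaults *are* the emulated study conditions,
fixed once:

* 200 foreground and 1000 background promoters of 1000 bp, uniform base
  composition, one 8-mer planted at 90% foreground / 5% background
  occurrence — the recovery design for discovery;
* mean primary transcript length 4500 bp (uniform on 0.7–1.3×, so the
  sample mean at 200 genes sits within 5% of target), 5 exons per gene,
  200 bp terminal UTRs — the TTS then falls ~4.5 kb from the TSS in the
  profile;
* six DE groups (up/down × 10/30/60 min) of 25 genes each;
* 1000 peaks at 25/25/21/21/8 percent across promoter, intergenic,
  exon, intron and UTR categories (UTR mass split equally between the
  two UTRs).

Planted motifs overwrite rather than insert, keeping promoter lengths
fixed; one occurrence per selected promoter (multiplicity is irrelevant
under presence counting); strand uniform. Genes are placed on a jittered
grid with at least 11 kb between neighbours so that 5 kb promoter
windows never collide and every planted peak category is unambiguous:
peak anchors are drawn from the category's genomic intervals shrunk by
10 bp. Everything is reproducible byte-for-byte from the seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: non-uniform base composition and repeats
(a GC-skew option exists as a stress test), overlapping and nested gene
models, alternative transcripts, motif positional preference within
promoters, correlated occurrences, peak-shape/coverage signal, and
realistic DE effect-size distributions. Recovery rates on this design
are upper bounds on real-data behaviour.

## Numerical choices and problem sizes

* Hypergeometric p-values via `phyper` in log space; test oracles use
  exact integer enumeration (`choose()` is exact well beyond N = 12).
* Strictly-lower comparisons in growth are exact floating-point
  comparisons of p-values computed identically for parent and child, so
  the strictness is well-defined.
* Degenerate PFM columns (zero variance) contribute 0 to alignment
  scores rather than NaN.
* The test suite exercises discovery at the full 200 + 1000 × 1000 bp
  design for 10 recovery seeds and 20 null seeds (~2–3 s per run via the
  compiled index); unit tests use scaled-down variants (40 genes,
  300 bp promoters) where the full design adds nothing.

## Known limitations

* The growth search is greedy: a child that momentarily worsens the
  p-value is discarded even if its own children would improve it.
* Presence-based counting saturates for very common motifs (m near N),
  where the test has little power by construction.
* `best_match()`'s empirical p-values are bounded below by
  `1/(n_shuffles+1)`; with BH across a large library, tiny FDR
  thresholds need proportionally more shuffles.
* The first-mRNA primary-transcript rule and both promoter anchors are
  conventions; with annotations whose transcript order is meaningful
  (e.g. longest first) results will follow that order.
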