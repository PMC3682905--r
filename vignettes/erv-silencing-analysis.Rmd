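---
title: "Methods: ERV silencing analysis with ervpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERV silencing analysis with ervpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervpipe)
```

## The problem

Mouse genomes carry hundreds of near-intact endogenous retroviruses (ERVs)
whose transcription is kept off by H3K9-methylation-based chromatin
silencing. Different ERV classes answer to different machinery: class I/II
families (IAPEz, MMERVK10C) to the KAP1–SETDB1/H3K9me3 axis, the class III
family MERVL to G9a/GLP-dependent H3K9me2, with HP1 proteins and indirect
"2C-like state" effects layered on top. Asking *which* family responds to
*which* factor requires four quantitative analyses over sequencing data:
family- and element-level expression change, ChIP enrichment in the unique
flanks of intact proviruses, LTR-initiated chimeric transcripts, and the
overlap between derepressed genes and the two-cell (2C) embryonic program.
`ervpipe` implements these as composable, individually tested functions.

This vignette records the models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where more than one defensible reading existed.

## Coordinates and containers

All tables use 0-based half-open coordinates (the BED convention); GTF and
RepeatMasker inputs are converted on read. Interval arithmetic, overlap
queries and coverage are delegated to GenomicRanges/IRanges; the 1-based
conversion is confined to two internal helpers. Alignments travel either as
SAM (written/read through Rsamtools, so records stay standards-clean) or as
a plain TSV mirror with identical columns.

## Intact elements and flank geometry

A *full-length element* is a maximal LTR–internal–LTR run on one strand in
which both LTRs carry the identical family annotation string, internal
segments belong to the configured internal family, adjacent components are
separated by at most `gap_tolerance` (default 100 bp), and the total span
falls in a per-superfamily window (`default_family_spec()`: MERVL 5–8 kb,
IAPEz 6–9 kb, MMERVK10C 5–10 kb). Two choices deserve note:

* **"Identical LTRs" means identical annotation.** The pipeline consumes
  annotations, not sequence, so LTR identity is the family string; no
  percent-identity computation is attempted (sequence analysis is a
  non-goal).
* **The length windows are configuration, not measurement.** They are
  stated explicitly so tests are exact, and are adjustable per family.

Flank geometry: `span`/`bin_width` (defaults 6000/50) bins tile each side,
bin 0 adjacent to the element boundary, sides defined by element strand (a
minus-strand element's 5′ flank lies at higher genomic coordinates). Bins
crossing a chromosome end are truncated and flagged. Bins overlapping a
neighboring annotated element are *not* masked — the confound is visible in
per-element heatmaps rather than silently removed.

## Expression and the Poisson Z-score

RPKM is `count / (length/1e3) / (library/1e6)`, with mate pairs counted
once for RNA-seq (a fragment is one observation of one molecule) and reads
counted for ChIP. A read or pair overlapping two regions by ≥ 1 bp counts
once in each — no fractional assignment; the rule is simple, documented,
and only matters for the rare fragments spanning region boundaries.
Uniqueness is approximated by mapQ ≥ 10 (both mates, for pairs).

The pairwise deregulation score between single libraries A and B is

$$z = \frac{\mathrm{RPKM}_A - \mathrm{RPKM}_B}
        {\sqrt{\mathrm{RPKM}_A + r_{AB}\,\mathrm{RPKM}_B}},
  \qquad r_{AB} = N_A / N_B,$$

treating each RPKM as Poisson-distributed (variance ≈ mean) with the
library-size ratio rescaling B's variance contribution. The score is 0 for
an all-zero region, has the sign of the RPKM difference, and satisfies
$z(A,B) = -z(B,A)$ when $N_A = N_B$. The denominator convention is isolated
in `poisson_zscore()` so an alternative variance proxy is a one-line
change.

**Calibration caveat.** The statistic is numerically calibrated (≈ 5 % of
|z| > 1.96 under the null) when RPKM is on the scale of the raw count —
1 kb regions and ~1e6-read libraries, the regime the null-calibration test
uses. Away from that scale the denominator is a variance *proxy*, not the
variance, and |z| is stretched or shrunk by a constant factor. This is an
inherent property of the score, acceptable because it is used as a ranking
and thresholding statistic within one comparison, not as a p-value.

Fold changes are pseudocounted, `(a + eps)/(b + eps)` with `eps = 0.1`
RPKM: zero-reference regions otherwise have undefined ratios, and 0.1 is
small against the ≥ 0.5 RPKM signals of interest. The pseudocount is a
parameter everywhere it is used.

## ChIP coverage and flank profiles

`build_coverage()` reproduces the classic tag-extension construction:
duplicates — identical (chromosome, 5′ start, strand) — collapse to one
read; reads with mapQ ≥ 10 are extended 300 bp downstream of their 5′ end
in read orientation; per-base coverage accumulates, truncated at chromosome
ends. `threshold_coverage()` extracts maximal intervals of height ≥ 10 and
zeroes the rest. The pipeline's profile stage defaults to the thresholded
track; the recovery tests use the unthresholded one, because thresholding
zeroes the background flanks that the enrichment-ratio comparison needs.

The aggregate profile normalizes bin coverage to *mean per-base coverage
per element per million retained reads* — the raw per-total-reads division
rescaled by 1e6 so densities are O(1); a pure rescaling that affects no
shape-based conclusion. Heatmap rows use the same definition with one
element per row, so the column means of the heatmap equal the aggregate
profile exactly (a tested identity).

**Extension spill.** Because reads are extended 300 bp, element-body
coverage spills up to one extension length into the flanks (and flank reads
into the body). The first 6 bins (300 bp) of any flank therefore carry body
signal even for a factor with no flank binding. Flatness checks in the test
suite start at bin 6 for this reason.

## Chimeric transcripts

Fragment-size statistics are estimated per library from the central 99 %
of same-chromosome fragment sizes (0.5 % trimmed per tail, so genuinely
discordant pairs do not inflate the SD), with the SD corrected for the
trimming-induced shrinkage under a Normal fragment-size model; at least 50
pairs are required and a zero SD is an error.

A mate pair supports a chimera iff

* |fragment − mean| > 1 SD (strictly),
* one mate overlaps an ERV element lying upstream — in gene orientation,
  within 10 kb — of the gene's first exon, or overlapping exon 1 itself,
* the other mate overlaps an annotated exon of that same gene,
* both mates have mapQ ≥ 10 and the pair's start-coordinate pair is unique
  (the operational meaning adopted for "unique support reads").

Candidates are keyed by (gene, element); a transcript is *valid* when its
support strictly exceeds 5 (i.e. ≥ 6). The 10 kb upstream bound is a
package choice: an unbounded search would join arbitrarily distal elements
to genes. A `mode = "loose"` variant drops the upstream requirement (one
mate in any listed ERV, the other in any exon of the gene), for family
breakdowns of all LTR-driven transcription rather than promoter-proximal
chimeras; the positional (upstream) definition is the default.

Family breakdowns report counts and integer percentages of valid calls;
percentages use round-half-up (`round_half_up()`), the convention that
renders 15/78 as 19 % and 5/43 as 12 %.

## 2C-specific genes and MT2 proximity

Stage tables carry reads-per-million per gene for oocyte, 2C and 8C pools;
RPKM is RPM divided by transcript length in kb. A gene is *2C-specific*
when its 2C RPKM is at least 4-fold above both the oocyte and the 8C RPKM
(inclusive thresholds — "at least 4-fold" reads as ≥) *and* clears a 0.5
RPKM floor at 2C. The floor is a package addition: without it, all-zero
genes with infinitesimal noise ratios classify as 2C-specific; 0.5 RPKM is
below any biologically meaningful expression yet above numerical noise.

KO upregulation uses the same inclusive 4-fold rule on pseudocounted fold
changes. Overlap summaries report per-line, union and all-line-intersection
counts with integer percentages of the 2C set.

Proximity: a gene is MT2-proximal when its TSS lies inside an MT2/MT2A/MT2C
LTR (distance 0) or within 5 kb of one, *inclusive* (≤ 5000 bp; "within"
read inclusively, stated so tests are exact). Enrichment of a gene set is
tested with the hypergeometric upper tail, P(X ≥ k) with population all
genes, successes the background-proximal genes, draws the gene set — the
natural exact test for "overrepresented among"; the implementation is
`stats::phyper`, dual-checked against subset enumeration for all
populations up to N = 12. Background proximal fractions are additionally
reported truncated to one decimal (the convention under which 1387/30321
renders as 4.5 %).

## The synthetic world

`sim_config()` fixes a stated world; `generate_toy_genome()`,
`simulate_rnaseq_pairs()`, `simulate_chip_reads()` and
`simulate_stage_table()` are deterministic given its seed (substreams per
generator, so outputs are independent but reproducible).

* **Genome.** 3 × 400 kb chromosomes; 12 MERVL, 8 IAPEz and 6 MMERVK10C
  full-length proviruses placed so that every 6 kb flank is free of other
  repeats (each element's exclusion zone covers its flanks plus a margin);
  20/6/4 solo LTRs; 40 three-exon genes. 15 % of genes receive a solo MT2
  LTR within 5 kb upstream of their TSS; 6 of them at 1.5–2.5 kb serve as
  chimera donors.
* **RNA-seq.** Per-region fragment counts Poisson around base × fold
  (wt all 1×; ko 27× MERVL, 4× IAPEz, 1× MMERVK10C — the magnitudes of
  deregulation this analysis is designed to detect); fragments
  Normal(200, 30) bp with 75 bp mates, a typical paired-end library
  geometry; 95 % of pairs unique (mapQ 60 vs 0). Planted chimeras emit the
  configured number of pairs with one mate in the LTR and one in exon 2,
  fragment sizes (LTR-to-exon distances) far beyond mean + SD. Gene
  expression (40 × 2500 pairs) dominates the library so that total-read
  normalization compresses planted folds by only ~6 % — mirroring real
  libraries, where deregulated repeats are a small library fraction.
* **ChIP.** Uniform background at 0.004 reads/bp plus per-family body
  enrichment; "spreading" families add flank reads decaying exponentially
  (rate continuous at the boundary: enrichment × background at distance 0)
  with a configured half-length; "focal" families get body-only signal.
  The background default keeps per-position collisions rare so duplicate
  collapsing does not saturate planted enrichment; recovery tests disable
  dedup entirely, since the simulator plants no PCR duplicates and
  collapsing random collisions is a known downward bias unrelated to the
  profiling geometry under test.
* **Stage table.** Planted 2C-specific genes at 8× (twice the
  classification threshold, so moderate noise cannot unplant them), other
  genes flat; multiplicative lognormal noise with σ = 0.2 (≈ 98.6 %
  expected sensitivity), σ = 0 for exact-recovery tests.

What the generator does **not** emulate: mappability structure and
multi-mapping ambiguity (mapQ is a planted label, not an aligner output),
sequence content of any kind, PCR duplication, splice junctions (gene
fragments live in the genomic span), overdispersion beyond Poisson, and
between-replicate biological variance (the analysis is single-library by
design). A green recovery test therefore establishes that the *algorithms*
recover planted structure under the stated noise — not that the pipeline is
robust to alignment artifacts of real data.

## Statistical notes on the acceptance checks

* **Z-score null calibration** is evaluated where the statistic is
  calibrated by construction (1 kb regions, 1e6-read libraries, λ = 100),
  with a 99 % binomial band around 5 %.
* **Fold recovery** runs the full generator → counting → RPKM →
  pseudocounted-fold path over 100 seeds and requires mean recovered folds
  within 15 % of {1, 4, 27}; the known ~6 % normalization compression is
  inside that band, deliberately: it is part of the method's behaviour.
* **Flank recovery** compares the spreading family's boundary bin to the
  distal (4–6 kb) background, requiring the ratio within 25 % of the
  configured 50×. With 300 bp extension the boundary bin is a smoothed
  average of body and near-flank signal, giving a structural recovery
  around 0.8 × enrichment — inside the band, again deliberately.
* **Focal flatness** is tested on 1 kb windows from 300 bp (past extension
  spill) to 2.3 kb against the distal mean plus 3 SD, with the SD pooled
  across seeds and rescaled by √(7/5) to account for the variance of a
  window's deviation from the distal mean (prox: (1+1/6)σ²; distal:
  (1−1/6)σ²). A literal per-bin 3 SD rule over ~100 correlated bins with a
  per-seed SD estimate false-alarms on ~10 % of seeds under a perfectly
  flat null — a property of the test, not the data — so the windowed,
  pooled version tests the same hypothesis at ~1 % family-wise false-alarm.
* The ChIP acceptance configuration raises the background rate to 0.03
  reads/bp, set by power analysis (per-window relative SD ≈ 4 %) before
  the acceptance loop was first run.

## Known limitations

* The Z-score's scale dependence (above): comparisons should be read
  within one pairwise analysis, not across region-length regimes.
* Multi-counting of boundary-spanning reads slightly inflates family
  counts when regions abut; flagged, not corrected.
* The chimera caller uses mate-location logic only — no split reads, no
  junction assembly — so it cannot resolve which exon the LTR splices
  into, only that LTR-proximal discordant support exists.
* Flank profiles retain bins overlapping neighboring annotations; on dense
  repeat landscapes the per-element heatmap is the trustworthy view.
* `percent_of()` rounds half away from zero; a published figure derived
  with a different convention can differ by one percentage point at exact
  halves (e.g. 27.45 % → 27 %, not 28 %).
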