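---
title: "Termination-region binding, R-loops and regional mutation burden"
author: "termloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Termination-region binding, R-loops and regional mutation burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(termloop)
  library(GenomicRanges)
})
```

## The scientific question

R-loops — three-stranded structures of an RNA:DNA hybrid plus displaced
single-stranded DNA — form co-transcriptionally over a subset of
transcription termination regions, where they participate in RNA
polymerase II pausing. Repair factors recruited to these pause sites
(BRCA1 among them) protect the displaced strand; when that protection
fails, termination regions become local mutation hotspots. Two
genome-scale questions follow:

1. **Binding**: are ChIP-seq peaks of a repair factor enriched in
   termination regions (TRs) of active, R-loop-forming genes, beyond what
   random placement would give?
2. **Consequence**: in tumours lacking that factor, are somatic mutations
   (in particular small insertions/deletions) enriched specifically within
   the regions around those genes' termination sites, relative to tumours
   with the factor intact?

`termloop` implements both analyses as reusable, tested components, plus a
synthetic-data generator that plants known structure so every stage can be
validated closed-loop, without any external download.

## Region definitions

All regions derive from one gene model per gene (multi-transcript genes
are collapsed to the transcript with the most extreme annotated 3' end, so
each gene has a single TTS). With TSS/TTS the first/last transcribed base
and all windows strand-aware:

| region | definition | default |
|---|---|---|
| termination region (TR) | TTS to TTS + L downstream | L = 4000 bp |
| promoter | TSS − u to TSS | u = 1250 bp |
| whole-gene region | TSS − u to TTS + d | u = 1250, d = 5000 bp |
| TTS window | TTS ± f | f = 4000 bp |

Internally coordinates are 1-based closed `GRanges`; BED input/output
(0-based half-open) is converted by `rtracklayer` at the boundary. Regions
running off a chromosome are clipped, not dropped, so gene counts in
enrichment denominators are preserved. The promoter width is a
convention (annotation sets rarely define "promoter" numerically); 1250 bp
matches the only upstream distance used elsewhere in the analysis and can
be overridden.

```{r regions}
genes <- GRanges("chr1", IRanges(c(10001, 30001), c(20000, 40000)),
                 strand = c("+", "-"), gene_id = c("gA", "gB"),
                 seqinfo = Seqinfo("chr1", 100000L))
names(genes) <- genes$gene_id
terminationRegions(genes)
```

## Overlap enrichment

`countOverlappingPeaks()` counts *distinct* peaks overlapping at least one
region (any-base overlap by default) and reports every (peak, gene) pair,
because one peak can serve several genes and several peaks one gene —
peak-level and gene-level tallies are deliberately separate.

Two null models are provided:

* **Uniform placement** (`poissonOverlapTest()`). Under the null each
  peak keeps its length and chromosome and its start is uniform on the
  chromosome. The expected overlap count is
  $\lambda = \sum_j p_j$ with $p_j$ the per-peak hit probability — the
  width of the union of the windows $[s_i - L_j + 1,\, e_i]$ over regions
  $i$, divided by the chromosome length. When the dilated regions are
  disjoint this is the classical effective-target-size expectation
  $n\,(\sum_i \mathrm{len}_i + (\bar L - 1)k)/G$. The reported upper tail
  $P(X \ge \mathrm{obs})$ is computed from the exact Poisson-binomial
  distribution of the independent placements; a classical Poisson tail at
  $\lambda$ is available via `method = "poisson"`. The exact tail is the
  default because at desk scale per-peak hit probabilities are large
  enough (~0.1) that the Poisson approximation visibly disagrees with a
  permutation null, and the permutation null is the ground truth this
  statistic estimates. The suite verifies the exact tail against both
  brute-force enumeration and a 100,000-draw placement simulation.
* **Chromosome-aware shuffling** (`shuffleEnrichment()`). Every shuffle
  relocates each peak uniformly within its own chromosome; the empirical
  p value uses the add-one estimator $(1 + \#\{null \ge obs\})/(n+1)$ and
  so is never zero; fold enrichment is observed over mean null fraction.
  Shuffles ignore assembly gaps (none exist in the synthetic world; for
  real genomes supply pre-masked chromosome sizes if this matters).

The "TR gene" set is produced by `filterPeaks()` (drop every peak touching
a promoter or a transcript span — binding there is ambiguous between
promoter-associated and termination-associated roles) followed by
`trGeneTable()`.

## Expression and DRIP stratification

`compareExpression()` is a Mann-Whitney U test, one-sided "greater" by
default since the scientific claim is directional (TR-bound genes are more
highly expressed); exact enumeration for ≤ 20 values per group, otherwise
the tie-corrected normal approximation. Outlying values take part in the
test even when a plot would hide them.

`rpkmOverRegions()` quantifies a bedGraph-semantics coverage track over
regions as RPKM = signal / (region kb) / (library millions). When no
library size is given, the track's own total signal is the denominator.
One consequence matters for paired comparisons: *self-normalising two
tracks by their own totals removes any genome-wide depletion*. If an
RNaseH-treated control loses hybrid signal everywhere, equalising totals
hides exactly that loss whenever background mass is small. Real DRIP and
DRIP+RH libraries are sequenced to comparable depth, so the package's
validation supplies explicit, equal library sizes; do the same when
comparing treatment against a globally-depleting control.
`pairedSignalTest()` is the Wilcoxon signed-rank test on per-region
differences (zeros dropped; exact null up to 25 informative pairs).

## The stratified CMH effect size

Regional mutation burden is compared between tumour groups with a
Cochran-Mantel-Haenszel construction stratified by gene. For gene $k$,
let $a_k$ be the number of group-A patients with at least one mutation of
the class of interest inside the gene's region, $m_k$ the number of such
patients in both groups, $N = n_A + n_B$:

$$Z = \frac{\sum_k (a_k - E_k)}{\sqrt{\sum_k V_k}},\qquad
E_k = \frac{n_A m_k}{N},\qquad
V_k = \frac{n_A n_B m_k (N - m_k)}{N^2 (N-1)}.$$

Positive $Z$ means enrichment in group A; the p value is the one-tailed
normal tail $1 - \Phi(Z)$, with the direction fixed a priori as "mutant
group enriched". Strata with $m_k \in \{0, N\}$ carry no information and
contribute nothing; when no stratum is informative the result is flagged
degenerate with $p = 1$ rather than producing a 0/0.

Design choices worth stating:

* **Binarisation.** Each patient contributes at most one hit per gene.
  This is robust to hypermutated patients dominating the statistic. A
  raw-count variant (`variant = "count"`, binomial allocation of each
  stratum's total under the null) is provided for sensitivity analysis;
  the published construction is not printed in enough detail to know
  which was used, so reproduction attempts should report both.
* **No burden offset.** The statistic deliberately does not normalise by
  each group's genome-wide mutation load: the scientific claim is about
  *regional* enrichment and survives one group having a higher global
  rate.
* **Rearrangements** enter as breakpoint records; a rearrangement hits a
  region if either breakpoint falls in it.
* **No multiplicity correction** across panel cells; the report carries
  the number of cells so a reader can apply one.

`effectSizePanel()` runs every combination of region definition
(whole-gene, TTS window), gene set (TR-bound, negative control), mutation
class (SBM, indel, rearrangement) and comparison (each mutant group vs
the sporadic group). Germline subtraction (`subtractGermline()`: remove
tumour records matching a same-patient, same-class normal record) runs
first when normal catalogs are available.

## The synthetic world

`simulationConfig()` states one desk-scale world; the generators are pure
functions of it (per-generator seed offsets keep the streams independent,
so adding a generator never changes another's output).

* **Genome**: one 10 Mb chromosome, 200 non-overlapping genes of 2–10 kb
  with ≥ 10 kb flanks — large enough for ~184 TR genes (the size of gene
  set the mutation analysis is designed around) plus a negative set,
  small enough that thousands of replicates run in minutes.
* **Peaks**: 500 peaks of 150–500 bp (typical ChIP peak widths), 30%
  planted uniformly inside randomly chosen TRs, the rest uniform.
* **Expression**: log-normal (meanlog 1, sdlog 1 — a right-skewed
  RPKM-like distribution), a 2-fold boost for TR genes, 30% of non-TR
  genes silent.
* **DRIP signal**: Poisson counts (mean 50) per candidate region, RNaseH
  factor 0.3 on the control track, sparse low-level background.
* **Mutations**: per patient and class, a genome-wide uniform Poisson
  process; per-Mb rates (SBM 6.4, indel 6.4, rearrangement 3.2) chosen so
  a TTS ± 4 kb window has ≈ 5% per-patient hit probability — the regime
  the binarised CMH operates in, and the baseline the validation design
  specifies. (Real tumour genomes are 300× larger with correspondingly
  lower per-Mb indel rates; on a 10 Mb toy genome the per-region hit
  probability, not the per-Mb rate, is the quantity to preserve.) The
  cohort is 12 sporadic, 5 BRCA1, 4 BRCA2 patients. `theta[[group]][[class]]`
  multiplies the rate inside the designated regions of TR genes for that
  group's patients; the default is 1 everywhere (no effect).

What a green closed-loop test establishes — and what it does not: the
generator emulates the *statistical* structure (planted enrichment, rate
ratios, paired depletion) but not sequence content, mappability,
assembly gaps, peak-calling artefacts, clustered mutational processes, or
inter-patient rate heterogeneity. Green tests certify the machinery
(regions, counting, nulls, statistics) on data whose truth is known; they
do not certify that any particular biological dataset satisfies the
models' assumptions.

## Numerical and degenerate-input conventions

* Overlap is strand-blind and any-base by default (`minOverlap`
  configurable); region ends are inclusive, a record one base past a
  region is outside it.
* Tail probabilities are floored at `1e-300` so downstream `log10` never
  meets a hard zero.
* All-tied rank tests, all-zero paired differences, and CMH panels with
  no informative stratum return `p = 1` with a warning or flag instead of
  erroring, so a pipeline run on degenerate inputs completes and reports.
* Empty TRs after chromosome-end clipping are dropped with a warning;
  clipped (shortened) regions are kept.
* `simulateSignal()` merges overlapping candidate regions before writing
  a track, since bedGraph forbids overlapping intervals.

## Validation design

The test suite closes the loop at the replicate counts the validation
design states: the analytic overlap tail against a 100,000-draw placement
null on 20 random instances (within 3 Monte-Carlo SEs); CMH correctness
against hand evaluation, the Pearson-chi-square identity and
`stats::mantelhaen.test`; type-I calibration of the one-tailed CMH at
θ ≡ 1 over 2000 synthetic cohorts (5% ± 1.5%); recovery of a planted
θ = 3 indel effect over 500 cohorts (median Z > 2, correct panel cell);
planted peak enrichment and unbiasedness of λ; rank-test size and power;
and exact hand-enumerated stage counts on a 12-peak/5-gene fixture. One
statistical note: twenty simultaneous ±3 SE checks have a ≈ 5%
family-wise chance of a single random excursion, so the suite fixes the
Monte-Carlo streams (base seed 1) as any deterministic test of a
stochastic quantity must.

## Known limitations

* Analyses of this kind run on external datasets (ENCODE-style
  ChIP-seq/RNA-seq, DRIP-seq, whole-genome tumour mutation catalogs)
  that are not redistributable with a package; `termloop` validates the
  machinery on synthetic data and exposes readers for the real formats.
  Reported CMH z scores from such analyses depend on stratification
  choices that method descriptions rarely pin down; the default
  binarised gene-stratified construction is one defensible reading, and
  the count variant exists precisely because the choice is
  consequential.
* Peak calling, read alignment and expression quantification are out of
  scope: peaks, tracks and expression tables are inputs.
* The uniform-placement null ignores mappability and assembly gaps;
  supply masked chromosome sizes if that bias matters for a real genome.
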