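# termloop

Genome-scale analysis of protein binding at transcription **termination
regions (TRs)** — the ~4 kb immediately downstream of a gene's
transcription termination site (TTS) — and of its mutational consequences
in tumour cohorts. The package is aimed at computational biologists who
have ChIP-seq peak sets, expression tables, DRIP-seq (R-loop) coverage
tracks and per-patient somatic mutation catalogs, and want to ask:

1. Are peaks enriched in TRs of active genes beyond random placement?
2. Do those TR-bound genes form R-loops (DRIP > DRIP+RNaseH control)?
3. In tumours lacking the factor, are somatic mutations enriched within
   those genes' regions relative to control tumours?

## The statistics at the core

**Overlap enrichment.** For peaks with lengths $L_j$ placed uniformly on
their chromosomes, the expected number overlapping at least one region is
$\lambda = \sum_j p_j$, where $p_j$ is the width of the union of windows
$[s_i - L_j + 1, e_i]$ over regions $i$ divided by the chromosome length
(the classical effective-target-size expectation
$n(\sum_i \mathrm{len}_i + (\bar L - 1)k)/G$ when regions are sparse).
The upper-tail p value is the exact Poisson–binomial tail of the
independent placements (a Poisson tail at $\lambda$ is available as an
option), and a chromosome-aware shuffle null provides the permutation
analogue with fold enrichment and an add-one empirical p.

**Regional mutation burden.** Tumour groups are compared with a
gene-stratified one-tailed Cochran–Mantel–Haenszel Z:

$$Z = \frac{\sum_k (a_k - E_k)}{\sqrt{\sum_k V_k}},\quad
E_k = \frac{n_A m_k}{N},\quad
V_k = \frac{n_A n_B m_k (N-m_k)}{N^2(N-1)},$$

where $a_k$ counts group-A patients with ≥ 1 mutation of a class in gene
$k$'s region and $m_k$ counts such patients in both groups. Positive $Z$
means enrichment in group A; $p = 1 - \Phi(Z)$.

Rank tests (Mann–Whitney for expression, paired Wilcoxon for DRIP vs
DRIP+RH) handle the stratification steps. A synthetic-data module
generates genomes, peaks, expression, coverage and mutation catalogs with
planted, parameterised structure so the whole pipeline is validated
closed-loop. See the vignette
(`vignettes/termination-region-analysis.Rmd`) for models, assumptions and
design decisions.

## Worked example

Simulate a world with a planted 3-fold indel rate ratio in the BRCA1
group confined to TTS ± 4 kb of TR genes, then run both analyses:

```r
library(termloop)

cfg <- simulationConfig(seed = 7, theta = list(BRCA1 = list(indel = 3)))
sim <- simulateAll(cfg)

tr <- runTRDiscovery(sim$genome$genes, sim$peaks$peaks, sim$genome$seqinfo,
                     expression = sim$expression$expression,
                     nShuffles = 199, seed = 7)
print(tr)
#> TR discovery report
#>   peaks: 500 | overlapping a TR: 186 | after promoter/transcript filter: 182 | in expressed TRs: 167
#>   TR peaks: 182 -> TR genes: 120
```

500 simulated peaks, 186 of which fall in a TR (150 planted plus ~36 by
chance, against λ ≈ 43.2 expected under uniform placement — an excess the
overlap test puts far beyond chance); 4 are discarded for also touching a
promoter or transcript; 167 sit in TRs of expressed genes; the 182
retained TR peaks mark 120 distinct TR genes.

```r
mp <- runMutationPanel(sim$mutations$mutations, sim$mutations$cohort,
                       sim$genome$genes, trGenes = sim$trGeneIds,
                       negGenes = setdiff(sim$genome$genes$gene_id,
                                          sim$trGeneIds),
                       regionTypes = "tts_window",
                       genome = sim$genome$seqinfo)
subset(mp$panel, gene_set == "TR" & comparison == "BRCA1_vs_sporadic")
#>       region gene_set        mclass        comparison          z            p n_informative degenerate
#> 1 tts_window       TR           SBM BRCA1_vs_sporadic -0.4787251 6.839329e-01            66      FALSE
#> 3 tts_window       TR         indel BRCA1_vs_sporadic  5.5268563 1.630099e-08            75      FALSE
#> 5 tts_window       TR rearrangement BRCA1_vs_sporadic  0.6262562 2.655735e-01            38      FALSE
```

The planted cell — indels, BRCA1 vs sporadic — stands out (Z = 5.53,
one-tailed p = 1.6e-8) while SBMs and rearrangements stay at null levels;
informative strata are the TR genes in which at least one but not every
patient carries a hit.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on a synthetic dataset derived
from `--seed`: genome/peak/expression/signal/mutation generation, the TR
discovery chain (overlap test, promoter/transcript filter, expressed
filter, RNAPII co-localization shuffle, paired DRIP test) and the
mutation effect-size panel, writing the JSON summary to `--out` and the
full machine-readable reports next to it.
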