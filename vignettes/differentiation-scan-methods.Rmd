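---
title: "Methods: genome scans for differentiation between two closely related populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome scans for differentiation between two closely related populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdiff)
```

## The problem

Two closely related populations — think of two regional samples of the same
broader ancestry, genotyped and phased on a common SNP set — can differ in
allele frequencies and in haplotype structure at particular loci even when
their genome-wide differentiation is small. `hapdiff` scans phased haplotype
panels for such regions with three complementary statistics, then reports
only regions where at least two of the three agree:

1. **Allele-frequency differentiation (F_ST).** For each SNP with scored-allele
   frequencies $p_1, p_2$ in the two panels, the two-population form
   $$F_{ST} = \frac{(p_1 - p_2)^2}{(p_1 + p_2)\,(2 - p_1 - p_2)}$$
   is computed, and converted to a genome-wide *empirical p-value*
   (the fraction of scanned SNPs with an F_ST at least as large, the SNP
   itself included, so the smallest attainable value is $1/N$). Because a
   single extreme SNP may be a genotyping artefact, evidence is aggregated
   over windows: each chromosome is cut into non-overlapping 100 kb windows
   and the number of SNPs with empirical $p < 0.01$ per window is tested
   against Binomial(n, 0.01) with the one-sided exact tail
   $P(X \ge k)$; a parallel scan uses 500 kb windows at empirical
   $p < 0.001$. Windows are pooled genome-wide per window size and ranked
   by their binomial p-value.

2. **Within-population selection (iHS).** For a SNP with known ancestral
   allele, the extended haplotype homozygosity (EHH) of the derived-carrier
   and ancestral-carrier haplotype classes is integrated against genetic
   distance on both sides (truncated where EHH falls below 0.05), giving
   iHH$_D$ and iHH$_A$; the raw score $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$
   is standardized within 20 derived-allele-frequency bins of width 5%.
   An extreme |iHS| in one population *that the other population does not
   share* is evidence of population-specific selection.

3. **Cross-population haplotype length (XP-EHH).** EHH is computed over all
   haplotypes of each panel around the core SNP, both integrals truncated at
   the common boundary where the *pooled* two-panel EHH drops below the
   cutoff, and $\ln(\mathrm{iHH}_{pop2}/\mathrm{iHH}_{pop1})$ is
   standardized genome-wide to zero mean and unit variance. Negative
   normalized scores mean longer haplotypes — candidate selection — in
   population 1.

A region is *discovered* when one metric passes its stringent tier
(F_ST windows in the top 0.1% of the pooled ranking; an |iHS| SNP in one
population's top 0.1% with no top-1% SNP of the other population within
±100 kb; an XP-EHH SNP in the top 0.01% of either extreme) and *reported*
only when a second metric passes its laxer validation tier inside the
region (F_ST top 1%; differential iHS at top 1%; XP-EHH top 0.5% of an
extreme). For directional candidates the validating evidence must agree in
direction: a region attributed to selection in population 1 cannot be
"validated" by an XP-EHH extreme of the opposite sign or by an iHS signal
in the other population. Separately, a windowed **haplotype similarity
score** compares a focal population against two comparators: per 100 kb
window, the set $S$ of distinct haplotypes reaching ≥ 2% frequency in
*both* populations of a pair is found, and the score is the fraction of all
pooled haplotype copies matching $S$; windows are classified by the strict
0.5 rule (similar to one comparator and dissimilar to the other).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_size` | 100 kb / 500 kb | F_ST enrichment windows (0-based half-open grid on pos−1) |
| `tier_threshold` | 0.01 / 0.001 | empirical-p cutoff defining an extreme SNP per window size |
| `ehh_cutoff` | 0.05 | EHH truncation for iHH integration, both statistics |
| `max_gap_bp` | 200 kb | physical gap on the integration path that voids a SNP (assay deserts) |
| `min_carriers` | 3 | minimum haplotypes per allele class (iHS) or panel (XP-EHH) |
| `min_daf`/`max_daf` | 0.05 / 0.95 | derived-allele-frequency bounds for iHS |
| `region_pad` | 100 kb | half-width of SNP-seeded candidate regions |
| thresholds | see above | all Table-style discovery/validation tiers, each a `criterion_thresholds()` field |

The iHS discovery tier is configurable between 0.1% and 0.19%: the two
readings circulate for the same criterion; 0.1% is the default here.

## Percentile-tier semantics

"Top q%" is implemented as rank ≤ floor(N·q/100) under a deterministic
ordering (score descending, ties broken by chromosome then position), with
N counting scored items only. On genome sizes where a tier cannot be
resolved (floor = 0) the tier is empty rather than promoting the single
most extreme item. The alternative nearest-rank (ceiling) reading always
promotes at least one item per tier, which at desk scale forces one
discovery candidate per metric per scan and makes a zero-region outcome on
undifferentiated data impossible; at the scale of millions of SNPs the two
readings coincide. This choice matters only for small scans.

## The synthetic-data generator

Real phased panels of two related populations are emulated by a three-stage
generative model (`sim_config()`, `simulate_neutral()`):

1. **Frequencies.** Per-SNP ancestral frequencies follow a U-shaped
   Beta(0.5, 0.5) spectrum (clipped to [0.02, 0.98]). A shared ancestral
   founder pool of `n_founders` (default 60) haplotypes is drawn from them;
   the pool size sets the panel-level sampling noise of every statistic,
   and 60 founders for 160-haplotype panels emulates a haplotype-rich
   human-scale sample rather than a bottlenecked isolate.
2. **Divergence.** Each population's founder pool starts as a copy of the
   ancestral pool. Founder-level drift resamples whole segments (mean
   0.5 cM) from random ancestral founders with probability
   θ = min(1, 2·F·K), where F is `divergence_level` and K the pool size,
   giving mean F_ST ≈ θ/2K while the populations keep sharing long exact
   haplotype tracts — as real sister populations do. Drift beyond the
   founder-resampling ceiling is added as per-SNP flips toward
   Balding–Nichols target frequencies. At F = 0 the pools are identical
   (true panmixia).
3. **Emission.** Every sample haplotype is a mosaic of its population's
   founders with Poisson(`switch_rate` per cM, default 6) breakpoints along
   the genetic map, a small miscopy rate (0.003), and — crucially —
   *locus-specific coancestry*: per 0.25 cM block, Dirichlet
   founder-copying weights shared by all populations. Blocks where few
   founders dominate have long shared haplotypes in **both** populations at
   once. Without this feature each population's EHH landscape is an
   independent draw, the cross-population correlation of neutral iHS scores
   is far below what real sister populations show, and the
   other-population-exclusion clause of the iHS criterion loses its power.

A hard sweep (`impose_sweep()`) copies one derived-allele core haplotype
over exponentially distributed tracts (mean `selection_strength` cM per
side) into enough target-population haplotypes to reach `final_frequency`,
the star-like approximation of a recent strong sweep. The admixture design
(three populations, `admixture_proportion` α) emits population 1 as a
segment-level mosaic drawing from the population-2-like pool with
probability α.

What the generator does **not** emulate: genotyping error, phasing
switch errors, SNP ascertainment bias, realistic demographic history
(growth, migration), and fine-scale recombination-rate variation (the
simulated map is uniform; the scan machinery accepts any piecewise map).
Passing tests on this generator therefore show that the statistics and the
discovery logic behave as specified under controlled drift/LD/sweep
structure — not that any particular real dataset would yield particular
regions.

## Problem sizes used by the tests and the acceptance analysis

Pipeline-level properties are exercised on genomes of 4 chromosomes ×
2.5 Mb with 3,000 SNPs each (12,000 SNPs) and 160 haplotypes per
population, the scale of the HapMap-era panels this pipeline targets
(~80–85 diploid samples per population). This size is the smallest at
which both haplotype discovery channels resolve under the floor
semantics: iHS (top 0.1% of ~7,000 scored SNPs per population) and
XP-EHH (top 0.01% of ~10,800 scored SNPs, one SNP per extreme). The
windowed-F_ST discovery tier needs over a thousand windows and cannot
resolve here (120 windows); F_ST acts through validation, and its tier
occupancy is checked separately on a 4 × 30 Mb panmictic genome
(1,200 windows). Sweep recovery plants a selection strength of 0.5 cM
expected one-sided tract at 80% final frequency — a strong, recent hard
sweep — on one chromosome, with divergence 0.004 (the genome-wide
differentiation scale of closely related regional populations,
F_ST ≈ 0.4%) as the background. Replicate counts are 20 for the
calibration properties.

## Numerical choices and degenerate inputs

* iHH integration is trapezoidal in genetic distance; the trapezoid through
  the first sub-cutoff SNP is included, then integration stops. A curve
  still above the cutoff at the chromosome end (including a core SNP with
  no flanking SNPs on one side) makes the SNP non-computable (`edge`), as
  does an inter-SNP gap above `max_gap_bp` (`gap`).
* Monomorphic SNPs are removed before scanning (logged in the manifest);
  `fst_two_pop(0, 0)` and `(1, 1)` are defined as 0, never NaN.
* iHS bins with fewer than two scored SNPs or zero spread are flagged
  `unnormalized` and excluded from thresholds. Bin standardization uses the
  sample (n−1) SD; genome-wide XP-EHH standardization uses the population
  (n) SD so the normalized track has exactly unit variance.
* All rankings and merges are deterministic: ties break by (chromosome,
  position); re-running a scan on identical input is byte-identical.
* Windows are 0-based half-open `[kW, (k+1)W)` on `pos_bp − 1`; physical
  positions stay 1-based as parsed.
* Allele matching at panel intersection is by literal nucleotide identity;
  swapped ref/alt is repaired by flipping, incompatible allele sets are
  dropped and tallied, and no strand flipping is attempted.

## Known limitations

* The windowed-F_ST discovery tier is undefined on genomes with fewer than
  1,000 windows (floor semantics); on scaled-down genomes discovery then
  rests on iHS and XP-EHH, with F_ST acting through validation.
* The two-of-three rule inherits the correlation of its haplotype-based
  metrics: a population-specific sampling fluctuation lengthens haplotypes
  in one panel and therefore moves iHS and XP-EHH *together*, so a pair
  of "independent" criteria can both be satisfied by one fluke. On
  genomes of ~10⁴ SNPs the discovery tails sit near 3.5–4 sigma over only
  a few hundred effectively independent loci, and panmictic scans report
  a false region in a substantial fraction of replicates (the
  `neutral_zero_region_rate_pct` entry of the acceptance output measures
  this directly). The rate falls as the genome grows relative to the
  candidate-region pad and as discovery tails move further into the
  extreme; it is the main reason scaled-down scans should treat any
  single reported region with suspicion.
* iHS requires ancestral-allele annotation and mid-range derived-allele
  frequencies; sweeps taken near fixation are mostly visible to XP-EHH and
  windowed F_ST, not iHS.
* The haplotype similarity score uses exact haplotype-string identity; it is
  sensitive to genotyping or phasing error on real data in a way the
  miscopy-free synthetic windows are not.
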