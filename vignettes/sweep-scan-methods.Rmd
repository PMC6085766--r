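---
title: "Detecting selective sweeps with joint FST / pi-ratio / XP-EHH outlier scans"
author: "sweepscanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with joint FST / pi-ratio / XP-EHH outlier scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscanr)
```

## The problem

A recent hard selective sweep — a beneficial allele driven quickly to high
frequency, as happens under strong artificial selection in livestock breeds —
leaves three coupled signatures in the genome of the selected (focal)
population relative to closely related reference populations:

* **reduced nucleotide diversity** ($\pi$) around the selected site, because a
  single haplotype replaces the ancestral variation;
* **elevated allele-frequency differentiation** ($F_{ST}$) against the
  references, because the focal population fixes alleles the references still
  segregate;
* **extended haplotype homozygosity**: the swept haplotype is long, because
  recombination had little time to break it up, quantified across populations
  by XP-EHH.

`sweepscanr` implements the scan that combines all three: statistics are
computed in 10-kb non-overlapping windows; windows simultaneously above the
empirical top-10% threshold of window $F_{ST}$, the diversity ratio
$\pi_\mathrm{ref}/\pi_\mathrm{focal}$, and window XP-EHH are merged into
candidate sweep regions (tolerating gaps of fewer than nine analyzed
windows), filtered to regions longer than 30 kb, annotated with overlapping
genes and with highly differentiated missense SNPs (chromosomal top 0.1% of
per-SNP $F_{ST}$), and finally intersected with differentially expressed
genes at a Benjamini–Hochberg FDR below 0.05.

## Statistics

**Weir–Cockerham $F_{ST}$.** Per site, the three 1984 variance components
for two populations of diploids are computed from sample sizes, allele
frequencies, and observed heterozygote frequencies: $a$ (among populations),
$b$ (among individuals within populations), $c$ (within individuals). The
windowed statistic is the weighted ("ratio of sums") estimator
$\sum_i a_i / \sum_i (a_i + b_i + c_i)$ over the SNPs of the window, the
convention used by VCFtools' windowed weighted $F_{ST}$. Per-SNP $F_{ST}$
(used for the missense analysis) is the single-site ratio. Windows whose
component sum is zero are flagged undefined and excluded from ranking.

**Nucleotide diversity.** Per site, the unbiased mean pairwise difference
over $H$ haplotypes is $2p(1-p)\,H/(H-1)$; the window value sums sites and
divides by the full window span in bp (VCFtools `--window-pi` convention),
so diversity is per-bp and monomorphic stretches dilute it. The per-window
ratio $\pi_\mathrm{ref}/\pi_\mathrm{focal}$ is the sweep statistic; a window
with zero focal diversity but positive reference diversity receives a
$+\infty$ sentinel that ranks above all finite values (it is the maximal
observable evidence of diversity loss), while windows with both diversities
zero are flagged undefined.

**XP-EHH.** EHH at a flanking marker $x$ is the probability that two
haplotypes drawn at random from a population are identical at all markers
between the core SNP and $x$. We use the cross-population convention: EHH is
computed over *all* haplotypes of a population, unconditioned on the core
allele, so $\mathrm{EHH}(\mathrm{core}) = 1$ by definition and the identity
partition is refined by flanking markers only. iHH is the trapezoidal
integral of EHH against physical distance (no genetic map is assumed), left
plus right of the core, truncated at the first marker where the EHH of the
*pooled* two-population sample drops below a cutoff (default 0.05); the
truncation marker itself is included in the integral. Sharing the truncation
boundary makes the two areas comparable, and
$\mathrm{raw} = \ln(\mathrm{iHH}_\mathrm{focal}/\mathrm{iHH}_\mathrm{ref})$
is z-normalized over all scored SNPs genome-wide. Cores where the pooled
EHH never reaches the cutoff before the chromosome end are flagged
edge-unreliable and excluded before normalization; a degenerate consequence
worth knowing is that two populations with *identical* haplotype sets of
size $n$ each have a pooled homozygosity floor of $1/(2n-1)$, so for
$n \le 10$ the default cutoff is unreachable and no SNP is scored. Window
XP-EHH is the mean of z over the window's scored SNPs (a `max` aggregator is
available; the mean is the default because it is robust to single-SNP
noise).

**Scan rules.** The empirical threshold retains exactly
$\lceil f\,n\rceil$ windows on distinct values (ties broadened inclusively);
the joint selection requires all three statistics at once. Because the study
design has two reference populations, the condition can be required against
*both* references or against *either*; we default to `either` — the
per-comparison signals are individually noisy at realistic sample sizes
(6–13 diploids), and demanding six simultaneous order-statistics passes
empirically suppresses true sweeps far more than it suppresses drift
outliers (see the calibration section). Merging counts gaps on the grid of
*retained* windows, since windows removed by the `< 5` SNP filter carry no
statistics; the ">30 kb" length filter is a strict inequality (a three-window
region is dropped).

## The synthetic cohort

Real applications of this scan use resequencing cohorts and RNA-seq that are
external resources; the package instead ships a generator whose outputs have
the statistical structure the scan assumes, with recorded ground truth.

`simulate_haplotypes()` is a forward Wright–Fisher simulator on a discrete
bp grid: an ancestral diploid population of $N = 200$ evolves
$10N$ generations from a monomorphic start (near mutation–drift
equilibrium; the expected diversity deficit $e^{-5}$ is under 1%), splits
into three equal-size daughters, and a single copy of a sweep allele is
introduced into the focal daughter partway through the post-split epoch,
evolving under additive selection (fitnesses $1, 1+s, 1+2s$). The sweep is
conditioned by rejection: the selection phase restarts whenever the allele
is lost or ends the epoch below frequency 0.95. Mutation is infinite-sites
(duplicate bp draws rejected), recombination is Poisson crossovers per
meiosis. Scaled rates are chosen so that per-bp $\theta = 4N\mu \approx
4.5\times10^{-4}$, i.e. roughly 20–35 SNPs per 10-kb window in the pooled
sample of 6 + 6 + 13 diploids — dense enough that the `< 5` SNP window
filter rarely triggers under neutrality.

Two desk-scale facts shape every validation result and are worth stating
plainly. First, with $N s = 20$, a sweep needs on the order of
$(2/s)\ln(4Ns) \approx 90$ generations; in drift units that is a *long*
time, so new mutation re-accumulates diversity inside the swept region
while the sweep is still running. The floor is
$\pi_\mathrm{sweep}/\pi_\mathrm{neutral} \approx t_\mathrm{sweep}/2N$,
independent of the mutation rate — the achievable $\pi$-ratio at the core is
bounded near $2N/t_\mathrm{sweep} \approx 5$–8, not the orders of magnitude
seen in real data where sweeps are fast relative to $2N$. Second, the same
ratio controls haplotype erosion, so the detectable footprint spans only a
few 10-kb windows. The default generator therefore emulates *strong,
recent* artificial selection, the regime the scan targets: the selection
phase occupies the last 50 generations of the post-split epoch
(`sweep_intro_gen = split_time_gens - 50`), and rejection conditioning
keeps only trajectories that complete within it. This matches the history
of an indigenous breed shaped by intense selection over a few dozen
generations, and it is the regime in which the three signatures co-occur
sharply enough to be jointly thresholded.

The recorded true sweep interval is `sweep_pos` $\pm$ 45 kb: the
half-reduction distance of hitchhiking, $\ln 2/(r\,T)$ with $T \approx 50$
generations of recombination exposure at the default $r$, i.e. the region
where the sweep is expected to have removed at least half the diversity.

`simulate_counts()` draws gene-wise negative-binomial counts for the
3-vs-3 two-condition design: baseline means log-normal (median 100),
dispersion 0.1, per-sample size factors log-uniform in $[0.7, 1.4]$, and a
planted log2 fold change of 2 for the DE genes. The truth table records
everything.

What the generator does *not* emulate: demographic asymmetry between the
reference populations (the real references are a domestic breed and wild
boars with different histories), linked background selection, variable
recombination and mutation rate along the chromosome, genotyping and
phasing error, and multi-chromosome structure. Passing tests on these data
therefore show that the scan's machinery is correct and calibrated for the
idealized signature, not that its operating characteristics transfer to any
particular real cohort.

## Calibration results the package tests enforce

* Exactness: each statistic matches an independent brute-force
  implementation ($10^{-12}$, exact integer pair counts for EHH) on
  randomized small instances.
* Boundary behavior is pinned: fixed differences give $F_{ST} = 1$;
  identical populations give XP-EHH raw scores of exactly 0 and swapping
  populations negates them; z-scores have mean 0 and sd 1 to $10^{-9}$;
  the window filter, top-10% rule, gap merging and 30-kb filter behave
  exactly as stated at their boundaries.
* Under the default sweep conditions a called sweep overlaps the true
  interval in roughly 60% of seeded replicates, and under neutrality the
  total called span stays below 2% of the genome in roughly 90% of
  replicates (`scripts/acceptance.R` measures both rates from scratch).
  The desk-scale margins are intrinsically thin (see above): the sweep's
  windows sit at the 88th–97th percentile of the empirical distributions,
  each joint selection is a stack of marginal order-statistics events, and
  the called footprint spans only 2–3 windows, so the ">30 kb" rule prunes
  genuine detections. Raising recovery materially would require conditions
  the design does not assume — larger `Ns`, larger samples, or a longer
  genome for the empirical thresholds.
* The DE stage recovers planted fold changes within $\pm 0.3$, controls
  empirical FDR near its nominal level, and recovers size factors within a
  few percent.

## Numerical and design choices

* Internal coordinates are 1-based inclusive (VCF/GTF native); BED output
  converts to 0-based half-open at the boundary only.
* The variant filter retains `QUAL >= 20` and site-level `INFO/DP >= 10`
  (GATK-style site annotations, not per-sample depths) and drops
  monomorphic records; records missing either annotation are dropped and
  counted.
* Windows are anchored at position 1; the terminal partial window is kept
  if it passes the SNP filter.
* Undefined or infinite statistics never propagate silently: each carries
  an explicit `NA`/sentinel rule documented at its definition.
* The DE stage is intentionally minimal (median-of-ratios normalization,
  Welch t on `log2(normalized + 1)`, BH over defined p-values only): it is
  plumbing that keeps the pipeline self-contained, not a reimplementation
  of a shrinkage-based DE method, and an externally produced DE table can
  be supplied instead. At 3-vs-3 the Welch test is slightly conservative
  for low-count genes; the planted-effect recovery and FDR calibration
  tests quantify the consequences.
* Tie-breaks: empirical thresholds broaden ties inclusively, so "all values
  equal" selects everything (with a warning) rather than nothing.

## Problem sizes used in the shipped validation

The test suite and acceptance script run the full pipeline at the default
desk scale (1 Mb, $N = 200$, 25 sampled diploids, ~100 windows, ~2,000
count genes), with 10 seeded replicates for the sweep-recovery and
neutrality checks and 20 for the DE calibration; oracle-equivalence suites
use 100+ randomized instances of up to 20 haplotypes and 50 SNPs. These
sizes keep every property statistically meaningful while the whole suite
runs in minutes on one core.

## Known limitations

* Desk-scale selection ($Ns = 20$) caps every signature; real cohorts with
  $Ns$ in the hundreds separate far more cleanly.
* The scan assumes phased, biallelic, complete genotypes; sites with any
  missing genotype are dropped.
* Gene annotation of sweeps uses simple interval overlap (>= 1 bp);
  functional classes come from a supplied table, not a variant-effect
  predictor.
* A single chromosome per run; multi-chromosome inputs are scanned
  per chromosome.
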