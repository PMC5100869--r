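---
title: "Modelling and analysing postnatal DNA methylation dynamics from RRBS counts"
author: "methylDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing postnatal DNA methylation dynamics from RRBS counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDynamics)
```

# Scope and scientific setting

The developing mouse liver undergoes extensive DNA methylation remodelling
in the first weeks after birth: the great majority of assayable CpGs shift
methylation between late gestation (E18.5) and adulthood (9 weeks), the
changes are strongly biased toward methylation gain, magnitudes reach tens
of percentage points, and most of the movement is concentrated after
postnatal day 5 — coinciding with the terminal differentiation of
hepatoblasts into hepatocytes rather than with the earlier exodus of
hematopoietic cells. Interpreting bulk-liver bisulfite data over this window
is complicated by two confounders that this package models explicitly: the
tissue is a *mixture* of a parenchymal (hepatocyte-lineage) compartment and
a hematopoietic compartment whose proportions change dramatically with age,
and rapid cell division transiently *dilutes* observed methylation because
newly replicated DNA is hemimethylated.

`methylDynamics` implements the complete post-alignment analysis of such
reduced representation bisulfite sequencing (RRBS) count data — quality
control, two-group differential methylation, time-course trajectory
classification, and CpG-density-matched enrichment of genomic features —
together with a generative RRBS simulator, so that every stage is
exercisable and testable without any external data. The pipeline starts at
per-CpG count files (the Bismark coverage dialect); read alignment and
read-level QC are out of scope.

# The data container

`MethylationExperiment` extends `RangedSummarizedExperiment` with three
assays: methylated counts, total counts, and a logical *mask* marking
missing cells. Masking, rather than overwriting counts, keeps every filter
reversible and idempotent: all downstream statistics (fractions, group
means, tests) are computed on unmasked cells only. Sites are width-1
`GRanges` anchored at the plus-strand C of each CpG; opposite-strand
records are collapsed to this single anchor throughout, a documented
convention rather than a claim about the upstream extraction software.
Coordinates are 1-based closed internally; BED input/output is 0-based
half-open and converted at the boundary.

# The generative model

The simulator is a first-class, tested component whose defaults *are* the
study conditions being emulated. Its stages:

1. **Genome and digest.** `generateGenome()` draws an i.i.d. contig at a
   target GC content (default 0.42, mouse-like). `mspiDigest()` cuts at
   every CCGG using the enzyme's actual C^CGG convention — the fragments
   provably tile the contig. `sizeSelect()` keeps fragments of 150–600 bp
   inclusive (gel-extraction window), and `enumerateAssayedCpGs()` declares
   a CpG assayable when its C lies within one 50 bp read of a fragment end,
   approximating single-end sequencing from both fragment ends.
2. **Trajectories.** `assignTrajectories()` draws, per CpG, whether it
   changes (default probability 0.79), the direction (gain with probability
   0.89), a total magnitude uniform on 5–88 percentage points, and a shape:
   *discrete* (one step carrying the whole change, at an interval drawn
   from onset weights that put most mass after P5 and peak at P10→P15),
   *continuous* (monotone with every step guaranteed below half the
   total), or *other* (a non-monotone zig-zag whose largest step stays
   below half the total variation). The default shape mix (0.5/0.3/0.2) is
   a package choice; no empirical shape frequencies are asserted anywhere.
   Baselines are drawn from a bimodal Beta mixture (methylomes cluster near
   0 and 1) with room for the sampled change, so all values stay in [0, 1]
   by construction. A second, age-constant methylome is drawn for the
   hematopoietic compartment: its cells are exchanged for parenchyma over
   development, not remodelled.
3. **Mixture and dilution.** Observed truth per age is
   `f·m_hema + (1−f)·m_hep` with the hematopoietic fraction `f` following
   the histological schedule (0.48, 0.62, 0.38, 0.04, 0.01, 0 from E18.5
   through P20, 0 at 9 wk), then scaled by `1 − d/2` where `d` is the
   dividing-cell fraction (default: linear decline from 0.10 at E18.5 to 0
   in the adult; the endpoints are motivated by the dilution argument below
   and by the declining-division phenotype, and are clearly defaults, not
   measurements).
4. **Counts.** Coverage is negative-binomial with mean 40 (size 20 by
   default; Poisson at infinite dispersion) — only the mean is an emulated
   study condition, the shape is a modelling choice. Methylated calls are
   binomial with read-level probability `p = m + (1−m)·ε`, where
   `ε = 0.005` is the bisulfite non-conversion rate (the only error mode
   modelled; no over-conversion or sequencing error, which keeps the
   closed-form moment `E[X/N] = m + (1−m)ε` exactly testable). Zero
   coverage encodes missingness.

Every generator is a pure function of its configuration and seed.
`writeRRBSDataset()`/`readRRBSDataset()` round-trip the simulation through
the on-disk Bismark-dialect format byte-identically.

What the simulator does **not** emulate: PCR duplicates, fragment-level
coverage correlation along reads, SNP-induced CpG/CpH misclassification,
batch effects between cohorts, or biological replicate variance beyond
count noise. Tests that pass on simulated data therefore certify the
*statistical machinery* under the stated generative assumptions, not
robustness to those unmodelled artefacts.

# Quality control

The cascade runs in a fixed, documented order: (i) cells under 10×
coverage are masked as missing (strict "fewer than": 10 reads is
retained); (ii) samples are scored by completeness and removed below a
cutoff; (iii) CpGs missing in strictly more than 20% of the remaining
samples are removed (exactly 20% is retained); (iv) CpGs strictly below
10% methylation in *every* unmasked sample are removed as never
methylated — a single sample at or above 10% rescues a site, and a site
with no unmasked cell at all is removed with a distinct `no_data` reason.
Running the missingness filter after sample removal is a deliberate
contract: the retained sample set defines the missingness denominators.

The sample score weights each CpG by the fraction of samples with data at
it and sums those weights over the CpGs a sample covers, so a sample
covering few but universally shared CpGs outscores one covering many
private CpGs. The historical absolute cutoff of 50,000 score units is tied
to genome-scale panels; because desk-scale panels have far fewer CpGs the
package also accepts a relative cutoff (fraction of the maximum attainable
score, default 0.5), and the scores are computed on the post-mask,
pre-CpG-filter matrix. Multidimensional-scaling outlier removal is *not*
automated — there is no defensible quantitative criterion — so ordination
is left to the analyst.

`screenCpH()` implements the conversion sanity screen: a CpH site is
flagged when every unmasked sample of at least one group exceeds 5%
methylation. On simulated panels with ε ≤ 0.01 and ≥ 10,000 observations
the estimated conversion rate `100·(1 − Σmeth/Σtotal)` exceeds 99%.

# Differential methylation

Per CpG, group means (percentages, unmasked cells only) are compared with a
two-sided pooled-variance Student's t-test; Welch is available behind a
flag but the equal-variance form is the default, matching the named test.
The implementation is vectorised over sites for speed and is cross-checked
in the test suite against `stats::t.test(var.equal = TRUE)` on random
inputs. Sites with fewer than two observations in either group are
*untestable* (excluded and reported as such, never silently called).
Degenerate variance resolves to p = 1 at equal means and p = 0 otherwise.

FDR control is Benjamini–Hochberg by default — deterministic, no tuning —
with Storey q-values (λ grid 0.05–0.95 step 0.05, spline-smoothed π₀)
available as an option. NA p-values propagate without inflating the test
count. Significance requires *both* `|Δ| > 5` percentage points (strictly
greater; the comparator is configurable, and the thresholds are percentage
points — e.g. 5% → 10% methylation qualifies) *and* `q ≤ 0.1`. Significant
sites are binned into moderate (5–30) and major (> 30 points) changes;
`directionSummary()` reports the gain fraction and `concordance()` the
fraction of secondary-dataset significant sites recovered in a primary
dataset on their shared site universe.

# Time-course analysis

`trajectoryMeans()` collapses replicates to per-age means; an age with no
unmasked observation at a site is skipped and the flanking delta bridges
the gap (the deltas always telescope to last-minus-first). Interval change
counts use an inclusive ≥ 30-point rule ("30% or more"), intentionally
different from the strict > 5 of the two-group caller; both comparators
follow their respective operational definitions and are configurable.
`sustainedCrosstab()` intersects the per-interval changing sets, so the
diagonal reproduces the interval counts.

Pattern classification applies the 50% single-step rule: a changing
trajectory is *discrete* when its largest step in the direction of the net
change carries at least half of the **total variation** (the sum of
absolute consecutive steps), *continuous* when it is monotone (non-strict,
since means are noisy) with every step below half, and *other* otherwise.
Measuring "total change" as total variation is a deliberate design choice:
for monotone trajectories it coincides exactly with the absolute net
change, so the canonical discrete and continuous examples are unaffected,
while for non-monotone trajectories it prevents one leg of a large zig-zag
(e.g. 10, 40, 20, 50, 30, 60) from being mislabelled as a discrete switch —
such shapes belong in *other*. Ties at exactly 50% are discrete ("50% or
more"). Net changes of at most 5 points are *unchanged*; fewer than three
observed ages is *unclassifiable*. Classification is exhaustive and
mutually exclusive over changing sites, and reversing a trajectory flips
the direction while preserving the class.

# Genomic context and enrichment

Interval arithmetic is native `GenomicRanges`: promoters are the 1 kb
strand-aware upstream of each TSS (clipped at contig bounds), and the genic
hierarchy is made exclusive by the literal two-step subtraction — exons
minus promoters, then introns minus the surviving exons. That two-step rule
can leave intron/promoter overlap; the residue is measured and attached as
an attribute rather than silently removed. Overlap uses half-open-aware
containment of the 1-based C position; distances are gap lengths (bases
strictly between site and feature), 0 on overlap, undefined (NA) when a
chromosome carries no feature.

Local CpG density counts CpGs whose C lies within ±200 bp of the focal C
(401 bp window, focal included); GC content is computed on the same
(clipped) window. The density-matched resampling test draws, for each focal
site, a universe site with **exactly** the same integer density (no
binning — "exactly" is taken literally), without replacement within one
resample; the focal set itself stays eligible for redraw (both behaviours
are switches, and an unmatched density is a hard error listing the values,
never a silent nearest-match). Per track, `fold` is observed over the
resample mean and both empirical tails are reported as raw tail fractions
(`#{count ≥ observed}/n` and the ≤ analogue; ties count in both, so the
two p-values sum to at least 1). A `(1+k)/(1+n)` zero-avoiding variant is
available. Focal groups mirror the analysis grouping: direction × pattern ×
magnitude bin. The whole procedure is deterministic given the seed, and on
a six-site uniform-density universe the resampled null reproduces the
exhaustively enumerated `C(6,2)` distribution.

`naiveFold()` keeps the unadjusted comparison available (e.g. 5.3% of
promoter CpGs changing versus 8.5% overall is a 1.60-fold depletion) —
precisely the statistic the density-matched test improves upon.

# Small analytic models

*Hemimethylation dilution*: with a fraction `f` of cells actively dividing
and locus methylation `m` percent, half the molecules of each dividing cell
read unmethylated, so the expected decrease is `m·f/2` points — 5 points at
`f = 0.10`, `m = 100`. The model assumes fully asynchronous division with a
single unreplicated-remethylation lag per cell; no cell-cycle-phase or
region-specific remethylation kinetics are modelled.

*Quantification granularity*: a CpG covered by `n` reads takes values on a
`100/n`-percent grid (2.5% at 40×).

*Methylation-level distributions*: per-group histograms (1-point bins by
default) plus the modal high-methylation level. At ~40× coverage the
all-reads-methylated outcome has non-negligible probability, which puts a
discrete spike at exactly 100% even when true methylation is below 1; a raw
histogram argmax would therefore be unstable. The high mode is instead the
argmax of a fixed-bandwidth (2-point) Gaussian kernel density restricted to
the ≥ 50% region — under dilution by `f` at `m = 1` the mode sits near
`100·(1 − f/2)`, and the diluted-versus-undiluted mode gap recovers `m·f/2`
within count noise.

# Orchestration, determinism and problem sizes

`runPipeline()` sequences QC → differential calls → time-course →
enrichment on *one cohort at a time* (cohorts are analysed separately by
design; there is no cross-cohort correction), aborts any failure with the
stage name, logs every removed entity exactly once with a machine-readable
reason, and emits a funnel-style plain-text report (sites in → retained →
significant). All stages are pure functions of (inputs, config, seed). The
exported functions, the worked examples and the acceptance script are the
package's interface; there is no shell wrapper.

The test suite exercises the pipeline at desk scale — panels of a few
hundred to 5,000 CpGs, 2–7 age groups, 2–5 replicates, 100–1,000 resamples
— sizes chosen so the full suite completes in well under a minute while
keeping every Monte-Carlo assertion inside 3σ bands of its closed-form or
exhaustively enumerated expectation. Genome-scale behaviour differs only in
constant factors: every algorithm is linear or `n log n` in sites.

# Known limitations

* The t-test on fractions ignores the binomial mean–variance relationship;
  beta-binomial or logistic models are deliberately out of scope.
* Trajectory classification is rule-based; no smoothing or changepoint
  inference is attempted beyond the 50% rule.
* The dividing-fraction schedule and the trajectory shape mix are
  modelling defaults, not measured quantities.
* The simulator's replicate variance is pure count noise; real biological
  replicates are overdispersed, so real-data sensitivity will be lower
  than the simulated recovery rates at matched settings.

# Session-free example

```{r example, eval = FALSE}
ages <- c("E18.5", "P5", "P10", "P15", "9wk")
sim <- simulateRRBS(genome = generateGenome(60000, seed = 1),
                    ages = ages, n_replicates = 3,
                    trajectory = trajectoryConfig(ages),
                    schedule = cellCompositionSchedule(
                      ages, c(0.48, 0.38, 0.04, 0.01, 0),
                      c(0.10, 0.07, 0.05, 0.02, 0)),
                    seed = 1)
res <- runPipeline(sim$experiment, seed = 1)
cat(res$report, sep = "\n")
```
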