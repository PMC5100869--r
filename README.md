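# methylDynamics

Simulation and analysis of developmental DNA methylation dynamics from
reduced representation bisulfite sequencing (RRBS) count data, modelled on
the postnatal mouse liver.

The first weeks of life remodel the liver methylome on a scale unusual for
a healthy adult tissue: most assayable CpGs shift methylation between late
gestation and adulthood, with a strong bias toward gain and magnitudes of
up to tens of percentage points, concentrated after postnatal day 5. Bulk
liver is simultaneously losing its hematopoietic compartment and dividing
rapidly, and both confound bisulfite measurements. This package is for
epigenomics analysts who want the full post-alignment RRBS workflow —
quality control, differential methylation, time-course trajectory
classification, feature enrichment — together with a generative simulator
that makes every stage testable offline, with those confounders modelled
explicitly.

## What it computes

Data live in a `MethylationExperiment` (an S4 extension of
`RangedSummarizedExperiment`) holding methylated counts *M*, total counts
*N* and an explicit missingness mask over CpG sites × samples.

* **Simulator** — in-silico MspI digestion (C^CGG), 150–600 bp size
  selection, read-end CpG enumeration; ground-truth trajectories
  (change probability 0.79, gain bias 0.89, magnitudes 5–88 points,
  discrete/continuous/other shapes); two-compartment mixing
  `f·m_hema + (1−f)·m_hep` with a histology-based hematopoietic schedule;
  cell-division dilution `m·(1 − d/2)`; negative-binomial coverage (mean
  40×) with binomial calls at `p = m + (1−m)·ε`, bisulfite non-conversion
  `ε = 0.005`.
* **QC** — mask cells with `N < 10`; score samples by
  completeness-weighted coverage `score_s = Σ_c w_c·I(covered)`,
  `w_c = fraction of samples with data at c`; drop CpGs missing in > 20%
  of samples or unmethylated (< 10%) in every sample; screen CpH sites for
  apparent methylation (> 5% across a whole group).
* **Differential methylation** — per-CpG pooled-variance Student's *t* on
  methylation percentages, Benjamini–Hochberg (or Storey) FDR, and the
  joint rule |Δ| > 5 points **and** q ≤ 0.1, with 5–30 / ≥ 30 magnitude
  bins, gain-fraction summaries, and cross-dataset concordance.
* **Time-course** — consecutive-age deltas with gap bridging, ≥ 30-point
  interval change counts, sustained-change cross-tabulation, and the 50%
  single-step rule classifying changing CpGs into discrete, continuous and
  other patterns.
* **Genomic context** — strand-aware 1 kb promoters, the exclusive
  promoter/exon/intron hierarchy, overlap and distance annotation, ±200 bp
  CpG density and GC, the naive fold `max(p_f/p_u, p_u/p_f)`, and a
  CpG-density-matched resampling test (1000 draws, exact integer density
  matching, empirical tail p-values) for feature enrichment.
* **Analytic models** — hemimethylation dilution `m·f/2`, quantification
  granularity `100/N`, and per-age methylation-level distributions with a
  kernel-density high mode.

## Worked example

Simulate a five-age liver cohort on a synthetic 60 kb contig and run the
pipeline end to end:

```r
library(methylDynamics)

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
#> input: 302 sites x 15 samples
#> seed: 1
#> qc: 302 sites and 15 samples retained (0 removal records)
#> diff (E18.5 vs 9wk): 302 tested, 233 significant (68 at 5-30, 165 at >=30), gain fraction 0.781
#> timecourse: 233 trajectories; patterns continuous=50, discrete=134, other=49

res$interval_counts
#>    interval gain loss
#> 1 E18.5->P5   10    2
#> 2   P5->P10   29    8
#> 3  P10->P15   29    6
#> 4  P15->9wk   21    4
```

The digest of the 60 kb contig yields 302 assayable CpGs; 233 of them
change significantly between E18.5 and 9 wk (joint |Δ| > 5, q ≤ 0.1 rule),
165 by more than 30 points. The observed gain fraction (0.781) sits below
the generator's hepatocyte-lineage gain bias (0.89) because at E18.5 the
bulk signal is almost half hematopoietic — exactly the mixture confounding
the simulator is built to reproduce. The interval counts show the change
concentrated after P5, mirroring the configured onset weights.

The analytic calculators print their textbook values:

```r
expectedDilution(0.10, 100)   # 5   (points lost when 10% of cells divide)
quantificationInterval(40)    # 2.5 (% granularity at 40x coverage)
naiveFold(5.3, 8.5)           # fold 1.60, direction "depletion"
```

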