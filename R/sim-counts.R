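drawCoverage <- function(n, noise) {
  x <- if (is.finite(noise$coverage_dispersion)) {
    stats::rnbinom(n, mu = noise$coverage_mean,
                   size = noise$coverage_dispersion)
  } else {
    stats::rpois(n, noise$coverage_mean)
  }
  as.integer(x)
}

#' Simulate bisulfite read counts for one sample
#'
#' Coverage is drawn from a negative-binomial (Poisson when the dispersion is
#' infinite) with the configured mean; methylated calls are binomial with
#' read-level success probability `p = m + (1 - m) * nonconversion_rate`,
#' i.e. failed conversion is the only error mode. Zero coverage encodes a
#' missing observation.
#'
#' @param m_true Vector of true methylation fractions in `[0, 1]`.
#' @param noise A [noiseModel()].
#' @param seed Integer seed.
#'
#' @return A list with integer vectors `meth` and `total`.
#' @export
simulateCounts <- function(m_true, noise = noiseModel(), seed = NULL) {
  stopifnot(inherits(noise, "NoiseModel"))
  assertProportion(m_true, "'m_true'")
  withSeed(seed, {
    n <- length(m_true)
    total <- drawCoverage(n, noise)
    p <- m_true + (1 - m_true) * noise$nonconversion_rate
    meth <- stats::rbinom(n, total, p)
    list(meth = meth, total = total)
  })
}

#' Simulate a CpH conversion-control panel
#'
#' Non-CpG cytosines are (by construction) unmethylated in the simulated
#' tissue, so every methylated CpH call arises from failed bisulfite
#' conversion. The panel therefore estimates the conversion rate:
#' `100 * (1 - sum(meth) / sum(total))` per sample.
#'
#' @param genome A [SyntheticGenome-class] with at least `n_sites` CpH
#'   cytosines.
#' @param n_sites Number of CpH positions to assay.
#' @param n_samples Number of samples.
#' @param noise A [noiseModel()].
#' @param seed Integer seed.
#'
#' @return A list with `sites` (GRanges, context `"CpH"`), `meth` and
#'   `total` (site x sample integer matrices).
#' @export
simulateCpHPanel <- function(genome, n_sites, n_samples = 1,
                             noise = noiseModel(), seed = NULL) {
  stopifnot(is(genome, "SyntheticGenome"), inherits(noise, "NoiseModel"))
  pos <- cphPositions(genome)
  if (n_sites > length(pos)) {
    stop("genome has only ", length(pos), " CpH cytosines, need ", n_sites)
  }
  withSeed(seed, {
    pos <- sort(sampleExactly(pos, n_sites))
    gr <- GenomicRanges::GRanges(names(genome),
                                 IRanges::IRanges(pos, width = 1L))
    S4Vectors::mcols(gr)$context <- rep("CpH", length(gr))
    meth <- matrix(0L, n_sites, n_samples)
    total <- matrix(0L, n_sites, n_samples)
    for (j in seq_len(n_samples)) {
      cnt <- simulateCounts(rep(0, n_sites), noise)
      meth[, j] <- cnt$meth
      total[, j] <- cnt$total
    }
    ids <- siteId(names(genome), pos)
    dimnames(meth) <- dimnames(total) <-
      list(ids, sprintf("sample_%d", seq_len(n_samples)))
    list(sites = gr, meth = meth, total = total)
  })
}

#' Estimate bisulfite conversion rates from a CpH panel
#'
#' @param meth,total CpH count matrices (sites x samples) as returned by
#'   [simulateCpHPanel()], or vectors for a single sample.
#'
#' @return Per-sample conversion rate in percent:
#'   `100 * (1 - colSums(meth) / colSums(total))`.
#' @export
estimateConversionRate <- function(meth, total) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  tot <- colSums(total)
  if (any(tot == 0)) stop("a sample has zero CpH observations")
  100 * (1 - colSums(meth) / tot)
}

#' Simulate a full RRBS experiment
#'
#' End-to-end generative model: a CpG panel (from an in-silico MspI digest of
#' a supplied genome, or a synthetic panel of `n_sites` positions), ground
#' truth trajectories for the hepatocyte lineage plus an age-constant
#' hematopoietic methylome, per-age cell-composition mixing and
#' cell-division dilution, and per-sample binomial read counts with
#' bisulfite non-conversion noise.
#'
#' @param genome Optional [SyntheticGenome-class]; when supplied the CpG
#'   panel is `enumerateAssayedCpGs(sizeSelect(mspiDigest(genome)))` and
#'   `n_sites` is ignored.
#' @param n_sites Panel size when no genome is supplied.
#' @param ages Ordered age labels.
#' @param n_replicates Replicates per age (scalar or per-age vector).
#' @param trajectory A [trajectoryConfig()] (defaults to one over `ages`).
#' @param schedule A [cellCompositionSchedule()] over `ages`.
#' @param noise A [noiseModel()].
#' @param cohort,tissue Sample-sheet annotations.
#' @param seed Integer seed; the full simulation is a pure function of the
#'   configuration and this seed.
#'
#' @return A list with `experiment` (a [MethylationExperiment-class]),
#'   `truth` (per-site truth table), `hepatocyte`/`hematopoietic` (true
#'   fraction matrices), `observed_truth` (sites x ages matrix of mixed,
#'   dilution-adjusted true fractions), `sites`, and `genome` (or `NULL`).
#' @export
#' @examples
#' sim <- simulateRRBS(n_sites = 50, ages = c("E18.5", "9wk"),
#'                     n_replicates = 3, seed = 11)
#' sim$experiment
simulateRRBS <- function(genome = NULL, n_sites = 1000,
                         ages = defaultAgeGroups(), n_replicates = 5,
                         trajectory = NULL, schedule = NULL,
                         noise = noiseModel(), cohort = "discovery",
                         tissue = "liver", seed = NULL) {
  if (is.null(trajectory)) trajectory <- trajectoryConfig(age_groups = ages)
  if (is.null(schedule)) schedule <- cellCompositionSchedule(age_groups = ages)
  stopifnot(identical(trajectory$age_groups, ages),
            identical(schedule$age_groups, ages))
  n_replicates <- rep_len(n_replicates, length(ages))
  withSeed(seed, {
    sites <- if (!is.null(genome)) {
      enumerateAssayedCpGs(genome, sizeSelect(mspiDigest(genome)))
    } else {
      GenomicRanges::GRanges("chrS",
        IRanges::IRanges(11L + 41L * (seq_len(n_sites) - 1L), width = 1L))
    }
    if (length(sites) == 0L) stop("no assayable CpGs in the panel")
    traj <- assignTrajectories(sites, trajectory, schedule)
    n <- length(sites)
    k <- length(ages)

    obs_truth <- matrix(0, n, k, dimnames = list(rownames(traj$hepatocyte),
                                                 ages))
    for (g in seq_len(k)) {
      mixed <- mixtureMethylation(traj$hepatocyte[, g],
                                  traj$hematopoietic[, g],
                                  schedule$hematopoietic[g])
      obs_truth[, g] <- divisionDilution(mixed, schedule$dividing[g])
    }

    n_total <- sum(n_replicates)
    meth <- matrix(0L, n, n_total)
    total <- matrix(0L, n, n_total)
    sample_id <- character(n_total)
    age_group <- character(n_total)
    j <- 0L
    for (g in seq_len(k)) {
      for (r in seq_len(n_replicates[g])) {
        j <- j + 1L
        cnt <- simulateCounts(obs_truth[, g], noise)
        meth[, j] <- cnt$meth
        total[, j] <- cnt$total
        sample_id[j] <- paste0(ages[g], "_", r)
        age_group[j] <- ages[g]
      }
    }
    sheet <- data.frame(sample_id = sample_id,
                        age_group = orderedAges(age_group),
                        tissue = tissue, cohort = cohort,
                        stringsAsFactors = FALSE)
    me <- MethylationExperiment(meth, total, sites, sheet)
    list(experiment = me, truth = traj$truth,
         hepatocyte = traj$hepatocyte, hematopoietic = traj$hematopoietic,
         observed_truth = obs_truth, sites = sites, genome = genome)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits one Bismark-dialect coverage file per sample (zero-coverage rows
#' omitted), a TSV sample sheet, and a TSV truth table keyed by site id, so
#' the full simulation round-trips through the package's readers.
#'
#' @param sim Result of [simulateRRBS()].
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, a named list of written paths.
#' @export
writeRRBSDataset <- function(sim, dir) {
  stopifnot(is.list(sim), !is.null(sim$experiment))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory ", dir)
  }
  me <- sim$experiment
  meth <- methCounts(me)
  total <- totalCounts(me)
  rr <- SummarizedExperiment::rowRanges(me)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  cov_files <- character(ncol(me))
  for (j in seq_len(ncol(me))) {
    keep <- total[, j] > 0L
    pct <- sprintf("%.1f", 100 * meth[keep, j] / total[keep, j])
    lines <- paste(chrom[keep], pos[keep], pos[keep], pct,
                   meth[keep, j], total[keep, j] - meth[keep, j],
                   sep = "\t")
    f <- file.path(dir, paste0(colnames(me)[j], ".cov"))
    writeLines(lines, f)
    cov_files[j] <- f
  }
  sheet_file <- file.path(dir, "sample_sheet.tsv")
  writeMethTable(as.data.frame(SummarizedExperiment::colData(me)), sheet_file)
  truth_file <- file.path(dir, "truth.tsv")
  writeMethTable(sim$truth, truth_file)
  invisible(list(coverage = cov_files, sample_sheet = sheet_file,
                 truth = truth_file))
}

#' Read a dataset written by [writeRRBSDataset()]
#'
#' @param dir Directory containing `<sample_id>.cov` files and
#'   `sample_sheet.tsv`.
#'
#' @return A [MethylationExperiment-class].
#' @export
readRRBSDataset <- function(dir) {
  sheet_file <- file.path(dir, "sample_sheet.tsv")
  if (!file.exists(sheet_file)) stop("no sample_sheet.tsv in ", dir)
  sheet <- utils::read.delim(sheet_file, stringsAsFactors = FALSE)
  records <- lapply(sheet$sample_id, function(id) {
    readBismarkCoverage(file.path(dir, paste0(id, ".cov")))
  })
  names(records) <- sheet$sample_id
  buildMethylationExperiment(records, sheet)
}
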