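#' QC configuration
#'
#' Thresholds for the quality-control cascade. Defaults follow standard RRBS
#' practice on genome-scale panels: cells under 10x coverage are missing,
#' CpGs missing in more than 20% of samples are dropped, CpGs below 10%
#' methylation in every sample are dropped as never methylated, and samples
#' whose completeness-weighted score falls below a cutoff are removed. The
#' historical absolute cutoff for genome-scale panels is 50,000 score units;
#' for small panels a relative cutoff (fraction of the maximum attainable
#' score, default 0.5) scales with panel size.
#'
#' @param min_coverage Minimum reads for a cell to count as observed.
#' @param max_missing_fraction A CpG is removed when its missing fraction is
#'   strictly greater than this.
#' @param never_methylated_threshold Percentage below which a sample is
#'   "unmethylated" (strict `<`).
#' @param sample_score_cutoff Absolute score cutoff, or `NULL` to use
#'   `relative_score_cutoff`.
#' @param relative_score_cutoff Fraction of the maximum attainable score.
#' @param cph_threshold CpH screen percentage (strict `>`).
#'
#' @return A list of class `QCConfig`.
#' @export
qcConfig <- function(min_coverage = 10, max_missing_fraction = 0.20,
                     never_methylated_threshold = 10,
                     sample_score_cutoff = NULL,
                     relative_score_cutoff = 0.5,
                     cph_threshold = 5) {
  stopifnot(min_coverage >= 1)
  assertProportion(max_missing_fraction, "'max_missing_fraction'")
  stopifnot(never_methylated_threshold >= 0,
            never_methylated_threshold <= 100,
            cph_threshold >= 0, cph_threshold <= 100)
  if (!is.null(sample_score_cutoff)) stopifnot(sample_score_cutoff >= 0)
  assertProportion(relative_score_cutoff, "'relative_score_cutoff'")
  structure(list(min_coverage = min_coverage,
                 max_missing_fraction = max_missing_fraction,
                 never_methylated_threshold = never_methylated_threshold,
                 sample_score_cutoff = sample_score_cutoff,
                 relative_score_cutoff = relative_score_cutoff,
                 cph_threshold = cph_threshold),
            class = "QCConfig")
}

#' Mask low-coverage cells
#'
#' A (site, sample) cell with fewer than `min_coverage` reads is treated as
#' missing data (10x by default, so a cell with 9 reads is masked and one
#' with 10 is retained). Counts are preserved; only the mask changes, so the
#' operation is idempotent and raising the threshold only grows the mask.
#'
#' @param x A [MethylationExperiment-class].
#' @param min_coverage Minimum read count (strict "fewer than" boundary).
#'
#' @return `x` with its mask updated.
#' @export
maskLowCoverage <- function(x, min_coverage = 10) {
  stopifnot(is(x, "MethylationExperiment"), min_coverage >= 1)
  covMask(x) <- covMask(x) | totalCounts(x) < min_coverage
  x
}

#' Score samples by completeness-weighted coverage
#'
#' Each CpG carries a weight equal to the fraction of samples with data at
#' it; a sample's score is the sum of weights over the CpGs it covers. This
#' rewards samples that cover widely-shared CpGs: a sample covering few but
#' universally-shared CpGs scores higher than one covering many private
#' CpGs. Samples below the cutoff are flagged for removal. Scores are
#' computed on the post-mask, pre-CpG-filter matrix.
#'
#' @param x A masked [MethylationExperiment-class].
#' @param cutoff Absolute score cutoff (e.g. 50000 for a genome-scale
#'   panel), or `NULL` to derive it as `relative_cutoff` times the maximum
#'   attainable score `sum(w_c)`.
#' @param relative_cutoff Fraction of the maximum attainable score.
#'
#' @return A data.frame with `sample_id`, `score`, `max_score`, `cutoff`,
#'   `retained`.
#' @export
scoreSamples <- function(x, cutoff = NULL, relative_cutoff = 0.5) {
  stopifnot(is(x, "MethylationExperiment"))
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty methylation matrix")
  covered <- !covMask(x)
  w <- rowMeans(covered)
  score <- colSums(covered * w)
  max_score <- sum(w)
  if (is.null(cutoff)) cutoff <- relative_cutoff * max_score
  data.frame(sample_id = colnames(x), score = unname(score),
             max_score = max_score, cutoff = cutoff,
             retained = unname(score >= cutoff),
             stringsAsFactors = FALSE)
}

#' Remove samples flagged by the completeness score
#'
#' @param x A [MethylationExperiment-class].
#' @param scores Result of [scoreSamples()].
#'
#' @return `x` restricted to retained samples, with the removal logged.
#' @export
filterSamplesByScore <- function(x, scores) {
  stopifnot(is(x, "MethylationExperiment"),
            all(c("sample_id", "retained") %in% colnames(scores)))
  drop <- scores$sample_id[!scores$retained]
  out <- x[, !colnames(x) %in% drop]
  appendQcLog(out, "sample_score", "sample", drop, "score_below_cutoff")
}

#' Remove CpGs with excessive missing data
#'
#' A CpG is removed when strictly more than `max_missing_fraction` of
#' samples are missing at it (so 3 of 15 missing, exactly 20%, is retained).
#'
#' @param x A masked [MethylationExperiment-class].
#' @param max_missing_fraction Missingness bound (strict `>` removal).
#'
#' @return `x` restricted to retained CpGs, with removals logged.
#' @export
filterHighMissingness <- function(x, max_missing_fraction = 0.20) {
  stopifnot(is(x, "MethylationExperiment"))
  assertProportion(max_missing_fraction, "'max_missing_fraction'")
  miss <- rowMeans(covMask(x))
  drop <- miss > max_missing_fraction
  out <- x[!drop, ]
  appendQcLog(out, "missingness", "cpg", rownames(x)[drop],
              "missing_fraction_above_threshold")
}

#' Remove never-methylated CpGs
#'
#' A CpG is removed when every unmasked sample shows methylation strictly
#' below `threshold` percent (one sample at or above the threshold rescues
#' the site). A CpG with no unmasked cells at all is removed with a distinct
#' `no_data` reason.
#'
#' @param x A masked [MethylationExperiment-class].
#' @param threshold Percentage (default 10).
#'
#' @return `x` restricted to retained CpGs, with removals logged.
#' @export
filterNeverMethylated <- function(x, threshold = 10) {
  stopifnot(is(x, "MethylationExperiment"))
  pct <- methFraction(x, percent = TRUE)
  n_obs <- rowSums(!is.na(pct))
  any_meth <- rowSums(pct >= threshold, na.rm = TRUE) > 0
  no_data <- n_obs == 0L
  never <- !no_data & !any_meth
  out <- x[!(never | no_data), ]
  out <- appendQcLog(out, "never_methylated", "cpg", rownames(x)[never],
                     "unmethylated_in_all_samples")
  appendQcLog(out, "never_methylated", "cpg", rownames(x)[no_data],
              "no_data")
}

#' Screen CpH sites for apparent methylation
#'
#' A CpH site is flagged when there exists at least one sample group in
#' which every unmasked sample shows methylation strictly above `threshold`
#' percent (a conversion-failure or misclassification signature). Groups
#' with no unmasked observation at a site cannot flag it.
#'
#' @param x A [MethylationExperiment-class] of CpH sites.
#' @param groups Per-sample grouping factor; defaults to `ageGroups(x)`.
#' @param threshold Percentage (default 5, strict `>`).
#'
#' @return A data.frame with `site`, `flagged`, and the flagging `group`
#'   (`NA` when not flagged).
#' @export
screenCpH <- function(x, groups = NULL, threshold = 5) {
  stopifnot(is(x, "MethylationExperiment"))
  if (is.null(groups)) groups <- ageGroups(x)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(x))
  pct <- methFraction(x, percent = TRUE)
  flagged <- rep(FALSE, nrow(x))
  flag_group <- rep(NA_character_, nrow(x))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    sub <- pct[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    all_above <- n_obs > 0L & rowSums(sub > threshold, na.rm = TRUE) == n_obs
    newly <- all_above & !flagged
    flag_group[newly] <- g
    flagged <- flagged | all_above
  }
  data.frame(site = rownames(x), flagged = flagged, group = flag_group,
             stringsAsFactors = FALSE)
}

#' Run the full QC cascade
#'
#' Fixed order: coverage masking, sample scoring and removal, CpG
#' missingness filter, never-methylated filter. Sample scores are computed
#' on the post-mask, pre-CpG-filter matrix, and the missingness filter runs
#' after sample removal so that the retained sample set defines the
#' missingness denominators.
#'
#' @param x A [MethylationExperiment-class].
#' @param config A [qcConfig()].
#'
#' @return A list with `experiment` (the filtered object, removal log in
#'   `qcLog()`) and `sample_scores`.
#' @export
runQC <- function(x, config = qcConfig()) {
  stopifnot(is(x, "MethylationExperiment"), inherits(config, "QCConfig"))
  x <- maskLowCoverage(x, config$min_coverage)
  scores <- scoreSamples(x, cutoff = config$sample_score_cutoff,
                         relative_cutoff = config$relative_score_cutoff)
  x <- filterSamplesByScore(x, scores)
  if (ncol(x) == 0L) stop("all samples removed by the completeness score")
  x <- filterHighMissingness(x, config$max_missing_fraction)
  x <- filterNeverMethylated(x, config$never_methylated_threshold)
  list(experiment = x, sample_scores = scores)
}
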