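stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on one cohort
#'
#' Sequences the analysis stages on a single cohort: quality control,
#' two-group differential methylation between the first and last age,
#' time-course trajectory analysis restricted to the significant sites
#' (interval change counts, sustained-change cross-tabulation, pattern
#' classification), and — when feature tracks are supplied — CpG-density-
#' matched enrichment per direction x pattern x magnitude group. Cohorts
#' are analysed one at a time by design; run the pipeline once per cohort.
#' Any stage failure aborts with the stage name and cause, and identical
#' inputs with the same seed reproduce identical outputs.
#'
#' @param x A [MethylationExperiment-class] (one cohort).
#' @param qc A [qcConfig()].
#' @param test A [testConfig()].
#' @param group_a,group_b Age groups for the discovery comparison; default
#'   to the first and last observed ages.
#' @param interval_threshold Percentage points for the interval change
#'   counts.
#' @param min_total_change Percentage points for pattern classification.
#' @param tracks Optional named list of feature [GenomicRanges::GRanges]
#'   for the enrichment stage.
#' @param genome Optional [SyntheticGenome-class]; required for the
#'   enrichment stage (local CpG density).
#' @param n_resamples Resampling draws for the enrichment stage.
#' @param min_group_size Smallest focal group passed to the enrichment
#'   stage.
#' @param seed Integer seed for the resampling stage.
#' @param outdir Optional directory; when given, all result tables and a
#'   plain-text funnel report are written there.
#'
#' @return A list with `qc` (filtered experiment + scores), `calls`,
#'   `summary` (counts by bin and the gain fraction), `trajectories`,
#'   `interval_counts`, `crosstab`, `patterns`, `enrichment` (or `NULL`),
#'   and `report` (character lines).
#' @export
runPipeline <- function(x, qc = qcConfig(), test = testConfig(),
                        group_a = NULL, group_b = NULL,
                        interval_threshold = 30, min_total_change = 5,
                        tracks = NULL, genome = NULL, n_resamples = 1000,
                        min_group_size = 5, seed = NULL, outdir = NULL) {
  stopifnot(is(x, "MethylationExperiment"))
  report <- c(sprintf("input: %d sites x %d samples", nrow(x), ncol(x)),
              sprintf("seed: %s", if (is.null(seed)) "none" else seed))

  qc_res <- stageTry("qc", runQC(x, qc))
  me <- qc_res$experiment
  report <- c(report, sprintf(
    "qc: %d sites and %d samples retained (%d removal records)",
    nrow(me), ncol(me), nrow(qcLog(me))))

  ages <- levels(droplevels(ageGroups(me)))
  if (is.null(group_a)) group_a <- ages[1L]
  if (is.null(group_b)) group_b <- ages[length(ages)]
  calls <- stageTry("diff", callDifferential(me, group_a, group_b, test))
  n_sig <- sum(calls$significant)
  gain_frac <- if (n_sig > 0) directionSummary(calls) else NA_real_
  summary_df <- data.frame(
    n_tested = sum(calls$testable),
    n_significant = n_sig,
    n_moderate = sum(calls$magnitude_bin == "5-30"),
    n_major = sum(calls$magnitude_bin == ">=30"),
    gain_fraction = gain_frac)
  report <- c(report, sprintf(
    "diff (%s vs %s): %d tested, %d significant (%d at 5-30, %d at >=30), gain fraction %s",
    group_a, group_b, summary_df$n_tested, n_sig, summary_df$n_moderate,
    summary_df$n_major,
    ifelse(is.na(gain_frac), "undefined", sprintf("%.3f", gain_frac))))

  traj <- interval_counts <- crosstab <- patterns <- NULL
  if (length(ages) >= 3L) {
    sig_sites <- calls$site[calls$significant]
    traj <- stageTry("timecourse", trajectoryMeans(
      me, sites = if (length(sig_sites)) sig_sites else NULL))
    interval_counts <- stageTry("timecourse",
                                countIntervalChanges(traj, interval_threshold))
    crosstab <- stageTry("timecourse",
                         sustainedCrosstab(traj, interval_threshold))
    patterns <- stageTry("timecourse",
                         classifyPatterns(traj, min_total_change))
    report <- c(report, sprintf(
      "timecourse: %d trajectories; patterns %s",
      nrow(traj),
      paste(names(table(patterns$pattern)), table(patterns$pattern),
            sep = "=", collapse = ", ")))
  } else {
    report <- c(report, "timecourse: skipped (fewer than 3 age groups)")
  }

  enrichment <- NULL
  if (!is.null(tracks)) {
    enrichment <- stageTry("enrich", {
      if (is.null(genome)) stop("enrichment requires a genome")
      rr <- SummarizedExperiment::rowRanges(me)
      ann <- annotateSites(rr, tracks, genome = genome)
      groups <- enrichmentGroups(calls, patterns, min_group_size)
      res <- lapply(names(groups), function(g) {
        er <- densityMatchedEnrichment(ann, groups[[g]],
                                       n_resamples = n_resamples,
                                       seed = seed)
        cbind(group = g, er)
      })
      do.call(rbind, res)
    })
    report <- c(report, sprintf("enrich: %d group x track results",
                                if (is.null(enrichment)) 0L
                                else nrow(enrichment)))
  }

  out <- list(qc = qc_res, calls = calls, summary = summary_df,
              trajectories = traj, interval_counts = interval_counts,
              crosstab = crosstab, patterns = patterns,
              enrichment = enrichment, report = report)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
      stop("cannot create output directory ", outdir)
    }
    writeMethTable(qcLog(me), file.path(outdir, "qc_log.tsv"))
    writeMethTable(qc_res$sample_scores,
                   file.path(outdir, "sample_scores.tsv"))
    writeMethTable(calls, file.path(outdir, "diff_calls.tsv"))
    writeMethTable(summary_df, file.path(outdir, "diff_summary.tsv"))
    if (!is.null(interval_counts)) {
      writeMethTable(interval_counts,
                     file.path(outdir, "interval_counts.tsv"))
    }
    if (!is.null(patterns)) {
      writeMethTable(patterns, file.path(outdir, "pattern_calls.tsv"))
    }
    if (!is.null(enrichment)) {
      writeMethTable(enrichment, file.path(outdir, "enrichment.tsv"))
    }
    writeLines(report, file.path(outdir, "report.txt"))
  }
  out
}

# Focal site groups for the enrichment stage: direction x pattern x
# magnitude bin, mirroring the grouping of changing CpGs by the shape of
# their temporal change.
enrichmentGroups <- function(calls, patterns, min_group_size = 5) {
  sig <- calls[calls$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  if (!is.null(patterns)) {
    pat <- patterns$pattern[match(sig$site, patterns$site)]
  } else {
    pat <- rep("all", nrow(sig))
  }
  key <- paste(sig$direction, pat, sig$magnitude_bin, sep = ".")
  groups <- split(sig$site, key)
  groups[vapply(groups, length, integer(1)) >= min_group_size]
}
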