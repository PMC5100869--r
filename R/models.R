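#' Expected methylation decrease from cell division
#'
#' Newly replicated DNA is transiently hemimethylated: half the strands of a
#' dividing cell read as unmethylated until maintenance methylation catches
#' up. With a fraction `f` of cells actively dividing and a locus methylated
#' at `m` percent, the expected decrease in observed methylation is
#' `m * f / 2` percentage points — 5 points for a fully methylated locus in
#' a sample with 10% of cells dividing.
#'
#' @param dividing_fraction Fraction of actively dividing cells in `[0, 1]`.
#' @param methylation_percent Locus methylation in percent, `[0, 100]`.
#'
#' @return Expected decrease in percentage points.
#' @export
#' @examples
#' expectedDilution(0.10, 100)  # 5
expectedDilution <- function(dividing_fraction, methylation_percent) {
  assertProportion(dividing_fraction, "'dividing_fraction'")
  if (any(!is.finite(methylation_percent)) || any(methylation_percent < 0) ||
      any(methylation_percent > 100)) {
    stop("'methylation_percent' must lie in [0, 100]")
  }
  methylation_percent * dividing_fraction / 2
}

#' Quantification granularity at a given coverage
#'
#' A CpG covered by `n` reads can only take methylation values on a grid of
#' `100 / n` percent: 2.5% intervals at 40x coverage.
#'
#' @param coverage Read count (>= 1).
#'
#' @return Percentage granularity `100 / coverage`.
#' @export
#' @examples
#' quantificationInterval(40)  # 2.5
quantificationInterval <- function(coverage) {
  if (any(!is.finite(coverage)) || any(coverage < 1)) {
    stop("'coverage' must be at least 1")
  }
  100 / coverage
}

#' Per-group methylation-level distribution
#'
#' Histogram of per-cell (site x sample) methylation percentages for one
#' sample group, plus the modal high-methylation level. At typical RRBS
#' coverage the read-sampling process puts a discrete atom at exactly 100%
#' (all reads methylated) even when the underlying methylation is below 1,
#' so the high mode is estimated as the argmax of a fixed-bandwidth Gaussian
#' kernel density restricted to the high-methylation region rather than as
#' the raw histogram argmax.
#'
#' @param x A [MethylationExperiment-class].
#' @param group Age-group label selecting the samples.
#' @param binwidth Histogram bin width in percentage points.
#' @param high_cutoff Lower bound (percent) of the region searched for the
#'   high mode.
#' @param bandwidth Kernel bandwidth in percentage points.
#'
#' @return A list with `histogram` (data.frame `lower`, `upper`, `mid`,
#'   `proportion`; proportions sum to 1), `mode_high` (percent), and `n`
#'   (number of unmasked cells).
#' @export
methylationDistribution <- function(x, group, binwidth = 1,
                                    high_cutoff = 50, bandwidth = 2) {
  stopifnot(is(x, "MethylationExperiment"), binwidth > 0, bandwidth > 0)
  ag <- as.character(ageGroups(x))
  if (!group %in% ag) stop("group '", group, "' absent from the samples")
  pct <- methFraction(x, percent = TRUE)[, ag == group, drop = FALSE]
  vals <- pct[!is.na(pct)]
  if (length(vals) == 0L) stop("group '", group, "' has no unmasked cells")
  breaks <- seq(0, 100 + binwidth, by = binwidth)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE, right = FALSE)
  hist_df <- data.frame(lower = utils::head(h$breaks, -1L),
                        upper = h$breaks[-1L],
                        mid = h$mids,
                        proportion = h$counts / length(vals))
  hist_df <- hist_df[hist_df$lower <= 100, , drop = FALSE]
  grid <- seq(0, 100, by = 0.1)
  dens <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = vals, sd = bandwidth))
  }, numeric(1))
  hi <- grid >= high_cutoff
  mode_high <- if (any(hi)) grid[hi][which.max(dens[hi])] else NA_real_
  list(histogram = hist_df, mode_high = mode_high, n = length(vals))
}
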