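#' Trajectory configuration for the RRBS simulator
#'
#' Defines the ground-truth methylation dynamics of the hepatocyte lineage
#' across an ordered set of developmental ages. Defaults emulate the study
#' conditions of postnatal mouse liver: about 79% of retained CpGs change,
#' 89% of changes are methylation gains, total magnitudes span 5-88
#' percentage points, and most change is concentrated after P5 (dominant
#' interval P10->P15).
#'
#' @param age_groups Ordered character vector of age labels (>= 2).
#' @param change_fraction Probability that a CpG changes with age.
#' @param gain_bias Probability that a changing CpG gains methylation.
#' @param magnitude_range Two-element range (percentage points, within
#'   0-100) for the total change magnitude; sampled uniformly.
#' @param pattern_mix Named probabilities over `discrete`, `continuous` and
#'   `other` trajectory shapes; must sum to 1. `continuous` and `other`
#'   shapes require at least 4 ages (with fewer ages every consecutive step
#'   necessarily carries at least half the change); the default mix adapts
#'   accordingly.
#' @param onset_weights Probabilities over the consecutive age intervals for
#'   the dominant (discrete) change step; length `length(age_groups) - 1`.
#'
#' @return A validated list of class `TrajectoryConfig`.
#' @export
trajectoryConfig <- function(age_groups = defaultAgeGroups(),
                             change_fraction = 0.79,
                             gain_bias = 0.89,
                             magnitude_range = c(5, 88),
                             pattern_mix = NULL,
                             onset_weights = NULL) {
  k <- length(age_groups)
  if (k < 2L) stop("at least two age groups are required")
  if (is.null(pattern_mix)) {
    pattern_mix <- if (k >= 4L) {
      c(discrete = 0.5, continuous = 0.3, other = 0.2)
    } else {
      c(discrete = 1, continuous = 0, other = 0)
    }
  }
  assertProportion(change_fraction, "'change_fraction'")
  assertProportion(gain_bias, "'gain_bias'")
  if (length(magnitude_range) != 2L || any(magnitude_range < 0) ||
      any(magnitude_range > 100) || magnitude_range[1] > magnitude_range[2]) {
    stop("'magnitude_range' must be an increasing range within [0, 100]")
  }
  if (!all(c("discrete", "continuous", "other") %in% names(pattern_mix))) {
    stop("'pattern_mix' needs named entries discrete, continuous, other")
  }
  pattern_mix <- pattern_mix[c("discrete", "continuous", "other")]
  assertProportion(pattern_mix, "'pattern_mix'")
  if (abs(sum(pattern_mix) - 1) > 1e-8) stop("'pattern_mix' must sum to 1")
  if (k < 4L && (pattern_mix[["other"]] > 0 ||
                 pattern_mix[["continuous"]] > 0)) {
    stop("'continuous' and 'other' trajectories need at least 4 age groups")
  }
  if (is.null(onset_weights)) {
    onset_weights <- if (identical(age_groups, defaultAgeGroups())) {
      c(0.03, 0.05, 0.17, 0.40, 0.25, 0.10)  # mass after P5, peak P10->P15
    } else {
      rep(1 / (k - 1), k - 1L)
    }
  }
  if (length(onset_weights) != k - 1L || any(onset_weights < 0)) {
    stop("'onset_weights' must be ", k - 1L, " non-negative weights")
  }
  onset_weights <- onset_weights / sum(onset_weights)
  structure(list(age_groups = age_groups,
                 change_fraction = change_fraction,
                 gain_bias = gain_bias,
                 magnitude_range = magnitude_range,
                 pattern_mix = pattern_mix,
                 onset_weights = onset_weights),
            class = "TrajectoryConfig")
}

#' Cell-composition schedule across ages
#'
#' Per-age hematopoietic cell fraction and actively-dividing cell fraction of
#' the simulated tissue. Defaults follow the histological composition of
#' postnatal mouse liver (hematopoietic: 48, 62, 38, 4, 1, 0 percent from
#' E18.5 through P20, extended with 0 at 9 wk) and a linear decline of the
#' dividing fraction from 0.10 at E18.5 to 0 in the adult.
#'
#' @param age_groups Ordered age labels.
#' @param hematopoietic Per-age hematopoietic fraction in `[0, 1]`; recycled
#'   if scalar.
#' @param dividing Per-age dividing-cell fraction in `[0, 1]`; recycled if
#'   scalar.
#'
#' @return A list of class `CellCompositionSchedule`.
#' @export
cellCompositionSchedule <- function(age_groups = defaultAgeGroups(),
                                    hematopoietic = NULL,
                                    dividing = NULL) {
  k <- length(age_groups)
  if (is.null(hematopoietic)) {
    hematopoietic <- if (identical(age_groups, defaultAgeGroups())) {
      c(0.48, 0.62, 0.38, 0.04, 0.01, 0, 0)
    } else 0
  }
  if (is.null(dividing)) dividing <- seq(0.10, 0, length.out = k)
  hematopoietic <- rep_len(hematopoietic, k)
  dividing <- rep_len(dividing, k)
  assertProportion(hematopoietic, "'hematopoietic'")
  assertProportion(dividing, "'dividing'")
  structure(list(age_groups = age_groups,
                 hematopoietic = stats::setNames(hematopoietic, age_groups),
                 dividing = stats::setNames(dividing, age_groups)),
            class = "CellCompositionSchedule")
}

#' Bisulfite noise and coverage model
#'
#' @param nonconversion_rate Probability that an unmethylated cytosine is
#'   read as methylated (failed bisulfite conversion); must lie in
#'   `[0, 0.05]`. The observed read-level methylation probability is
#'   `p = m + (1 - m) * nonconversion_rate`.
#' @param coverage_mean Mean read coverage per site per sample.
#' @param coverage_dispersion Negative-binomial size parameter of the
#'   coverage distribution; `Inf` gives Poisson coverage.
#'
#' @return A list of class `NoiseModel`.
#' @export
noiseModel <- function(nonconversion_rate = 0.005, coverage_mean = 40,
                       coverage_dispersion = 20) {
  if (!is.numeric(nonconversion_rate) || nonconversion_rate < 0 ||
      nonconversion_rate > 0.05) {
    stop("'nonconversion_rate' must lie in [0, 0.05]")
  }
  if (!is.numeric(coverage_mean) || coverage_mean <= 0) {
    stop("'coverage_mean' must be positive")
  }
  if (!is.numeric(coverage_dispersion) || coverage_dispersion <= 0) {
    stop("'coverage_dispersion' must be positive (Inf for Poisson)")
  }
  structure(list(nonconversion_rate = nonconversion_rate,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion),
            class = "NoiseModel")
}

# Signed step weights (fractions of the total change) realizing one pattern
# over n intervals. Cumulative sums stay within [0, 1] so baselines can be
# drawn from U(0, 1 - magnitude).
patternSteps <- function(pattern, n, onset = NULL) {
  if (pattern == "discrete") {
    w <- numeric(n)
    w[onset] <- 1
    w
  } else if (pattern == "continuous") {
    # positive weights in (0.75, 1.25)/sum: for n >= 3 intervals every step
    # is guaranteed below 50% of the total
    raw <- 0.75 + stats::runif(n) / 2
    raw / sum(raw)
  } else {
    # non-monotone zig-zag with every step below 50% of the total variation
    if (n == 3L) {
      c(0.6, -0.6, 1.0)
    } else {
      w <- rep(c(1.5, -0.5), length.out = n) / n
      w[n] <- w[n] + (1 - sum(w))
      w
    }
  }
}

#' Assign ground-truth methylation trajectories
#'
#' Draws, for every CpG site, whether it changes with age, the direction,
#' pattern and magnitude of the change, and realizes per-age true
#' methylation fractions for the hepatocyte lineage. A second, age-constant
#' methylome is drawn for the hematopoietic compartment (its cells are
#' exchanged for parenchyma over development, not remodelled). Baselines are
#' drawn from a bimodal mixture typical of methylomes (mostly near 0 or 1).
#'
#' @param sites A [GenomicRanges::GRanges] of CpG sites (or an integer site
#'   count).
#' @param config A [trajectoryConfig()].
#' @param schedule Optional [cellCompositionSchedule()]; only checked for age
#'   consistency here (mixing happens at count simulation).
#' @param seed Integer seed.
#'
#' @return A list with elements `truth` (data.frame: `site`, `changed`,
#'   `direction`, `pattern`, `onset_interval`, `total_change` in signed
#'   percentage points, `baseline` fraction), `hepatocyte` and
#'   `hematopoietic` (sites x ages matrices of true methylation fractions),
#'   and `ages`.
#' @export
assignTrajectories <- function(sites, config = trajectoryConfig(),
                               schedule = NULL, seed = NULL) {
  stopifnot(inherits(config, "TrajectoryConfig"))
  if (!is.null(schedule) &&
      !identical(schedule$age_groups, config$age_groups)) {
    stop("schedule and config disagree on age groups")
  }
  ids <- if (is(sites, "GRanges")) {
    siteId(as.character(GenomeInfoDb::seqnames(sites)),
           GenomicRanges::start(sites))
  } else {
    sprintf("site%06d", seq_len(sites))
  }
  n <- length(ids)
  ages <- config$age_groups
  k <- length(ages)
  withSeed(seed, {
    changed <- stats::runif(n) < config$change_fraction
    gain <- stats::runif(n) < config$gain_bias
    magnitude <- stats::runif(n, config$magnitude_range[1],
                              config$magnitude_range[2]) / 100
    pattern <- sample(names(config$pattern_mix), n, replace = TRUE,
                      prob = config$pattern_mix)
    onset <- sample.int(k - 1L, n, replace = TRUE,
                        prob = config$onset_weights)

    baselineDraw <- function(m) {
      kind <- sample.int(3L, m, replace = TRUE, prob = c(0.45, 0.45, 0.10))
      b <- numeric(m)
      b[kind == 1L] <- stats::rbeta(sum(kind == 1L), 1.5, 12)
      b[kind == 2L] <- stats::rbeta(sum(kind == 2L), 12, 1.5)
      b[kind == 3L] <- stats::runif(sum(kind == 3L))
      b
    }

    hep <- matrix(0, n, k, dimnames = list(ids, ages))
    baseline <- baselineDraw(n)
    hep[] <- baseline  # flat for unchanged sites
    for (i in which(changed)) {
      m <- magnitude[i]
      steps <- patternSteps(pattern[i], k - 1L, onset[i])
      prof <- c(0, cumsum(steps)) * m          # within [0, m]
      if (gain[i]) {
        b <- stats::runif(1, 0, 1 - m)
        hep[i, ] <- b + prof
      } else {
        b <- stats::runif(1, m, 1)
        hep[i, ] <- b - prof
      }
      baseline[i] <- hep[i, 1L]
    }
    hema <- matrix(baselineDraw(n), n, k, dimnames = list(ids, ages))

    truth <- data.frame(
      site = ids,
      changed = changed,
      direction = ifelse(changed, ifelse(gain, "increase", "decrease"),
                         NA_character_),
      pattern = ifelse(changed, pattern, NA_character_),
      onset_interval = ifelse(changed & pattern == "discrete",
                              intervalLabels(ages)[onset], NA_character_),
      total_change = ifelse(changed,
                            100 * (hep[, k] - hep[, 1L]), 0),
      baseline = baseline,
      stringsAsFactors = FALSE
    )
    stopifnot(all(hep >= 0 & hep <= 1), all(hema >= 0 & hema <= 1))
    list(truth = truth, hepatocyte = hep, hematopoietic = hema, ages = ages)
  })
}

#' Mixture methylation of a two-compartment tissue
#'
#' The bulk methylation of a site in a tissue composed of parenchymal and
#' hematopoietic cells is the composition-weighted average of the two
#' compartment methylomes.
#'
#' @param m_parenchyma,m_hematopoietic True methylation fractions in
#'   `[0, 1]` (vectorized).
#' @param hsc_fraction Hematopoietic cell fraction in `[0, 1]`.
#'
#' @return `hsc_fraction * m_hematopoietic + (1 - hsc_fraction) *
#'   m_parenchyma`.
#' @export
#' @examples
#' mixtureMethylation(0.8, 0.4, 0.5)  # 0.6
mixtureMethylation <- function(m_parenchyma, m_hematopoietic, hsc_fraction) {
  assertProportion(m_parenchyma, "'m_parenchyma'")
  assertProportion(m_hematopoietic, "'m_hematopoietic'")
  assertProportion(hsc_fraction, "'hsc_fraction'")
  hsc_fraction * m_hematopoietic + (1 - hsc_fraction) * m_parenchyma
}

#' Cell-division (hemimethylation) dilution
#'
#' Immediately after DNA replication the nascent strand is unmethylated, so
#' each actively dividing cell transiently contributes half its molecules as
#' unmethylated. With a fraction `f` of cells dividing, observed methylation
#' is scaled by `1 - f/2`: a locus fully methylated in all cells of a sample
#' with 10% dividing cells reads 5 percentage points lower.
#'
#' @param m True methylation fraction(s) in `[0, 1]`.
#' @param dividing_fraction Fraction of actively dividing cells in `[0, 1]`.
#'
#' @return `m * (1 - dividing_fraction / 2)`.
#' @export
#' @examples
#' divisionDilution(1.0, 0.10)  # 0.95
divisionDilution <- function(m, dividing_fraction) {
  assertProportion(m, "'m'")
  assertProportion(dividing_fraction, "'dividing_fraction'")
  m * (1 - dividing_fraction / 2)
}
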