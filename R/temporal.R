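#' Per-age trajectory means
#'
#' Mean methylation percentage per site per age group, computed on unmasked
#' cells only. Ages with no unmasked observation at a site are `NA`; the
#' downstream trajectory operations bridge such gaps by working on the
#' observed ages only.
#'
#' @param x A [MethylationExperiment-class].
#' @param sites Optional site whitelist (character ids), e.g. the sites
#'   called significant in a discovery comparison.
#'
#' @return A sites x ages numeric matrix of mean percentages, with an `"n"`
#'   attribute holding the per-cell sample counts.
#' @export
trajectoryMeans <- function(x, sites = NULL) {
  stopifnot(is(x, "MethylationExperiment"))
  if (!is.null(sites)) {
    missing_sites <- setdiff(sites, rownames(x))
    if (length(missing_sites)) {
      stop(length(missing_sites), " whitelist site(s) absent from the matrix")
    }
    x <- x[sites, ]
  }
  ag <- ageGroups(x)
  ages <- levels(ag)[levels(ag) %in% ag]
  pct <- methFraction(x, percent = TRUE)
  means <- matrix(NA_real_, nrow(x), length(ages),
                  dimnames = list(rownames(x), ages))
  counts <- matrix(0L, nrow(x), length(ages),
                   dimnames = list(rownames(x), ages))
  for (g in ages) {
    sub <- pct[, ag == g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[n == 0L] <- NA_real_
    means[, g] <- mu
    counts[, g] <- n
  }
  attr(means, "n") <- counts
  means
}

#' Changes between consecutive ages
#'
#' Signed methylation deltas (percentage points) between adjacent observed
#' ages of one trajectory. Ages with missing means are skipped and the
#' flanking delta bridges the gap, so the deltas always telescope: their sum
#' equals last mean minus first mean.
#'
#' @param trajectory Named numeric vector of per-age means (NA = no data).
#'
#' @return Named vector of deltas (`"age1->age2"`).
#' @export
#' @examples
#' consecutiveChanges(c(E18.5 = 10, P1 = 15, P5 = 25, P10 = 55, P15 = 80,
#'                      P20 = 85))
consecutiveChanges <- function(trajectory) {
  obs <- trajectory[!is.na(trajectory)]
  if (length(obs) < 2L) stop("need at least two ages with data")
  d <- diff(obs)
  names(d) <- intervalLabels(names(obs))
  d
}

adjacentDeltas <- function(means) {
  k <- ncol(means)
  d <- means[, -1L, drop = FALSE] - means[, -k, drop = FALSE]
  colnames(d) <- intervalLabels(colnames(means))
  d
}

#' Count sites changing per age interval
#'
#' For each pair of adjacent ages, counts the sites whose methylation gained
#' at least `threshold` percentage points and those that lost at least as
#' much ("30% or more" is inclusive). A site can contribute to several
#' intervals; a site with a missing mean at either flanking age is excluded
#' from that interval.
#'
#' @param means Sites x ages matrix from [trajectoryMeans()].
#' @param threshold Percentage points (inclusive `>=`).
#'
#' @return A data.frame with `interval`, `gain`, `loss`.
#' @export
countIntervalChanges <- function(means, threshold = 30) {
  stopifnot(is.matrix(means), ncol(means) >= 2L, threshold >= 0)
  d <- adjacentDeltas(means)
  data.frame(interval = colnames(d),
             gain = colSums(d >= threshold & d > 0, na.rm = TRUE),
             loss = colSums(-d >= threshold & d < 0, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tabulate sustained changes
#'
#' `M[i, j]` counts the sites changing by at least `threshold` percentage
#' points (either direction) in interval `i` that also change by at least as
#' much in interval `j`. The diagonal equals the per-interval change counts;
#' the matrix is symmetric.
#'
#' @param means Sites x ages matrix from [trajectoryMeans()].
#' @param threshold Percentage points (inclusive `>=`).
#'
#' @return A square integer matrix with interval labels as dimnames.
#' @export
sustainedCrosstab <- function(means, threshold = 30) {
  stopifnot(is.matrix(means), ncol(means) >= 2L, threshold > 0)
  d <- adjacentDeltas(means)
  chg <- !is.na(d) & abs(d) >= threshold
  m <- crossprod(chg)
  storage.mode(m) <- "integer"
  m
}

#' Classify one methylation trajectory
#'
#' Changing trajectories are classified, per the direction of the net
#' change, into:
#' \describe{
#'   \item{discrete}{at least 50% of the total methylation change occurs in
#'     a single consecutive-age step,}
#'   \item{continuous}{a monotone (non-strict) increase or decrease with
#'     every step below 50% of the total,}
#'   \item{other}{all remaining changing trajectories.}
#' }
#' "Total methylation change" is measured as the total variation (the sum of
#' absolute consecutive steps); for monotone trajectories this equals the
#' absolute net change, and for non-monotone ones it prevents a large
#' zig-zag step from masquerading as a discrete switch. A tie at exactly 50%
#' classifies as discrete. A trajectory whose absolute net change is at most
#' `min_total_change` is `unchanged`; fewer than three observed ages is
#' `unclassifiable`.
#'
#' @param trajectory Named numeric vector of per-age mean percentages (NA
#'   ages are bridged).
#' @param min_total_change Percentage points (non-strict `<=` for
#'   unchanged).
#'
#' @return A list with `pattern` (`discrete`, `continuous`, `other`,
#'   `unchanged` or `unclassifiable`), `direction` (`increase`/`decrease` or
#'   NA), `dominant_interval` (for discrete calls), and `total_change`
#'   (signed net change, percentage points).
#' @export
#' @examples
#' classifyPattern(c(10, 10, 10, 60, 60, 60))   # discrete increase
#' classifyPattern(c(10, 20, 30, 40, 50, 60))   # continuous increase
#' classifyPattern(c(10, 40, 20, 50, 30, 60))   # other
classifyPattern <- function(trajectory, min_total_change = 5) {
  if (is.null(names(trajectory))) {
    names(trajectory) <- sprintf("t%d", seq_along(trajectory))
  }
  obs <- trajectory[!is.na(trajectory)]
  out <- list(pattern = "unclassifiable", direction = NA_character_,
              dominant_interval = NA_character_, total_change = NA_real_)
  if (length(obs) < 3L) return(out)
  d <- diff(obs)
  labels <- intervalLabels(names(obs))
  total <- sum(d)
  out$total_change <- total
  if (abs(total) <= min_total_change) {
    out$pattern <- "unchanged"
    return(out)
  }
  s <- sign(total)
  out$direction <- if (s > 0) "increase" else "decrease"
  tv <- sum(abs(d))
  directed <- d * s
  if (max(directed) >= 0.5 * tv) {
    out$pattern <- "discrete"
    out$dominant_interval <- labels[which.max(directed)]
  } else if (all(directed >= 0)) {
    out$pattern <- "continuous"
  } else {
    out$pattern <- "other"
  }
  out
}

#' Classify all trajectories of a matrix
#'
#' @param means Sites x ages matrix from [trajectoryMeans()].
#' @param min_total_change Passed to [classifyPattern()].
#'
#' @return A data.frame with one row per site: `site`, `pattern`,
#'   `direction`, `dominant_interval`, `total_change`.
#' @export
classifyPatterns <- function(means, min_total_change = 5) {
  stopifnot(is.matrix(means))
  rows <- lapply(seq_len(nrow(means)), function(i) {
    cl <- classifyPattern(means[i, ], min_total_change)
    data.frame(site = rownames(means)[i], pattern = cl$pattern,
               direction = cl$direction,
               dominant_interval = cl$dominant_interval,
               total_change = cl$total_change,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
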