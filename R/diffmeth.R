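#' Differential-methylation test configuration
#'
#' Significance requires both a minimum absolute methylation difference and
#' an FDR bound: a site is significant when `|delta| > min_delta` (strictly,
#' in percentage points) and `q <= max_fdr`. Significant sites are binned by
#' magnitude into moderate (`5-30`) and major (`>=30`, i.e.
#' `|delta| > major_delta`) changes.
#'
#' @param min_delta Minimum absolute difference in percentage points.
#' @param major_delta Bin boundary for major changes (percentage points).
#' @param max_fdr FDR bound.
#' @param fdr_method `"bh"` (Benjamini-Hochberg, default) or `"storey"`.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#'
#' @return A list of class `TestConfig`.
#' @export
testConfig <- function(min_delta = 5, major_delta = 30, max_fdr = 0.1,
                       fdr_method = c("bh", "storey"), var_equal = TRUE) {
  stopifnot(min_delta > 0, min_delta <= major_delta, major_delta <= 100,
            max_fdr > 0, max_fdr < 1)
  fdr_method <- match.arg(fdr_method)
  assertFlag(var_equal, "'var_equal'")
  structure(list(min_delta = min_delta, major_delta = major_delta,
                 max_fdr = max_fdr, fdr_method = fdr_method,
                 var_equal = var_equal),
            class = "TestConfig")
}

# Vectorised two-sample t-test over matrix rows. NA cells are missing
# observations. Returns NA p for rows with < 2 observations in either group.
rowTTest <- function(a, b, var_equal = TRUE) {
  na <- rowSums(!is.na(a))
  nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE)
  mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1L, stats::var, na.rm = TRUE)
  vb <- apply(b, 1L, stats::var, na.rm = TRUE)
  testable <- na >= 2L & nb >= 2L
  p <- rep(NA_real_, nrow(a))
  tt <- rep(NA_real_, nrow(a))
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  idx <- which(testable)
  d <- mb[idx] - ma[idx]
  s <- se[idx]
  ti <- d / s
  pi <- 2 * stats::pt(-abs(ti), df[idx])
  # degenerate variance: equal means => t = 0, p = 1; unequal => p -> 0
  zero <- s == 0
  ti[zero & d == 0] <- 0
  pi[zero & d == 0] <- 1
  ti[zero & d != 0] <- sign(d[zero & d != 0]) * Inf
  pi[zero & d != 0] <- 0
  p[idx] <- pi
  tt[idx] <- ti
  list(p = p, t = tt, mean_a = ma, mean_b = mb, n_a = na, n_b = nb,
       testable = testable)
}

#' Two-group Student's t-test for one CpG
#'
#' Two-sided pooled-variance Student's t-test (Welch with
#' `var_equal = FALSE`) on per-sample methylation percentages. Groups with
#' fewer than two values are untestable and return `NA`. Zero variance in
#' both groups gives p = 1 at equal means and p = 0 otherwise.
#'
#' @param values_a,values_b Numeric vectors of methylation percentages
#'   (NA = missing).
#' @param var_equal Pooled-variance (default) or Welch.
#'
#' @return The two-sided p-value, or `NA` if untestable.
#' @export
#' @examples
#' cpgTTest(c(10, 12, 11, 13), c(30, 31, 29, 32))
cpgTTest <- function(values_a, values_b, var_equal = TRUE) {
  r <- rowTTest(matrix(values_a, nrow = 1L), matrix(values_b, nrow = 1L),
                var_equal = var_equal)
  r$p[1L]
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default; Storey's q-values optionally,
#' with the pi0 estimate from the usual lambda grid (0.05 to 0.95 in steps
#' of 0.05) and a cubic smoothing spline. `NA` p-values propagate as `NA`
#' and are excluded from the ranking and from the test count.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param method `"bh"` or `"storey"`.
#' @param lambda Lambda grid for the Storey pi0 estimate.
#'
#' @return Vector of q-values, same length as `p`.
#' @export
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
fdrAdjust <- function(p, method = c("bh", "storey"),
                      lambda = seq(0.05, 0.95, 0.05)) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  if (method == "bh") {
    q[ok] <- stats::p.adjust(pv, method = "BH", n = m)
  } else {
    pi0 <- storeyPi0(pv, lambda)
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    qv <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))
    q[ok] <- qv[ro]
  }
  q
}

storeyPi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (length(lambda) >= 4L && stats::var(pi0_l) > 0) {
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  } else {
    pi0 <- min(pi0_l)
  }
  min(max(pi0, 1 / m), 1)
}

#' Call differential methylation between two age groups
#'
#' Per-CpG two-sided Student's t-test on methylation percentages between two
#' sample groups, FDR adjustment over testable sites, and the combined
#' significance rule `|delta| > min_delta` and `q <= max_fdr`. Deltas are
#' `mean_b - mean_a` in percentage points; group means use unmasked cells
#' only, and a site is testable only when both groups retain at least two
#' observations.
#'
#' @param x A QC'd [MethylationExperiment-class].
#' @param group_a,group_b Age-group labels (levels of `ageGroups(x)`).
#' @param config A [testConfig()].
#'
#' @return A data.frame of per-site calls: `site`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `delta`, `p_value`, `q_value`, `testable`, `significant`,
#'   `magnitude_bin` (`none`, `5-30`, `>=30`), `direction`.
#' @export
callDifferential <- function(x, group_a, group_b, config = testConfig()) {
  stopifnot(is(x, "MethylationExperiment"), inherits(config, "TestConfig"))
  ag <- as.character(ageGroups(x))
  if (!group_a %in% ag) stop("group '", group_a, "' absent from the samples")
  if (!group_b %in% ag) stop("group '", group_b, "' absent from the samples")
  pct <- methFraction(x, percent = TRUE)
  a <- pct[, ag == group_a, drop = FALSE]
  b <- pct[, ag == group_b, drop = FALSE]
  r <- rowTTest(a, b, var_equal = config$var_equal)
  q <- fdrAdjust(r$p, method = config$fdr_method)
  delta <- r$mean_b - r$mean_a
  delta[!r$testable] <- NA_real_
  sig <- r$testable & abs(delta) > config$min_delta & q <= config$max_fdr
  sig[is.na(sig)] <- FALSE
  bin <- rep("none", nrow(x))
  bin[sig] <- ifelse(abs(delta[sig]) > config$major_delta, ">=30", "5-30")
  direction <- rep(NA_character_, nrow(x))
  nz <- r$testable & !is.na(delta) & delta != 0
  direction[nz] <- ifelse(delta[nz] > 0, "increase", "decrease")
  data.frame(site = rownames(x),
             n_a = r$n_a, n_b = r$n_b,
             mean_a = r$mean_a, mean_b = r$mean_b,
             delta = delta, p_value = r$p, q_value = q,
             testable = r$testable, significant = sig,
             magnitude_bin = bin, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of significant calls that gain methylation
#'
#' @param calls Result of [callDifferential()].
#'
#' @return Fraction in `[0, 1]` of significant sites with direction
#'   `increase`, or `NA` (with a message) when there is no significant call.
#' @export
directionSummary <- function(calls) {
  sig <- calls[calls$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    message("no significant calls; direction summary undefined")
    return(NA_real_)
  }
  mean(sig$direction == "increase")
}

#' Cross-dataset concordance of significant calls
#'
#' Restricted to sites shared by the two call sets, the fraction of
#' secondary-significant sites that are also significant in the primary
#' calls.
#'
#' @param calls_primary,calls_secondary Results of [callDifferential()].
#'
#' @return A list with `concordance` (NA when the secondary set has no
#'   significant shared site), `n_shared`, `n_secondary_significant`.
#' @export
concordance <- function(calls_primary, calls_secondary) {
  shared <- intersect(calls_primary$site, calls_secondary$site)
  if (length(shared) == 0L) stop("the call sets share no sites")
  prim_sig <- calls_primary$site[calls_primary$significant]
  sec_sig <- intersect(calls_secondary$site[calls_secondary$significant],
                       shared)
  if (length(sec_sig) == 0L) {
    message("no secondary-significant shared sites; concordance undefined")
    return(list(concordance = NA_real_, n_shared = length(shared),
                n_secondary_significant = 0L))
  }
  list(concordance = mean(sec_sig %in% prim_sig),
       n_shared = length(shared),
       n_secondary_significant = length(sec_sig))
}
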