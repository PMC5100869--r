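# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. seed = NULL leaves the stream untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

siteId <- function(chrom, pos) paste(chrom, pos, sep = ":")

# sample() treats a length-1 numeric x as 1:x; this never does.
sampleExactly <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

assertProportion <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

assertFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}

#' Default developmental age groups
#'
#' The ordered postnatal liver sampling ages used throughout the package:
#' embryonic day 18.5, postnatal days 1-20, and 9 weeks (adult).
#'
#' @return Character vector of age-group labels in developmental order.
#' @export
#' @examples
#' defaultAgeGroups()
defaultAgeGroups <- function() {
  c("E18.5", "P1", "P5", "P10", "P15", "P20", "9wk")
}

# Coerce an age-group vector to an ordered factor. Known default labels are
# ordered developmentally; unknown label sets keep first-appearance order.
orderedAges <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  lev <- unique(x)
  def <- defaultAgeGroups()
  if (all(lev %in% def)) lev <- def[def %in% lev]
  factor(x, levels = lev, ordered = TRUE)
}

intervalLabels <- function(ages) {
  k <- length(ages)
  paste(ages[-k], ages[-1L], sep = "->")
}
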