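# Fixture builders and independent oracles shared across the test files.
# All fixtures are constructed in code; nothing is read from disk.

# Small MethylationExperiment from count matrices. `ages` is recycled over
# the columns.
makeME <- function(meth, total, ages, chrom = "chr1", pos = NULL,
                   cohort = "discovery") {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (is.null(pos)) pos <- seq_len(nrow(meth)) * 100L
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  ages <- rep_len(ages, ncol(meth))
  sd <- data.frame(
    sample_id = sprintf("%s_r%d", ages, stats::ave(seq_along(ages), ages,
                                                   FUN = seq_along)),
    age_group = ages, tissue = "liver", cohort = cohort,
    stringsAsFactors = FALSE)
  MethylationExperiment(meth, total, sites, sd)
}

# ME whose methylation percentages approximate `pct` (sites x samples) at a
# fixed high coverage, so group means land close to the requested values.
makePctME <- function(pct, ages, coverage = 1000L) {
  pct <- as.matrix(pct)
  meth <- round(pct / 100 * coverage)
  total <- matrix(coverage, nrow(pct), ncol(pct))
  storage.mode(meth) <- "integer"
  storage.mode(total) <- "integer"
  makeME(meth, total, ages)
}

toyGenome <- function(seq, name = "toy") {
  new("SyntheticGenome", name = name,
      sequence = Biostrings::DNAString(seq))
}

# Brute-force oracles --------------------------------------------------------

# MspI digest by direct string scan: cut after the first C of every CCGG.
oracleDigest <- function(seq) {
  n <- nchar(seq)
  cuts <- integer()
  for (i in seq_len(max(0L, n - 3L))) {
    if (substr(seq, i, i + 3L) == "CCGG") cuts <- c(cuts, i)
  }
  bounds <- sort(unique(c(0L, cuts, n)))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# Benjamini-Hochberg step-up from first principles.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Nearest-interval distance by exhaustive scan (1-based closed intervals;
# gap semantics: the number of bases strictly between site and interval).
oracleDistance <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(NA_real_)
  d <- ifelse(pos >= starts & pos <= ends, 0,
              ifelse(pos < starts, starts - pos - 1, pos - ends - 1))
  min(d)
}
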