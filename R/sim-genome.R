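#' Generate a synthetic reference contig
#'
#' Draws an i.i.d. base sequence at a target GC content and optionally plants
#' additional MspI recognition motifs (CCGG) so that a downstream in-silico
#' digest yields enough size-selectable fragments. At the default GC of 0.42
#' a CCGG occurs roughly every 500 bp already, giving at least one 150-600 bp
#' fragment per 10 kb without boosting.
#'
#' @param length Contig length in bp (>= 1000).
#' @param gc_fraction Target GC proportion, strictly inside (0, 1).
#' @param ccgg_boost Rate multiplier for planted CCGG motifs; 1 plants none
#'   beyond the background expectation.
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @param name Contig name.
#'
#' @return A [SyntheticGenome-class].
#' @export
#' @examples
#' g <- generateGenome(10000, seed = 7)
#' length(g)
generateGenome <- function(length, gc_fraction = 0.42, ccgg_boost = 1,
                           seed = NULL, name = "chrS") {
  if (!is.numeric(length) || length(length) != 1L || length < 1000) {
    stop("'length' must be a single number >= 1000")
  }
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stop("'gc_fraction' must lie strictly inside (0, 1)")
  }
  if (!is.numeric(ccgg_boost) || ccgg_boost < 0) {
    stop("'ccgg_boost' must be non-negative")
  }
  length <- as.integer(length)
  bases <- withSeed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    b <- sample(names(p), length, replace = TRUE, prob = p)
    if (ccgg_boost > 1 && length >= 8L) {
      n_extra <- stats::rpois(1L, (ccgg_boost - 1) * length / 500)
      if (n_extra > 0) {
        at <- sampleExactly(seq_len(length - 3L), min(n_extra, length - 3L))
        for (s in at) b[s:(s + 3L)] <- c("C", "C", "G", "G")
      }
    }
    b
  })
  new("SyntheticGenome", name = name,
      sequence = Biostrings::DNAString(paste(bases, collapse = "")))
}

#' In-silico MspI digestion
#'
#' Cuts the contig at every CCGG motif using the enzyme's C^CGG convention
#' (cleavage after the first C). The returned fragments tile the contig
#' without gaps or overlaps; concatenating their sequences reproduces the
#' genome exactly.
#'
#' @param genome A [SyntheticGenome-class].
#'
#' @return A data.frame with columns `start` (0-based), `end` (exclusive) and
#'   `length`, ordered along the contig.
#' @export
#' @examples
#' g <- new("SyntheticGenome", name = "toy",
#'          sequence = Biostrings::DNAString("AAACCGGAAA"))
#' mspiDigest(g)  # fragments [0,4) and [4,10)
mspiDigest <- function(genome) {
  stopifnot(is(genome, "SyntheticGenome"))
  len <- length(genome)
  hits <- Biostrings::matchPattern("CCGG", genomeSequence(genome))
  # cut after the first C: 0-based boundary equals the 1-based motif start
  cuts <- BiocGenerics::start(hits)
  bounds <- unique(c(0L, cuts[cuts > 0L & cuts < len], len))
  bounds <- sort(bounds)
  n <- length(bounds) - 1L
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
             length = diff(bounds))
}

#' Size-select digest fragments
#'
#' Retains fragments whose length falls inside the gel-extraction window,
#' bounds inclusive. The defaults mirror a standard RRBS 150-600 bp cut.
#'
#' @param fragments Fragment data.frame from [mspiDigest()].
#' @param min_len,max_len Inclusive length bounds in bp.
#'
#' @return The retained subset of `fragments`, input order preserved.
#' @export
sizeSelect <- function(fragments, min_len = 150, max_len = 600) {
  stopifnot(is.data.frame(fragments), all(c("start", "end") %in% colnames(fragments)))
  if (min_len > max_len) stop("'min_len' must not exceed 'max_len'")
  len <- fragments$end - fragments$start
  fragments[len >= min_len & len <= max_len, , drop = FALSE]
}

# 1-based positions of the plus-strand C of every CpG dinucleotide.
cpgPositions <- function(genome) {
  BiocGenerics::start(Biostrings::matchPattern("CG", genomeSequence(genome)))
}

# 1-based positions of CpH cytosines (C not followed by G; last base excluded).
cphPositions <- function(genome) {
  cs <- BiocGenerics::start(Biostrings::matchPattern("C", genomeSequence(genome)))
  cs <- cs[cs < length(genome)]
  cg <- cpgPositions(genome)
  setdiff(cs, cg)
}

#' Enumerate RRBS-assayable CpGs
#'
#' Single-end sequencing reads start at either end of each size-selected
#' fragment, so a CpG is assayable when its plus-strand C lies within
#' `read_length` bp of a fragment end. Both strands are collapsed to one
#' record anchored at the plus-strand C.
#'
#' @param genome A [SyntheticGenome-class].
#' @param fragments Size-selected fragment data.frame (0-based half-open).
#' @param read_length Read length in bp.
#'
#' @return A [GenomicRanges::GRanges] of width-1 CpG sites, sorted, unique,
#'   with a `context = "CpG"` metadata column.
#' @export
enumerateAssayedCpGs <- function(genome, fragments, read_length = 50) {
  stopifnot(is(genome, "SyntheticGenome"), is.data.frame(fragments))
  cg <- cpgPositions(genome)
  keep <- logical(length(cg))
  if (nrow(fragments) && length(cg)) {
    for (i in seq_len(nrow(fragments))) {
      s <- fragments$start[i]
      e <- fragments$end[i]
      inside <- cg > s & cg <= e
      offset_start <- cg - (s + 1L)     # 0-based distance from fragment start
      offset_end <- e - cg              # bases from C to fragment end
      keep <- keep |
        (inside & (offset_start < read_length | offset_end < read_length))
    }
  }
  pos <- sort(unique(cg[keep]))
  gr <- GenomicRanges::GRanges(
    rep(names(genome), length(pos)),
    IRanges::IRanges(pos, width = 1L),
    seqinfo = GenomeInfoDb::Seqinfo(names(genome), length(genome)))
  S4Vectors::mcols(gr)$context <- rep("CpG", length(gr))
  gr
}
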