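#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom Biostrings DNAString
NULL

#' MethylationExperiment: per-CpG bisulfite counts across samples
#'
#' An S4 container for site-by-sample bisulfite sequencing counts, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Three assays are
#' mandatory:
#' \describe{
#'   \item{`meth`}{integer counts of methylated read calls,}
#'   \item{`total`}{integer counts of total read calls (methylated +
#'     unmethylated),}
#'   \item{`mask`}{logical; `TRUE` marks a (site, sample) cell as missing
#'     (no data, or masked by a coverage filter). Counts are preserved under
#'     masking so that filters are reversible and idempotent.}
#' }
#' Row ranges hold the CpG sites (width-1 ranges anchored at the plus-strand
#' C, 1-based) with a `context` metadata column (`"CpG"` or `"CpH"`); column
#' data holds the sample sheet (`sample_id`, ordered `age_group`, `tissue`,
#' `cohort`).
#'
#' @name MethylationExperiment-class
#' @aliases MethylationExperiment-class
#' @exportClass MethylationExperiment
setClass("MethylationExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("meth", "total", "mask")
  if (!all(need %in% an)) {
    return(paste("assays must include", paste(need, collapse = ", ")))
  }
  m <- SummarizedExperiment::assay(object, "meth")
  tt <- SummarizedExperiment::assay(object, "total")
  mk <- SummarizedExperiment::assay(object, "mask")
  if (!is.logical(mk)) msg <- c(msg, "'mask' assay must be logical")
  if (any(m < 0, na.rm = TRUE) || any(tt < 0, na.rm = TRUE)) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (any(m > tt, na.rm = TRUE)) {
    msg <- c(msg, "methylated count exceeds total count")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "age_group") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'sample_id' and 'age_group'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param meth,total Integer matrices (sites x samples) of methylated and
#'   total read counts.
#' @param sites A [GenomicRanges::GRanges] of length `nrow(meth)` giving the
#'   CpG positions (width 1, plus-strand C). A `context` metadata column is
#'   added (default `"CpG"`) if absent.
#' @param sampleData A data.frame with one row per sample; must contain
#'   `sample_id` and `age_group` (coerced to an ordered factor); `tissue` and
#'   `cohort` are filled with defaults if absent.
#' @param mask Optional logical matrix of missing cells; defaults to
#'   `total == 0`.
#'
#' @return A [MethylationExperiment-class] object.
#' @export
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 50), width = 1))
#' meth <- matrix(c(3L, 8L, 0L, 12L), nrow = 2)
#' total <- matrix(c(10L, 10L, 15L, 15L), nrow = 2)
#' sd <- data.frame(sample_id = c("s1", "s2"), age_group = c("E18.5", "9wk"))
#' MethylationExperiment(meth, total, sites, sd)
MethylationExperiment <- function(meth, total, sites, sampleData, mask = NULL) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (!identical(dim(meth), dim(total))) {
    stop("'meth' and 'total' must have identical dimensions")
  }
  if (length(sites) != nrow(meth)) {
    stop("length(sites) must equal nrow(meth)")
  }
  sampleData <- as.data.frame(sampleData)
  if (nrow(sampleData) != ncol(meth)) {
    stop("nrow(sampleData) must equal ncol(meth)")
  }
  if (is.null(sampleData$sample_id)) {
    stop("sampleData must contain a 'sample_id' column")
  }
  if (is.null(sampleData$age_group)) {
    stop("sampleData must contain an 'age_group' column")
  }
  if (anyDuplicated(sampleData$sample_id)) {
    stop("duplicate sample_id in sampleData")
  }
  sampleData$age_group <- orderedAges(sampleData$age_group)
  if (is.null(sampleData$tissue)) sampleData$tissue <- "liver"
  if (is.null(sampleData$cohort)) sampleData$cohort <- "discovery"
  if (is.null(S4Vectors::mcols(sites)$context)) {
    S4Vectors::mcols(sites)$context <- "CpG"
  }
  if (is.null(mask)) mask <- total == 0L
  mask <- as.matrix(mask)
  ids <- siteId(as.character(GenomeInfoDb::seqnames(sites)),
                GenomicRanges::start(sites))
  dn <- list(ids, sampleData$sample_id)
  dimnames(meth) <- dn
  dimnames(total) <- dn
  dimnames(mask) <- dn
  names(sites) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total, mask = mask),
    rowRanges = sites,
    colData = S4Vectors::DataFrame(sampleData, row.names = sampleData$sample_id)
  )
  new("MethylationExperiment", se)
}

#' SyntheticGenome: a simulated reference contig
#'
#' A single named DNA contig used by the in-silico RRBS machinery. Purely a
#' stand-in for a real reference assembly so digestion, CpG enumeration and
#' window statistics are exercisable without any external download.
#'
#' @slot name Contig name (e.g. `"chrS"`).
#' @slot sequence A [Biostrings::DNAString] over the unambiguous alphabet
#'   A/C/G/T.
#'
#' @name SyntheticGenome-class
#' @aliases SyntheticGenome-class
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
         representation(name = "character", sequence = "DNAString"))

setValidity("SyntheticGenome", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name)) {
    msg <- c(msg, "name must be a single non-empty string")
  }
  if (length(object@sequence) < 1L) {
    msg <- c(msg, "sequence must be non-empty")
  }
  af <- Biostrings::alphabetFrequency(object@sequence, baseOnly = TRUE)
  if (af[["other"]] > 0) {
    msg <- c(msg, "sequence must contain only A/C/G/T")
  }
  if (length(msg)) msg else TRUE
})
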