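#' Accessors for MethylationExperiment and SyntheticGenome objects
#'
#' @description
#' `methCounts()`, `totalCounts()` and `covMask()` return the three assay
#' matrices. `methFraction()` returns the per-cell methylation fraction
#' `meth/total` (or percentage with `percent = TRUE`) with `NA` at masked or
#' zero-coverage cells — all statistics in this package are computed on
#' unmasked cells only. `ageGroups()` returns the per-sample ordered age
#' factor. `qcLog()` returns the accumulated removal log written by the QC
#' filters (a data.frame with columns `step`, `entity`, `id`, `reason`).
#'
#' @param x A [MethylationExperiment-class] (or [SyntheticGenome-class] for
#'   `genomeSequence`).
#' @param percent Logical; return percentages (0-100) instead of fractions.
#' @param value Replacement logical mask matrix.
#'
#' @return Matrices, an ordered factor, or a data.frame as described above.
#' @name MethylationExperiment-accessors
#' @examples
#' sim <- simulateRRBS(n_sites = 20, ages = c("E18.5", "9wk"),
#'                     n_replicates = 2, seed = 1)
#' me <- sim$experiment
#' dim(methCounts(me))
#' head(methFraction(me, percent = TRUE))
#' ageGroups(me)
NULL

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("methCounts", "MethylationExperiment", function(x) {
  SummarizedExperiment::assay(x, "meth")
})

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("totalCounts", "MethylationExperiment", function(x) {
  SummarizedExperiment::assay(x, "total")
})

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("covMask", "MethylationExperiment", function(x) {
  SummarizedExperiment::assay(x, "mask")
})

#' @rdname MethylationExperiment-accessors
#' @export
setReplaceMethod("covMask", "MethylationExperiment", function(x, value) {
  SummarizedExperiment::assay(x, "mask") <- value
  validObject(x)
  x
})

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("methFraction", "MethylationExperiment",
          function(x, percent = FALSE) {
  m <- methCounts(x)
  tt <- totalCounts(x)
  f <- m / tt
  f[covMask(x) | tt == 0] <- NA_real_
  if (percent) f <- 100 * f
  f
})

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("ageGroups", "MethylationExperiment", function(x) {
  ag <- SummarizedExperiment::colData(x)$age_group
  if (!is.factor(ag)) ag <- orderedAges(ag)
  ag
})

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("qcLog", "MethylationExperiment", function(x) {
  lg <- S4Vectors::metadata(x)$qc_log
  if (is.null(lg)) {
    lg <- data.frame(step = character(), entity = character(),
                     id = character(), reason = character())
  }
  lg
})

appendQcLog <- function(x, step, entity, id, reason) {
  if (length(id) == 0L) return(x)
  lg <- rbind(qcLog(x),
              data.frame(step = step, entity = entity, id = id,
                         reason = reason, stringsAsFactors = FALSE))
  S4Vectors::metadata(x)$qc_log <- lg
  x
}

setMethod("show", "MethylationExperiment", function(object) {
  cat("MethylationExperiment with", nrow(object), "sites and",
      ncol(object), "samples\n")
  ctx <- table(S4Vectors::mcols(SummarizedExperiment::rowRanges(object))$context)
  cat("  contexts:", paste(names(ctx), ctx, sep = "=", collapse = ", "), "\n")
  ag <- ageGroups(object)
  cat("  age groups:", paste(levels(ag), collapse = " < "), "\n")
  cat("  masked cells:", sum(covMask(object)), "of", length(covMask(object)),
      "\n")
  lg <- qcLog(object)
  if (nrow(lg)) cat("  qc log:", nrow(lg), "removal records\n")
  invisible(NULL)
})

#' @rdname SyntheticGenome-accessors
#' @name SyntheticGenome-accessors
#' @param x A [SyntheticGenome-class].
#' @return `genomeSequence()` returns the [Biostrings::DNAString];
#'   `length()` the contig length in bp; `names()` the contig name.
#' @export
setMethod("genomeSequence", "SyntheticGenome", function(x) x@sequence)

#' @rdname SyntheticGenome-accessors
#' @export
setMethod("length", "SyntheticGenome", function(x) length(x@sequence))

#' @rdname SyntheticGenome-accessors
#' @export
setMethod("names", "SyntheticGenome", function(x) x@name)

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome", object@name, "of", length(object@sequence), "bp\n")
  gc <- sum(Biostrings::alphabetFrequency(object@sequence)[c("C", "G")])
  cat("  GC content:", round(gc / length(object@sequence), 3), "\n")
  invisible(NULL)
})
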