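#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("methCounts", function(x) standardGeneric("methCounts"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("covMask", function(x) standardGeneric("covMask"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("covMask<-", function(x, value) standardGeneric("covMask<-"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("methFraction", function(x, percent = FALSE)
  standardGeneric("methFraction"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("ageGroups", function(x) standardGeneric("ageGroups"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))

#' @rdname SyntheticGenome-accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
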