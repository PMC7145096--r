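#' @include AllClasses.R
NULL

#' Run the four-stage TER candidate funnel
#'
#' Applies, in order, the mean-TPM expression filter, the known-gene overlap
#' discard, the template-domain screen and the cross-species conservation
#' filter, and returns a [FunnelReport-class] with per-stage accounting and
#' the final candidates ranked by descending mean TPM.
#'
#' @param x Feature-by-experiment counts matrix (non-negative integers with
#'   feature rownames), or a [SyntheticDataset-class].
#' @param ... Passed to methods.
#' @return A [FunnelReport-class].
#' @export
setGeneric("runFunnel", function(x, ...) standardGeneric("runFunnel"))

#' @rdname stageCounts
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname stageCounts
#' @export
setGeneric("survivors", function(x, stage) standardGeneric("survivors"))

#' @rdname stageCounts
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))

#' @rdname profileMatrix
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname profileMatrix
#' @export
setGeneric("baselineOligo", function(x) standardGeneric("baselineOligo"))

#' @rdname orthologMatrix-accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname orthologMatrix-accessors
#' @export
setGeneric("querySpecies", function(x) standardGeneric("querySpecies"))

#' @rdname orthologMatrix-accessors
#' @export
setGeneric("relativeCounts", function(x, ...) standardGeneric("relativeCounts"))

#' @rdname syntheticDataset-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname syntheticDataset-accessors
#' @export
setGeneric("candidateSequences", function(x) standardGeneric("candidateSequences"))

#' @rdname syntheticDataset-accessors
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))
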