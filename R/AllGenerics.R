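#' Species label of each sample
#'
#' @param x a \linkS4class{MotuExperiment}.
#' @return factor of species labels, one per sample.
#' @export
setGeneric("sampleSpecies", function(x) standardGeneric("sampleSpecies"))

#' @rdname sampleSpecies
#' @export
setMethod("sampleSpecies", "MotuExperiment", function(x)
    SummarizedExperiment::colData(x)$species)

#' Read-count matrix (MOTUs x samples)
#'
#' @param x a \linkS4class{MotuExperiment}.
#' @return numeric matrix of counts.
#' @export
setGeneric("motuCounts", function(x) standardGeneric("motuCounts"))

#' @rdname motuCounts
#' @export
setMethod("motuCounts", "MotuExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' Quality-filter a MOTU count table
#'
#' @param x a \linkS4class{MotuExperiment}.
#' @param ... filter thresholds, see the method.
#' @return a filtered \linkS4class{MotuExperiment}.
#' @export
setGeneric("filterCounts", function(x, ...) standardGeneric("filterCounts"))
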