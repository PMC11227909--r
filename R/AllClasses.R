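#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assays assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats density dnorm pnorm pt rbinom rmultinom rnorm rpois
#'   runif sd setNames t.test integrate p.adjust rgamma
#' @importFrom utils combn read.csv read.delim write.csv write.table head
NULL

#' MotuExperiment: a MOTU read-count table with per-sample species labels
#'
#' Container for a post-clustering metabarcoding count table. MOTUs
#' (molecular operational taxonomic units) are rows, samples are columns,
#' following the usual feature-by-sample orientation of
#' \linkS4class{SummarizedExperiment}, which this class extends. The
#' \code{counts} assay holds non-negative integer read counts; the column
#' data must contain a \code{species} factor giving the bird species each
#' fecal sample came from. MOTU-level taxonomy (assigned rank and name,
#' best database similarity) lives in \code{rowData}.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#'
#' @seealso [MotuExperiment()] for the constructor, [filterCounts()] for
#'   quality filtering, [rra()] and [foo()] for diet composition metrics.
#' @export
setClass("MotuExperiment", contains = "SummarizedExperiment")

setValidity("MotuExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
        if (any(cts != round(cts)))
            msg <- c(msg, "counts must be integers")
    }
    if (!"species" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'species' column")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a MotuExperiment
#'
#' @param counts integer matrix of read counts. Either MOTUs x samples
#'   (default) or samples x MOTUs with \code{samplesAsRows = TRUE}, the
#'   layout of a typical \code{motus.tsv} export.
#' @param species character or factor of species labels, one per sample.
#' @param taxonomy optional data.frame of per-MOTU taxonomy (rownames or a
#'   \code{motu_id} column matching the MOTU ids) stored in \code{rowData}.
#' @param samplesAsRows logical; set \code{TRUE} when \code{counts} is
#'   samples x MOTUs.
#'
#' @return A \linkS4class{MotuExperiment}.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("motu", 1:3), paste0("s", 1:4)))
#' me <- MotuExperiment(m, species = c("A", "A", "B", "B"))
#' sampleSpecies(me)
#' @export
MotuExperiment <- function(counts, species, taxonomy = NULL,
                           samplesAsRows = FALSE) {
    counts <- as.matrix(counts)
    if (samplesAsRows) counts <- t(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("motu", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    if (length(species) != ncol(counts))
        stop("'species' must have one label per sample (", ncol(counts),
             " samples, ", length(species), " labels)")
    storage.mode(counts) <- "double"
    cd <- S4Vectors::DataFrame(species = factor(species),
                               row.names = colnames(counts))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy)) {
        taxonomy <- as.data.frame(taxonomy)
        key <- if ("motu_id" %in% names(taxonomy)) taxonomy$motu_id else
            rownames(taxonomy)
        idx <- match(rownames(counts), key)
        if (anyNA(idx))
            stop("taxonomy is missing MOTUs: ",
                 paste(head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
        rd <- S4Vectors::DataFrame(
            taxonomy[idx, setdiff(names(taxonomy), "motu_id"), drop = FALSE],
            row.names = rownames(counts))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    new("MotuExperiment", se)
}

#' Breeding period of one species on the 1-April Julian scale
#'
#' @slot species species label.
#' @slot startJulian first day of the period (earliest first-egg date).
#' @slot endJulian last day (latest hatching date).
#' @slot lengthDays inclusive span, \code{endJulian - startJulian + 1}.
#' @export
setClass("BreedingPeriod",
    representation(species = "character", startJulian = "integer",
                   endJulian = "integer", lengthDays = "integer"))

setValidity("BreedingPeriod", function(object) {
    if (object@endJulian < object@startJulian)
        return("end day precedes start day")
    if (object@lengthDays != object@endJulian - object@startJulian + 1L)
        return("lengthDays must equal endJulian - startJulian + 1")
    TRUE
})

#' Result of a per-variable niche overlap permutation test
#'
#' @slot variable variable name.
#' @slot kind \code{"continuous"} or \code{"categorical"}.
#' @slot observed observed overlap index in [0, 1].
#' @slot nullMean,nullSd mean and sd of the permutation null distribution.
#' @slot pRaw one-sided empirical permutation p for observed overlap
#'   smaller than the null.
#' @slot pParametric t-distribution tail probability of the observed value
#'   within the null sample (parametric diagnostic).
#' @slot pAdjusted sequential-Bonferroni adjusted p (NA until adjustment).
#' @slot nPerm number of label permutations.
#' @export
setClass("OverlapResult",
    representation(variable = "character", kind = "character",
                   observed = "numeric", nullMean = "numeric",
                   nullSd = "numeric", pRaw = "numeric",
                   pParametric = "numeric", pAdjusted = "numeric",
                   nPerm = "integer"))

setValidity("OverlapResult", function(object) {
    msg <- character()
    if (object@observed < -1e-9 || object@observed > 1 + 1e-9)
        msg <- c(msg, "observed overlap must lie in [0, 1]")
    for (p in c(object@pRaw, object@pParametric))
        if (!is.na(p) && (p < 0 || p > 1))
            msg <- c(msg, "p values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MotuExperiment", function(object) {
    cts <- SummarizedExperiment::assay(object, "counts")
    cat("MotuExperiment:", nrow(object), "MOTUs x", ncol(object),
        "samples\n")
    cat("species:",
        paste(sprintf("%s (n=%d)", levels(sampleSpecies(object)),
                      table(sampleSpecies(object))), collapse = ", "), "\n")
    cat("total reads:", format(sum(cts), big.mark = ","), "\n")
    if (ncol(SummarizedExperiment::rowData(object)))
        cat("rowData:",
            paste(colnames(SummarizedExperiment::rowData(object)),
                  collapse = ", "), "\n")
})

setMethod("show", "BreedingPeriod", function(object) {
    cat(sprintf("BreedingPeriod '%s': day %d to day %d (%d days)\n",
                object@species, object@startJulian, object@endJulian,
                object@lengthDays))
})

setMethod("show", "OverlapResult", function(object) {
    cat(sprintf("OverlapResult '%s' (%s)\n", object@variable, object@kind))
    cat(sprintf("  observed overlap: %.3f\n", object@observed))
    cat(sprintf("  null: %.3f +/- %.3f (%d permutations)\n",
                object@nullMean, object@nullSd, object@nPerm))
    cat(sprintf("  p = %.4g (parametric %.4g, adjusted %s)\n", object@pRaw,
                object@pParametric,
                ifelse(is.na(object@pAdjusted), "NA",
                       sprintf("%.4g", object@pAdjusted))))
})
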