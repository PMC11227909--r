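#' Post-clustering quality filtering of a MOTU count table
#'
#' Applies the standard metabarcoding abundance filters to a post-clustering
#' MOTU table, in a fixed order:
#' \enumerate{
#'   \item per-sample relative-abundance filter: any entry contributing less
#'     than \code{minRelAbund} of its sample's total reads is set to zero
#'     (guards against tag-jumping and low-level cross-contamination);
#'   \item total-frequency filter: MOTUs whose total read count across all
#'     samples falls below \code{minTotal} are removed;
#'   \item prevalence filter: MOTUs detected (count > 0) in fewer than
#'     \code{minSamples} samples are removed.
#' }
#' The order matters (the relative-abundance step can push a MOTU below the
#' other two thresholds) and is applied as listed. Samples left with zero
#' reads are flagged in \code{colData(x)$flagged_empty} and kept, never
#' silently dropped. The operation is idempotent: filtering an
#' already-filtered table returns it unchanged.
#'
#' @param x a \linkS4class{MotuExperiment}.
#' @param minRelAbund minimum within-sample relative abundance (default
#'   0.001, i.e. 0.1\% of the sample's reads).
#' @param minTotal minimum total read count per MOTU (default 3).
#' @param minSamples minimum number of samples a MOTU must occur in
#'   (default 2).
#' @param verbose log the number of entries/MOTUs removed at each step.
#' @return the filtered \linkS4class{MotuExperiment}.
#' @examples
#' m <- rbind(motu1 = c(9, 60, 50), motu2 = c(2, 0, 0),
#'            motu3 = c(500, 400, 450))
#' colnames(m) <- paste0("s", 1:3)
#' me <- MotuExperiment(m, species = c("A", "A", "B"))
#' filterCounts(me, verbose = TRUE)
#' @rdname filterCounts
#' @export
setMethod("filterCounts", "MotuExperiment",
function(x, minRelAbund = 0.001, minTotal = 3, minSamples = 2,
         verbose = FALSE) {
    cts <- motuCounts(x)
    if (sum(cts) == 0) {
        warning("count table is all zero; nothing to filter")
        return(x)
    }
    totals <- colSums(cts)
    rel <- sweep(cts, 2, pmax(totals, 1), "/")
    low <- rel < minRelAbund & cts > 0
    cts[low] <- 0
    if (verbose)
        message(sum(low), " entries below the per-sample ",
                100 * minRelAbund, "% relative-abundance threshold zeroed")

    keepTotal <- rowSums(cts) >= minTotal
    keepPrev <- rowSums(cts > 0) >= minSamples
    if (verbose) {
        message(sum(!keepTotal), " MOTUs removed with total reads < ",
                minTotal)
        message(sum(keepTotal & !keepPrev),
                " further MOTUs removed as present in < ", minSamples,
                " samples")
    }
    keep <- keepTotal & keepPrev
    out <- x[keep, ]
    assays <- SummarizedExperiment::assays(out)
    assays[["counts"]] <- cts[keep, , drop = FALSE]
    SummarizedExperiment::assays(out) <- assays
    empty <- colSums(motuCounts(out)) == 0
    SummarizedExperiment::colData(out)$flagged_empty <- empty
    if (any(empty))
        warning(sum(empty), " sample(s) left with zero reads after ",
                "filtering: ", paste(colnames(out)[empty], collapse = ", "))
    validObject(out)
    out
})

#' Similarity-threshold taxonomy assignment for one MOTU
#'
#' Converts the database hits of a MOTU into a taxonomic assignment using
#' fixed percent-identity thresholds: species level at best similarity
#' >= 98, family level above 96.5 (and below 98), order level above 95 (and
#' at or below 96.5), otherwise unidentified. When several candidates tie
#' at the best similarity, the assignment is downgraded to the most
#' specific rank at which all tied candidates agree (species, then family,
#' then order), never exceeding the rank the similarity itself permits; if
#' the tied candidates do not even share an order, the MOTU is
#' unidentified.
#'
#' @param motu_id MOTU identifier.
#' @param candidates data.frame of database hits with columns
#'   \code{order}, \code{family}, \code{species} (lineage names; a
#'   \code{genus} column is accepted and ignored for ranking) and
#'   \code{similarity} (percent identity in [0, 100]).
#' @param thresholds named numeric vector with elements \code{species},
#'   \code{family}, \code{order}: the similarity cut-offs.
#' @return list with \code{motu_id}, \code{best_similarity},
#'   \code{assigned_rank} (one of \code{"species"}, \code{"family"},
#'   \code{"order"}, \code{"unidentified"}) and \code{assigned_name}.
#' @examples
#' hits <- data.frame(order = "Lepidoptera", family = "Noctuidae",
#'                    species = c("Noctua pronuba", "Noctua comes"),
#'                    similarity = c(98.6, 98.6))
#' assignTaxonomy("motu1", hits)  # tie -> downgraded to family
#' @export
assignTaxonomy <- function(motu_id, candidates,
                           thresholds = c(species = 98, family = 96.5,
                                          order = 95)) {
    candidates <- as.data.frame(candidates)
    if (nrow(candidates) == 0L)
        stop("no database candidates supplied for MOTU '", motu_id, "'")
    if (any(is.na(candidates$similarity)) ||
        any(candidates$similarity < 0 | candidates$similarity > 100))
        stop("candidate similarities must lie in [0, 100]")
    s <- max(candidates$similarity)
    simRank <- if (s >= thresholds[["species"]]) "species"
        else if (s > thresholds[["family"]]) "family"
        else if (s > thresholds[["order"]]) "order"
        else "unidentified"
    ranks <- c("species", "family", "order", "unidentified")
    best <- candidates[candidates$similarity == s, , drop = FALSE]
    agreeRank <- "unidentified"
    for (r in c("species", "family", "order")) {
        if (!r %in% names(best)) next
        vals <- unique(best[[r]])
        if (length(vals) == 1L && !is.na(vals)) { agreeRank <- r; break }
    }
    # final rank = coarser of what similarity permits and what ties allow
    rank <- ranks[max(match(simRank, ranks), match(agreeRank, ranks))]
    name <- if (rank == "unidentified") "unidentified" else
        as.character(unique(best[[rank]])[1L])
    list(motu_id = motu_id, best_similarity = s, assigned_rank = rank,
         assigned_name = name)
}

#' Assign taxonomy for every MOTU in a hit table
#'
#' @param hits data.frame of database hits with a \code{motu_id} column
#'   plus the columns described in [assignTaxonomy()].
#' @inheritParams assignTaxonomy
#' @return data.frame with one row per MOTU: \code{motu_id},
#'   \code{best_similarity}, \code{assigned_rank}, \code{assigned_name},
#'   and the \code{order} of the best hit (used for order-level diet
#'   aggregation; \code{NA} when unidentified).
#' @export
assignTaxonomyTable <- function(hits, thresholds = c(species = 98,
                                                     family = 96.5,
                                                     order = 95)) {
    hits <- as.data.frame(hits)
    stopifnot("motu_id" %in% names(hits))
    res <- lapply(split(hits, hits$motu_id), function(h) {
        a <- assignTaxonomy(h$motu_id[1L], h, thresholds)
        bestOrder <- h$order[which.max(h$similarity)]
        data.frame(motu_id = a$motu_id, best_similarity = a$best_similarity,
                   assigned_rank = a$assigned_rank,
                   assigned_name = a$assigned_name,
                   order = if (a$assigned_rank == "unidentified") NA_character_
                           else as.character(bestOrder))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out[match(unique(hits$motu_id), out$motu_id), , drop = FALSE]
}
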