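# Internal: one niche variable = paired observation vectors plus type info.
.makeVar <- function(name, a, b, kind = "continuous", bounds = NULL)
    list(name = name, a = a, b = b, kind = kind, bounds = bounds)

# Observed overlap and a joint permutation null for a set of variables that
# share sampling units (so one relabeling applies to all of them at once).
# Returns observed vector and an nPerm x nVar matrix of null overlaps.
.dimensionNull <- function(vars, nPerm, seed) {
    obs <- vapply(vars, function(v)
        .overlapFor(v$a, v$b, v$kind, bounds = v$bounds), numeric(1))
    names(obs) <- vapply(vars, `[[`, "", "name")
    nA <- length(vars[[1L]]$a)
    n <- nA + length(vars[[1L]]$b)
    null <- withSeed(seed, {
        t(vapply(seq_len(nPerm), function(i) {
            idx <- sample.int(n, nA)
            vapply(vars, function(v) {
                pooled <- c(v$a, v$b)
                .overlapFor(pooled[idx], pooled[-idx], v$kind,
                            bounds = v$bounds)
            }, numeric(1))
        }, numeric(length(vars))))
    })
    colnames(null) <- names(obs)
    list(observed = obs, null = null)
}

.pFromNull <- function(observed, null) {
    mu <- mean(null); sdev <- stats::sd(null)
    pEmp <- (1 + sum(null <= observed)) / (length(null) + 1)
    if (sdev == 0)
        return(c(p = pEmp, pParam = NA_real_, mu = mu, sd = sdev))
    tstat <- (mu - observed) / sdev
    c(p = pEmp,
      pParam = stats::pt(tstat, df = length(null) - 1, lower.tail = FALSE),
      mu = mu, sd = sdev)
}

#' Multi-dimensional niche overlap analysis for two species
#'
#' Runs the full per-variable / composite / overall niche-overlap analysis
#' on the three ecological dimensions: breeding time (first-egg,
#' incubation-start and hatching dates on the 1-April Julian scale), nest
#' site (mixed continuous and categorical variables) and diet (one
#' proportion-type variable per prey order: each sample's within-sample
#' read proportion of that order, compared with [proportionOverlap()]).
#'
#' For every variable the overlap index and a species-label permutation
#' null are computed (labels permuted jointly across the variables of a
#' dimension, since they share sampling units). Composite overlap per
#' dimension and the overall overlap are arithmetic means of the member
#' variables' observed values (with sample SD); their permutation nulls are
#' the corresponding means of the per-permutation member overlaps (the
#' overall null averages across dimensions permuted independently).
#' Holm's sequential Bonferroni is applied within each dimension's variable
#' family, and separately to the family of three composite tests plus the
#' overall test.
#'
#' @param breeding breeding-record data.frame (columns \code{species},
#'   \code{first_egg}, \code{incubation_start}, \code{hatching}; dates or
#'   Julian integers).
#' @param nestsites nest-site data.frame: \code{species} plus one column
#'   per variable; character/factor columns are treated as categorical,
#'   numeric as continuous.
#' @param motu a \linkS4class{MotuExperiment} (filtered with
#'   [filterCounts()] beforehand, or set \code{filter = TRUE}).
#' @param speciesA,speciesB the two species labels (default the first two
#'   found in \code{breeding}).
#' @param level \code{rowData} column used to aggregate diet counts.
#' @param nPerm permutations per null model (default 1000).
#' @param seed integer seed for all permutations.
#' @param filter run [filterCounts()] on \code{motu} first.
#' @param alpha significance level for the \code{significant} flag.
#' @return list with \code{variables} (data.frame: variable, dimension,
#'   kind, observed, null_mean, null_sd, p_raw, p_parametric, p_adjusted,
#'   significant), \code{composites} (data.frame for the three dimensions
#'   plus overall) and \code{nPerm}.
#' @examples
#' ds <- generateDataset(syntheticConfig(seed = 3, nNestsA = 25,
#'                                       nNestsB = 15))
#' res <- nicheOverlapAnalysis(ds$breeding, ds$nestsites, ds$motu,
#'                             nPerm = 100, seed = 9)
#' res$composites
#' @export
nicheOverlapAnalysis <- function(breeding, nestsites, motu,
                                 speciesA = NULL, speciesB = NULL,
                                 level = "order", nPerm = 1000, seed = NULL,
                                 filter = FALSE, alpha = 0.05) {
    breeding <- as.data.frame(breeding)
    nestsites <- as.data.frame(nestsites)
    if (is.null(speciesA)) speciesA <- unique(breeding$species)[1L]
    if (is.null(speciesB)) speciesB <- unique(breeding$species)[2L]
    if (filter) motu <- filterCounts(motu)

    asJulian <- function(x)
        if (inherits(x, "Date") || is.character(x)) toJulian(x) else
            as.numeric(x)
    bA <- breeding[breeding$species == speciesA, ]
    bB <- breeding[breeding$species == speciesB, ]
    breedingVars <- lapply(c("first_egg", "incubation_start", "hatching"),
        function(col) .makeVar(col, asJulian(bA[[col]]),
                               asJulian(bB[[col]])))

    nsCols <- setdiff(names(nestsites), c("nest_id", "species"))
    nA <- nestsites[nestsites$species == speciesA, ]
    nB <- nestsites[nestsites$species == speciesB, ]
    nestVars <- lapply(nsCols, function(col) {
        kind <- if (is.numeric(nestsites[[col]])) "continuous" else
            "categorical"
        .makeVar(col, nA[[col]], nB[[col]], kind)
    })

    mat <- aggregateToLevel(motu, level)
    prop <- .perSampleProportions(mat)
    sp <- sampleSpecies(motu)
    dietVars <- lapply(rownames(prop), function(ord)
        .makeVar(paste0("diet_", ord),
                 prop[ord, sp == speciesA],
                 prop[ord, sp == speciesB],
                 "proportion"))

    dims <- list(breeding_time = breedingVars, nest_site = nestVars,
                 diet = dietVars)
    seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
        as.list(seed + seq_along(dims))

    perDim <- Map(function(vars, s) .dimensionNull(vars, nPerm, s),
                  dims, seeds)

    varRows <- list(); compRows <- list()
    allObs <- numeric(0); allNull <- NULL
    for (dim in names(perDim)) {
        res <- perDim[[dim]]
        kinds <- vapply(dims[[dim]], `[[`, "", "kind")
        stats <- t(vapply(seq_along(res$observed), function(j)
            .pFromNull(res$observed[j], res$null[, j]),
            c(p = 0, pParam = 0, mu = 0, sd = 0)))
        pAdj <- sequentialBonferroni(stats[, "p"])
        varRows[[dim]] <- data.frame(
            variable = names(res$observed), dimension = dim, kind = kinds,
            observed = unname(res$observed), null_mean = stats[, "mu"],
            null_sd = stats[, "sd"], p_raw = stats[, "p"],
            p_parametric = stats[, "pParam"], p_adjusted = pAdj,
            row.names = NULL)
        compObs <- mean(res$observed)
        compNull <- rowMeans(res$null)
        cs <- .pFromNull(compObs, compNull)
        compRows[[dim]] <- data.frame(
            dimension = dim, n_variables = length(res$observed),
            mean = compObs,
            sd = if (length(res$observed) > 1) stats::sd(res$observed)
                 else 0,
            null_mean = cs[["mu"]], p_raw = cs[["p"]],
            p_parametric = cs[["pParam"]], row.names = NULL)
        allObs <- c(allObs, res$observed)
        allNull <- cbind(allNull, res$null)
    }
    overallObs <- mean(allObs)
    overallNull <- rowMeans(allNull)
    os <- .pFromNull(overallObs, overallNull)
    compRows$overall <- data.frame(
        dimension = "overall", n_variables = length(allObs),
        mean = overallObs, sd = stats::sd(allObs), null_mean = os[["mu"]],
        p_raw = os[["p"]], p_parametric = os[["pParam"]], row.names = NULL)

    variables <- do.call(rbind, varRows)
    rownames(variables) <- NULL
    variables$significant <- variables$p_adjusted < alpha
    composites <- do.call(rbind, compRows)
    rownames(composites) <- NULL
    composites$p_adjusted <- sequentialBonferroni(composites$p_raw)
    composites$significant <- composites$p_adjusted < alpha
    list(variables = variables, composites = composites,
         nPerm = as.integer(nPerm))
}

#' Breeding-time summary: periods, co-breeding overlap, hatching rates
#'
#' @param breeding breeding-record data.frame (see
#'   [nicheOverlapAnalysis()]), with \code{clutch_size}/\code{brood_size}
#'   columns if hatching rates are wanted.
#' @param speciesA,speciesB species labels (default the first two found).
#' @return list with the two \linkS4class{BreedingPeriod}s, the two
#'   co-breeding overlap percentages and per-species hatching-rate
#'   mean +/- SE (NA if sizes are absent).
#' @export
breedingTimeSummary <- function(breeding, speciesA = NULL, speciesB = NULL) {
    breeding <- as.data.frame(breeding)
    if (is.null(speciesA)) speciesA <- unique(breeding$species)[1L]
    if (is.null(speciesB)) speciesB <- unique(breeding$species)[2L]
    pA <- breedingPeriod(breeding, speciesA)
    pB <- breedingPeriod(breeding, speciesB)
    hr <- function(sp) {
        rows <- breeding[breeding$species == sp, ]
        if (!all(c("clutch_size", "brood_size") %in% names(rows)) ||
            all(is.na(rows$brood_size)))
            return(c(mean = NA_real_, se = NA_real_))
        ok <- !is.na(rows$brood_size) & rows$clutch_size > 0
        r <- hatchingRate(rows$brood_size[ok], rows$clutch_size[ok])
        c(mean = mean(r), se = stats::sd(r) / sqrt(length(r)))
    }
    list(periodA = pA, periodB = pB,
         overlapPctA = periodOverlapFraction(pA, pB),
         overlapPctB = periodOverlapFraction(pB, pA),
         hatchingRateA = hr(speciesA), hatchingRateB = hr(speciesB))
}
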