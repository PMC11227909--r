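#' Aggregate MOTU counts to a taxonomic level
#'
#' Sums MOTU read counts within each taxon at the requested level, using
#' the MOTU taxonomy stored in \code{rowData}. MOTUs not resolved at that
#' level can be dropped or pooled per class into "<class>_others"-style
#' bins upstream; here anything with an \code{NA} label is dropped with a
#' message.
#'
#' @param x a (filtered) \linkS4class{MotuExperiment}.
#' @param level name of the \code{rowData} column holding the taxon label
#'   at the desired level (e.g. \code{"order"}).
#' @return numeric matrix, taxa x samples.
#' @export
aggregateToLevel <- function(x, level = "order") {
    rd <- SummarizedExperiment::rowData(x)
    if (!level %in% colnames(rd))
        stop("rowData has no '", level, "' column")
    lab <- as.character(rd[[level]])
    keep <- !is.na(lab)
    if (!all(keep))
        message(sum(!keep), " MOTUs unresolved at the ", level,
                " level dropped from aggregation")
    cts <- motuCounts(x)[keep, , drop = FALSE]
    rowsum(cts, group = lab[keep])
}

.perSampleProportions <- function(mat) {
    totals <- colSums(mat)
    sweep(mat, 2, pmax(totals, 1), "/")
}

#' Relative read abundance (RRA) per taxon and species
#'
#' RRA weights every individual equally: within each sample the read counts
#' are converted to proportions, and the RRA of a taxon for a species is
#' the mean of those per-sample proportions over that species' samples,
#' expressed as a percentage. Each species' RRA vector sums to 100.
#' Samples with zero reads at the chosen level are excluded with a warning
#' (they carry no compositional information).
#'
#' @param x a filtered \linkS4class{MotuExperiment} with taxonomy in
#'   \code{rowData}.
#' @param level taxonomy level to aggregate to (a \code{rowData} column).
#' @param pooled if \code{TRUE}, use the pooled-reads form instead (taxon
#'   reads over all reads of the species); default \code{FALSE}, the
#'   mean-of-proportions form standard for diet metabarcoding.
#' @return matrix of percentages, taxa x species.
#' @examples
#' m <- rbind(motu1 = c(100, 0), motu2 = c(0, 50))
#' colnames(m) <- c("s1", "s2")
#' tax <- data.frame(order = c("Lepidoptera", "Araneae"),
#'                   row.names = c("motu1", "motu2"))
#' me <- MotuExperiment(m, species = c("A", "A"), taxonomy = tax)
#' rra(me)   # 50/50 for species A
#' @export
rra <- function(x, level = "order", pooled = FALSE) {
    mat <- aggregateToLevel(x, level)
    sp <- sampleSpecies(x)
    empty <- colSums(mat) == 0
    if (any(empty)) {
        warning(sum(empty), " sample(s) with zero reads at the ", level,
                " level excluded from RRA")
        mat <- mat[, !empty, drop = FALSE]
        sp <- droplevels(sp[!empty])
    }
    if (pooled) {
        out <- vapply(levels(sp), function(s) {
            tot <- rowSums(mat[, sp == s, drop = FALSE])
            100 * tot / sum(tot)
        }, numeric(nrow(mat)))
    } else {
        prop <- .perSampleProportions(mat)
        out <- vapply(levels(sp), function(s)
            100 * rowMeans(prop[, sp == s, drop = FALSE]),
            numeric(nrow(mat)))
    }
    .taxonBySpecies(out, mat, sp)
}

# vapply drops to a vector when there is a single taxon; restore the
# taxa x species matrix shape
.taxonBySpecies <- function(out, mat, sp) {
    if (!is.matrix(out))
        out <- matrix(out, nrow = nrow(mat))
    dimnames(out) <- list(rownames(mat), levels(sp))
    out
}

#' Percent frequency of occurrence (%FOO) per taxon and species
#'
#' The percentage of a species' samples in which each taxon is detected
#' (read count > 0).
#'
#' @inheritParams rra
#' @return matrix of percentages, taxa x species.
#' @export
foo <- function(x, level = "order") {
    mat <- aggregateToLevel(x, level)
    sp <- sampleSpecies(x)
    if (ncol(mat) == 0L) stop("no samples in the table")
    out <- vapply(levels(sp), function(s)
        100 * rowMeans(mat[, sp == s, drop = FALSE] > 0),
        numeric(nrow(mat)))
    .taxonBySpecies(out, mat, sp)
}

#' Individual diet richness: MOTUs detected per sample
#'
#' Counts the prey MOTUs detected in each fecal sample and summarizes per
#' species as mean and standard error, the usual "average number of prey
#' taxa consumed per individual".
#'
#' @param x a filtered \linkS4class{MotuExperiment}.
#' @return list with \code{per_sample} (data.frame: sample, species,
#'   richness) and \code{summary} (data.frame: species, n, mean, se).
#' @export
individualRichness <- function(x) {
    cts <- motuCounts(x)
    rich <- colSums(cts > 0)
    sp <- sampleSpecies(x)
    per <- data.frame(sample = colnames(cts), species = sp,
                      richness = as.integer(rich), row.names = NULL)
    summ <- do.call(rbind, lapply(levels(sp), function(s) {
        r <- rich[sp == s]
        data.frame(species = s, n = length(r), mean = mean(r),
                   se = stats::sd(r) / sqrt(length(r)))
    }))
    list(per_sample = per, summary = summ)
}

#' Levins standardized niche breadth
#'
#' Levins' measure of niche breadth over \eqn{n} resource categories with
#' use proportions \eqn{p_i} is \eqn{B = 1 / \sum p_i^2}; Hurlbert's
#' standardization \eqn{B_A = (B - 1) / (n - 1)} rescales it to [0, 1],
#' with 0 for complete specialization on one category and 1 for uniform
#' use of all categories.
#'
#' @param proportions non-negative numeric vector of diet proportions
#'   summing to 1 (tolerance \code{1e-6}), at least 2 categories.
#' @return list with \code{B}, \code{B_A} and \code{n_categories}.
#' @examples
#' levinsBA(c(0.5, 0.25, 0.25))
#' @export
levinsBA <- function(proportions) {
    p <- as.numeric(proportions)
    if (length(p) < 2L)
        stop("niche breadth needs at least 2 resource categories")
    if (any(is.na(p)) || any(p < 0))
        stop("proportions must be non-negative and non-missing")
    if (abs(sum(p) - 1) > 1e-6)
        stop("proportions must sum to 1 (got ", format(sum(p)), ")")
    B <- 1 / sum(p^2)
    n <- length(p)
    list(B = B, B_A = (B - 1) / (n - 1), n_categories = n)
}

# Expected richness in t pooled samples: the classical sample-based
# (incidence) rarefaction estimator. Y = incidence frequencies, T = number
# of sampling units. Uses log-scale binomial coefficients for stability.
.rarefyIncidence <- function(Y, T, t) {
    Y <- Y[Y > 0]
    vapply(t, function(tt) {
        if (tt >= T) return(length(Y))
        miss <- exp(lchoose(T - Y, tt) - lchoose(T, tt))
        miss[T - Y < tt] <- 0
        length(Y) - sum(miss)
    }, numeric(1))
}

# Chao2-style extrapolation of incidence richness t* units beyond T.
.extrapolateIncidence <- function(Y, T, tstar) {
    Y <- Y[Y > 0]
    Sobs <- length(Y)
    Q1 <- sum(Y == 1); Q2 <- sum(Y == 2)
    Q0hat <- if (Q2 > 0) (T - 1) / T * Q1^2 / (2 * Q2) else
        (T - 1) / T * Q1 * (Q1 - 1) / 2
    if (Q0hat == 0 || Q1 == 0) return(rep(Sobs, length(tstar)))
    Sobs + Q0hat * (1 - (1 - Q1 / (Q1 + T * Q0hat))^tstar)
}

#' Sample-based rarefaction and extrapolation of prey richness
#'
#' Richness (Hill number of order q = 0) as a function of the number of
#' sampling units, from incidence (presence/absence) data: interpolation by
#' the classical hypergeometric estimator, extrapolation beyond the
#' observed number of samples via the Chao2 estimate of undetected
#' richness. 95\% confidence intervals come from a percentile bootstrap
#' that resamples whole samples with replacement.
#'
#' @param presence logical or 0/1 matrix, taxa x samples (a count matrix is
#'   accepted and thresholded at > 0).
#' @param endpoint largest number of sampling units on the curve; defaults
#'   to twice the observed number.
#' @param nBoot bootstrap replications for the CIs (default 1000; set to 0
#'   to skip).
#' @param seed optional integer seed for the bootstrap.
#' @param conf confidence level.
#' @return data.frame with columns \code{t}, \code{method}
#'   (\code{"interpolated"}/\code{"observed"}/\code{"extrapolated"}),
#'   \code{richness}, \code{lower}, \code{upper}.
#' @examples
#' pres <- rbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(0, 1, 1))
#' rarefactionCurve(pres, nBoot = 0)
#' @export
rarefactionCurve <- function(presence, endpoint = NULL, nBoot = 1000,
                             seed = NULL, conf = 0.95) {
    inc <- (as.matrix(presence) > 0) * 1L
    T <- ncol(inc)
    if (T < 2L) stop("rarefaction needs at least 2 samples")
    if (is.null(endpoint)) endpoint <- 2L * T
    tGrid <- seq_len(endpoint)
    est <- function(m) {
        Y <- rowSums(m); TT <- ncol(m)
        c(.rarefyIncidence(Y, TT, tGrid[tGrid <= TT]),
          .extrapolateIncidence(Y, TT, tGrid[tGrid > TT] - TT))
    }
    rich <- est(inc)
    out <- data.frame(
        t = tGrid,
        method = ifelse(tGrid < T, "interpolated",
                        ifelse(tGrid == T, "observed", "extrapolated")),
        richness = rich, lower = NA_real_, upper = NA_real_)
    if (nBoot > 0) {
        boots <- withSeed(seed, {
            vapply(seq_len(nBoot), function(b) {
                est(inc[, sample.int(T, T, replace = TRUE), drop = FALSE])
            }, numeric(length(tGrid)))
        })
        alpha <- (1 - conf) / 2
        qs <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha))
        out$lower <- qs[1L, ]
        out$upper <- qs[2L, ]
    }
    out
}
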