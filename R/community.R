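#' Bray-Curtis distance matrix between sample compositions
#'
#' Pairwise Bray-Curtis dissimilarities
#' \eqn{d(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)} between the rows
#' of a composition matrix, computed via \code{vegan::vegdist}. A pair in
#' which both samples are all-zero has no defined dissimilarity and is
#' reported as \code{NA} with a warning.
#'
#' @param profiles non-negative numeric matrix, samples x taxa (counts or
#'   proportions).
#' @return a symmetric matrix with zero diagonal, dimnames from the sample
#'   names.
#' @examples
#' brayCurtis(rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1)))
#' @export
brayCurtis <- function(profiles) {
    profiles <- as.matrix(profiles)
    if (any(profiles < 0)) stop("compositions must be non-negative")
    if (is.null(rownames(profiles)))
        rownames(profiles) <- paste0("sample", seq_len(nrow(profiles)))
    zero <- rowSums(profiles) == 0
    d <- as.matrix(suppressWarnings(
        vegan::vegdist(profiles, method = "bray")))
    if (any(zero)) {
        warning(sum(zero), " all-zero sample(s); their pairwise distances ",
                "are undefined and set to NA")
        d[zero, ] <- NA_real_
        d[, zero] <- NA_real_
    }
    diag(d) <- 0
    d
}

.anosimR <- function(rk, within, n) {
    (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

#' ANOSIM: analysis of similarities
#'
#' Clarke's rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All pairwise distances are ranked (mid
#' ranks for ties) and
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{n(n-1)/4},}
#' which lies in [-1, 1] and is near 0 when grouping is arbitrary.
#' Significance comes from permuting the group labels: with
#' \code{exact = TRUE} every distinct assignment of labels to samples is
#' enumerated and p is the fraction of assignments with \eqn{R \ge R_{obs}}
#' (the observed labeling included); otherwise \code{nPerm} random
#' permutations are drawn and \eqn{p = (1 + \#\{R^* \ge R_{obs}\}) /
#' (nPerm + 1)}.
#'
#' @param dist symmetric distance matrix (or \code{dist} object).
#' @param labels group labels, one per sample; every group needs >= 2
#'   samples.
#' @param nPerm number of random permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @param exact enumerate all label assignments instead of sampling (only
#'   sensible for small n; two groups only).
#' @return list with \code{R}, \code{p}, \code{n_perm}.
#' @examples
#' m <- rbind(c(0, 0), c(0.1, 0), c(3, 3), c(3.1, 3))
#' d <- brayCurtis(m + 1)
#' anosim(d, c("A", "A", "B", "B"), exact = TRUE)
#' @export
anosim <- function(dist, labels, nPerm = 999, seed = NULL, exact = FALSE) {
    d <- as.matrix(dist)
    n <- nrow(d)
    labels <- as.character(labels)
    if (length(labels) != n)
        stop("need one label per sample")
    if (any(table(labels) < 2L))
        stop("every group needs at least 2 samples")
    lowIdx <- which(lower.tri(d))
    rk <- rank(d[lowIdx])  # mid-ranks for ties
    pairRow <- row(d)[lowIdx]
    pairCol <- col(d)[lowIdx]
    Rof <- function(lab)
        .anosimR(rk, lab[pairRow] == lab[pairCol], n)
    Robs <- Rof(labels)
    if (exact) {
        grp <- unique(labels)
        if (length(grp) != 2L)
            stop("exact enumeration implemented for two groups")
        nA <- sum(labels == grp[1L])
        sets <- combn(n, nA)
        Rnull <- apply(sets, 2, function(ix) {
            lab <- rep(grp[2L], n); lab[ix] <- grp[1L]
            Rof(lab)
        })
        p <- sum(Rnull >= Robs - 1e-12) / length(Rnull)
        nPerm <- length(Rnull)
    } else {
        Rnull <- withSeed(seed, {
            vapply(seq_len(nPerm), function(i) Rof(sample(labels)),
                   numeric(1))
        })
        p <- (1 + sum(Rnull >= Robs - 1e-12)) / (nPerm + 1)
    }
    list(R = Robs, p = p, n_perm = as.integer(nPerm))
}
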