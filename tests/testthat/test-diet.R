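test_that("RRA averages per-sample proportions and sums to 100 per
           species", {
    m <- rbind(motu1 = c(100L, 0L), motu2 = c(0L, 50L))
    colnames(m) <- c("s1", "s2")
    tax <- data.frame(order = c("Lepidoptera", "Araneae"),
                      row.names = rownames(m))
    me <- MotuExperiment(m, species = c("A", "A"), taxonomy = tax)
    r <- rra(me)
    expect_equal(unname(r["Lepidoptera", "A"]), 50)
    expect_equal(unname(r["Araneae", "A"]), 50)

    set.seed(11)
    me2 <- randomMotu()
    tax2 <- data.frame(order = sample(c("Lep", "Ara", "Dip"), 40,
                                      replace = TRUE),
                       row.names = rownames(motuCounts(me2)))
    me2 <- MotuExperiment(motuCounts(me2), sampleSpecies(me2), tax2)
    r2 <- rra(me2)
    expect_equal(unname(colSums(r2)), c(100, 100), tolerance = 1e-9)
    rp <- rra(me2, pooled = TRUE)
    expect_equal(unname(colSums(rp)), c(100, 100), tolerance = 1e-9)
})

test_that("all-one-taxon samples give 100% RRA and empty samples are
           excluded with a warning", {
    m <- rbind(motu1 = c(10L, 99L, 0L))
    colnames(m) <- paste0("s", 1:3)
    tax <- data.frame(order = "Lepidoptera", row.names = "motu1")
    me <- MotuExperiment(m, species = c("A", "A", "A"), taxonomy = tax)
    expect_warning(r <- rra(me), "zero reads")
    expect_equal(unname(r["Lepidoptera", "A"]), 100)
})

test_that("%FOO counts the share of samples containing each taxon", {
    m <- rbind(lep = c(5L, 1L, 9L, 0L), ara = c(0L, 0L, 0L, 0L),
               dip = c(1L, 1L, 1L, 1L))
    colnames(m) <- paste0("s", 1:4)
    tax <- data.frame(order = c("Lepidoptera", "Araneae", "Diptera"),
                      row.names = rownames(m))
    me <- MotuExperiment(m, species = rep("A", 4), taxonomy = tax)
    f <- foo(me)
    expect_equal(unname(f["Lepidoptera", "A"]), 75)
    expect_equal(unname(f["Araneae", "A"]), 0)
    expect_equal(unname(f["Diptera", "A"]), 100)
    expect_true(all(f >= 0 & f <= 100))
})

test_that("individual richness counts detected MOTUs with mean and SE", {
    m <- rbind(m1 = c(5L, 1L, 0L), m2 = c(0L, 1L, 0L), m3 = c(2L, 1L, 0L),
               m4 = c(0L, 1L, 0L), m5 = c(0L, 1L, 0L))
    colnames(m) <- paste0("s", 1:3)
    me <- MotuExperiment(m, species = c("A", "A", "B"))
    ir <- individualRichness(me)
    expect_identical(ir$per_sample$richness, c(2L, 5L, 0L))
    a <- ir$summary[ir$summary$species == "A", ]
    expect_equal(a$mean, 3.5)
    expect_equal(a$se, sd(c(2, 5)) / sqrt(2))
    # the (3,5) -> 4 +/- 1 arithmetic
    m2 <- matrix(c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L, 1L), nrow = 5)
    me2 <- MotuExperiment(m2, species = c("A", "A"))
    s2 <- individualRichness(me2)$summary
    expect_equal(s2$mean, 4)
    expect_equal(s2$se, 1)
})

test_that("Levins standardized breadth behaves across its range", {
    expect_equal(levinsBA(rep(1 / 7, 7))$B_A, 1)
    expect_equal(levinsBA(c(1, 0, 0, 0))$B_A, 0)
    r <- levinsBA(c(0.5, 0.25, 0.25))
    expect_equal(r$B, 1 / 0.375)
    expect_equal(r$B_A, (1 / 0.375 - 1) / 2)
    # invariance under permutation of categories
    p <- c(0.4, 0.3, 0.2, 0.1)
    expect_equal(levinsBA(p)$B_A, levinsBA(rev(p))$B_A)
    # breadth strictly decreases as use concentrates
    seqs <- list(c(0.25, 0.25, 0.25, 0.25), c(0.4, 0.3, 0.2, 0.1),
                 c(0.7, 0.1, 0.1, 0.1), c(0.97, 0.01, 0.01, 0.01))
    bas <- vapply(seqs, function(q) levinsBA(q)$B_A, numeric(1))
    expect_true(all(diff(bas) < 0))
    expect_error(levinsBA(1), "categories")
    expect_error(levinsBA(c(0.5, 0.4)), "sum to 1")
})

test_that("incidence rarefaction matches brute-force subsample
           enumeration", {
    pres <- rbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(0, 1, 1),
                  d = c(0, 0, 1), e = c(1, 1, 1))
    rc <- rarefactionCurve(pres, nBoot = 0)
    Tn <- ncol(pres)
    # endpoint identity: observed richness
    expect_equal(rc$richness[rc$t == Tn], sum(rowSums(pres) > 0))
    # t = 1: mean per-sample richness
    expect_equal(rc$richness[rc$t == 1], mean(colSums(pres > 0)))
    # t = 2: brute-force average over all sample pairs
    pairs <- combn(Tn, 2)
    brute <- mean(apply(pairs, 2, function(ix)
        sum(rowSums(pres[, ix]) > 0)))
    expect_equal(rc$richness[rc$t == 2], brute)
})

test_that("rarefaction agrees with vegan's exact sample-based expectation
           and extrapolation behaves", {
    set.seed(5)
    pres <- matrix(rbinom(15 * 8, 1, 0.35), nrow = 15)
    rc <- rarefactionCurve(pres, nBoot = 50, seed = 3)
    sac <- vegan::specaccum(t(pres), method = "exact")
    interp <- rc$richness[rc$t <= ncol(pres)]
    expect_equal(interp, sac$richness, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # monotone non-decreasing and concave over the whole curve
    expect_true(all(diff(rc$richness) >= -1e-9))
    expect_true(all(diff(diff(rc$richness)) <= 1e-6))
    # extrapolation never below the observed richness; CIs bracket
    obs <- rc$richness[rc$t == ncol(pres)]
    expect_true(all(rc$richness[rc$method == "extrapolated"] >= obs - 1e-9))
    expect_true(all(rc$lower <= rc$richness + 1e-9 &
                    rc$richness <= rc$upper + 1e-9))
    expect_error(rarefactionCurve(pres[, 1, drop = FALSE]), "2 samples")
})

test_that("rarefaction bootstrap is reproducible under a seed", {
    set.seed(99)
    pres <- matrix(rbinom(10 * 6, 1, 0.4), nrow = 10)
    r1 <- rarefactionCurve(pres, nBoot = 30, seed = 7)
    r2 <- rarefactionCurve(pres, nBoot = 30, seed = 7)
    expect_identical(r1, r2)
})
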