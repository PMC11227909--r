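# independent quadrature oracle for the overlap of two known densities
tvOverlap <- function(f1, f2, lo, hi, n = 100001) {
    x <- seq(lo, hi, length.out = n)
    y <- abs(f1(x) - f2(x))
    1 - 0.5 * sum(diff(x) * (y[-1] + y[-n])) / 2
}

test_that("kernel-density overlap matches analytic values for normal
           samples", {
    x <- rnorm(200)
    expect_equal(continuousOverlap(x, x), 1, tolerance = 1e-6)

    set.seed(202)
    far <- continuousOverlap(rnorm(500), rnorm(500, 100))
    expect_lt(far, 0.01)

    truth <- tvOverlap(function(x) dnorm(x), function(x) dnorm(x, 3),
                       -8, 11)
    expect_equal(truth, 2 * pnorm(-1.5), tolerance = 1e-6)
    est <- continuousOverlap(rnorm(2000), rnorm(2000, 3))
    expect_lt(abs(est - truth), 0.03)
})

test_that("overlap is symmetric in the two groups and bounded", {
    set.seed(7)
    for (i in 1:5) {
        a <- rnorm(60, runif(1, -2, 2), runif(1, 0.5, 2))
        b <- rgamma(45, 2, 1)
        expect_equal(continuousOverlap(a, b), continuousOverlap(b, a),
                     tolerance = 1e-12)
        ov <- continuousOverlap(a, b)
        expect_true(ov >= 0 && ov <= 1)
    }
    expect_equal(categoricalOverlap(c("x", "y"), c("y", "x")),
                 categoricalOverlap(c("y", "x"), c("x", "y")))
})

test_that("zero-spread groups fall back to label overlap with a warning", {
    expect_warning(ov <- continuousOverlap(rep(2, 10), rep(2, 8)),
                   "zero-spread")
    expect_equal(ov, 1)
    expect_warning(ov2 <- continuousOverlap(rep(2, 10), rep(5, 8)),
                   "zero-spread")
    expect_equal(ov2, 0)
})

test_that("categorical overlap is the proportional similarity of category
           use", {
    expect_equal(categoricalOverlap(c("a", "a", "b"), c("a", "a", "b")), 1)
    expect_equal(categoricalOverlap(rep("a", 5), rep("b", 3)), 0)
    a <- rep(c("x", "y"), c(2, 2))
    b <- rep(c("x", "y", "z"), c(1, 1, 2))
    expect_equal(categoricalOverlap(a, b), 0.5)
    expect_error(categoricalOverlap(character(0), "a"), "non-empty")
})

test_that("proportion overlap handles atoms at the boundaries exactly", {
    # both groups all-zero: identical point masses
    expect_equal(proportionOverlap(rep(0, 10), rep(0, 6)), 1)
    # one all-zero vs one all-one: disjoint
    expect_equal(proportionOverlap(rep(0, 10), rep(1, 6)), 0)
    # atom overlap is the smaller zero-share when interiors are disjoint
    a <- c(rep(0, 6), rep(0.9, 4))   # 60% zeros
    b <- c(rep(0, 3), rep(0.9, 7))   # 30% zeros
    suppressWarnings(ov <- proportionOverlap(a, b))
    expect_equal(ov, 0.3 + 0.4)  # min zero shares + min interior masses
    set.seed(31)
    x <- rbeta(300, 2, 5)
    expect_equal(proportionOverlap(x, x), 1, tolerance = 1e-6)
    expect_error(proportionOverlap(c(0.5, 1.2), c(0.1)), "\\[0, 1\\]")
})

test_that("proportion overlap recovers the analytic zero-inflated Beta
           overlap", {
    # mimic the diet observable: Beta latent proportion, atom at zero from
    # non-detection at finite read depth
    a1 <- 0.4; b1 <- 3.6; a2 <- 0.25; b2 <- 3.75; N <- 5000
    truth <- overlapTrueDietProportions(a1, b1, a2, b2, reads = N)
    set.seed(88)
    draw <- function(a, b, n) {
        p <- rbeta(n, a, b)
        vapply(p, function(pp) rbinom(1, N, pp), numeric(1)) / N
    }
    est <- mean(replicate(4, proportionOverlap(draw(a1, b1, 800),
                                               draw(a2, b2, 800))))
    expect_lt(abs(est - truth), 0.04)
})

test_that("composite overlap reproduces mean +/- sd arithmetic", {
    r <- compositeOverlap(c(0.448, 0.428, 0.444))
    expect_equal(round(r$mean, 3), 0.440)
    # members are themselves printed to 3 dp, so the recomputed sd carries
    # their rounding error (up to ~1e-3)
    expect_lt(abs(r$sd - 0.010), 1e-3)
    expect_equal(compositeOverlap(0.7)$sd, 0)
    expect_error(compositeOverlap(numeric(0)), "no member")
    expect_error(compositeOverlap(c(0.5, 1.4)), "\\[0, 1\\]")
})

test_that("sequential Bonferroni follows the Holm step-down by hand", {
    expect_equal(sequentialBonferroni(c(0.01, 0.04, 0.03)),
                 c(0.03, 0.06, 0.06))
    expect_equal(sequentialBonferroni(0.2), 0.2)
    expect_equal(sequentialBonferroni(rep(1, 4)), rep(1, 4))
    p <- c(0.001, 0.2, 0.04, 0.9)
    expect_true(all(sequentialBonferroni(p) >= p))
    expect_error(sequentialBonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identity relabeling reproduces the observed overlap", {
    set.seed(14)
    a <- rnorm(25); b <- rnorm(20, 1)
    pooled <- c(a, b)
    idx <- seq_along(a)
    expect_equal(continuousOverlap(pooled[idx], pooled[-idx]),
                 continuousOverlap(a, b))
})

test_that("null model test separates distinct groups and is reproducible", {
    set.seed(60)
    a <- rnorm(50); b <- rnorm(50, 5)
    r1 <- nullModelTest(a, b, nPerm = 500, seed = 42)
    r2 <- nullModelTest(a, b, nPerm = 500, seed = 42)
    expect_identical(r1@pRaw, r2@pRaw)
    expect_lt(r1@pRaw, 0.05)
    expect_lt(r1@observed, r1@nullMean)
    expect_true(r1@nullSd > 0)
    expect_true(r1@pParametric < 0.05)
    # same-distribution groups: p should not be extreme
    s <- nullModelTest(rnorm(50), rnorm(50), nPerm = 500, seed = 43)
    expect_true(s@pRaw > 0 && s@pRaw <= 1)
    expect_error(nullModelTest(a, b, nPerm = 50), "100")
})

test_that("categorical null model works on label data", {
    set.seed(61)
    a <- sample(c("N", "S"), 40, replace = TRUE, prob = c(0.9, 0.1))
    b <- sample(c("N", "S"), 40, replace = TRUE, prob = c(0.1, 0.9))
    r <- nullModelTest(a, b, kind = "categorical", nPerm = 300, seed = 2)
    expect_lt(r@pRaw, 0.05)
    expect_true(r@observed >= 0 && r@observed <= 1)
})
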