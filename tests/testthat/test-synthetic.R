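test_that("generation is deterministic under the config seed", {
    cfg <- syntheticConfig(seed = 7, nNestsA = 15, nNestsB = 10,
                           nFecalA = 8, nFecalB = 6)
    d1 <- generateDataset(cfg)
    d2 <- generateDataset(cfg)
    expect_identical(d1$breeding, d2$breeding)
    expect_identical(d1$nestsites, d2$nestsites)
    expect_identical(motuCounts(d1$motu), motuCounts(d2$motu))
    expect_identical(d1$taxonomy, d2$taxonomy)
    expect_identical(d1$truth, d2$truth)
    # and a different seed changes the draw
    d3 <- generateDataset(syntheticConfig(seed = 8, nNestsA = 15,
                                          nNestsB = 10, nFecalA = 8,
                                          nFecalB = 6))
    expect_false(identical(d1$breeding, d3$breeding))
})

test_that("identical group distributions give truth overlap 1
           everywhere", {
    base <- syntheticConfig()
    diet <- base$diet
    diet$dirichlet_alpha_B <- diet$dirichlet_alpha_A
    vars <- lapply(base$nestsiteVars, function(v) {
        v$params_B <- v$params_A
        v
    })
    truth <- generateDataset(
        syntheticConfig(seed = 2, nNestsA = 5, nNestsB = 5, nFecalA = 4,
                        nFecalB = 4, phenologyA = base$phenologyA,
                        phenologyB = base$phenologyA, nestsiteVars = vars,
                        diet = diet))$truth
    expect_equal(unname(truth), rep(1, length(truth)), tolerance = 1e-6)
})

test_that("truth overlap matches the closed form for two unit normals
           3 sd apart", {
    expect_equal(overlapTrueNormals(0, 1, 3, 1), 2 * pnorm(-1.5),
                 tolerance = 1e-6)
    vars <- list(list(name = "v", kind = "continuous",
                      params_A = list(mean = 0, sd = 1, lower = -Inf,
                                      upper = Inf),
                      params_B = list(mean = 3, sd = 1, lower = -Inf,
                                      upper = Inf)))
    cfg <- syntheticConfig(seed = 1, nNestsA = 5, nNestsB = 5,
                           nFecalA = 4, nFecalB = 4, nestsiteVars = vars)
    expect_equal(unname(generateDataset(cfg)$truth["v"]), 2 * pnorm(-1.5),
                 tolerance = 1e-6)
    # beta oracle: identical shapes overlap fully, disjoint-ish shapes don't
    expect_equal(overlapTrueBetas(2, 5, 2, 5), 1, tolerance = 1e-6)
    expect_lt(overlapTrueBetas(40, 2, 2, 40), 0.01)
})

test_that("generated records respect the configured structure", {
    cfg <- syntheticConfig(seed = 3, nNestsA = 20, nNestsB = 12,
                           nFecalA = 10, nFecalB = 7)
    ds <- generateDataset(cfg)
    expect_identical(nrow(ds$breeding), 32L)
    expect_identical(nrow(ds$nestsites), 32L)
    expect_setequal(unique(ds$breeding$species), c("A", "B"))
    expect_identical(ncol(ds$motu), 17L)
    cts <- motuCounts(ds$motu)
    expect_true(all(cts >= 0 & cts == round(cts)))
    # phenology ordering holds in every record
    expect_true(all(ds$breeding$first_egg <= ds$breeding$incubation_start))
    expect_true(all(ds$breeding$incubation_start <= ds$breeding$hatching))
    expect_true(all(ds$breeding$brood_size <= ds$breeding$clutch_size))
    # 13 default nest-site variables
    expect_identical(length(setdiff(names(ds$nestsites),
                                    c("nest_id", "species"))), 13L)
    # percentages stay in [0, 100]
    expect_true(all(ds$nestsites$canopy_cover_pct >= 0 &
                    ds$nestsites$canopy_cover_pct <= 100))
})

test_that("per-sample read totals stay within Poisson noise of the
           configured mean", {
    cfg <- syntheticConfig(seed = 10, nNestsA = 5, nNestsB = 5,
                           nFecalA = 30, nFecalB = 20)
    ds <- generateDataset(cfg)
    totals <- colSums(motuCounts(ds$motu))
    mu <- cfg$diet$reads_per_sample_mean
    expect_true(all(abs(totals - mu) < 6 * sqrt(mu)))
    expect_equal(mean(totals), mu, tolerance = 0.01)
})

test_that("invalid configurations fail with informative errors", {
    expect_error(syntheticConfig(nNestsA = 0), "positive")
    badDiet <- syntheticConfig()$diet
    badDiet$dirichlet_alpha_A <- c(1, -1)
    expect_error(syntheticConfig(diet = badDiet), "equal length|positive")
    ph <- syntheticConfig()$phenologyA
    ph$laying_len_mean <- NULL
    expect_error(syntheticConfig(phenologyA = ph), "laying_len_mean")
    vars <- list(list(name = "bad", kind = "fuzzy",
                      params_A = list(), params_B = list()))
    expect_error(syntheticConfig(nestsiteVars = vars), "unknown kind")
})

test_that("datasets survive a write/read round trip", {
    dir <- withr::local_tempdir()
    ds <- generateDataset(syntheticConfig(seed = 6, nNestsA = 8,
                                          nNestsB = 6, nFecalA = 5,
                                          nFecalB = 4))
    writeSyntheticDataset(ds, dir)
    expect_true(all(file.exists(file.path(dir,
        c("breeding.csv", "nestsites.csv", "motus.tsv", "taxonomy.tsv",
          "truth.json")))))
    back <- readSyntheticDataset(dir)
    expect_equal(back$breeding$first_egg, ds$breeding$first_egg)
    expect_equal(unname(motuCounts(back$motu)),
                 unname(motuCounts(ds$motu)))
    expect_identical(as.character(sampleSpecies(back$motu)),
                     as.character(sampleSpecies(ds$motu)))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    expect_equal(unlist(truth), ds$truth, tolerance = 1e-12)
})

test_that("estimated overlap recovers the analytic truth for a
           well-separated continuous variable", {
    vars <- list(list(name = "v", kind = "continuous",
                      params_A = list(mean = 0, sd = 1, lower = -Inf,
                                      upper = Inf),
                      params_B = list(mean = 3, sd = 1, lower = -Inf,
                                      upper = Inf)))
    cfg <- syntheticConfig(seed = 21, nNestsA = 600, nNestsB = 600,
                           nFecalA = 4, nFecalB = 4, nestsiteVars = vars)
    ds <- generateDataset(cfg)
    a <- ds$nestsites$v[ds$nestsites$species == "A"]
    b <- ds$nestsites$v[ds$nestsites$species == "B"]
    expect_lt(abs(continuousOverlap(a, b) - ds$truth[["v"]]), 0.05)
})
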