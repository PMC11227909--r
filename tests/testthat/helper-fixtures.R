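# Small MotuExperiment built in code for filter/diet tests.
toyMotu <- function() {
    counts <- rbind(
        motuA = c(9L,   60L,  50L),   # 9 < 0.1% of sample 1 total
        motuB = c(2L,    0L,   0L),   # total < 3 and single-sample
        motuC = c(500L, 400L, 450L),
        motuD = c(9000L, 540L, 0L),
        motuE = c(491L,   0L, 500L))
    colnames(counts) <- paste0("s", 1:3)
    tax <- data.frame(order = c("Lepidoptera", "Diptera", "Lepidoptera",
                                "Araneae", "Diptera"),
                      row.names = rownames(counts))
    MotuExperiment(counts, species = c("A", "A", "B"), taxonomy = tax)
}

randomMotu <- function(nMotus = 40, nSamples = 12, lambda = 80) {
    counts <- matrix(rpois(nMotus * nSamples, lambda) *
                     rbinom(nMotus * nSamples, 1, 0.4),
                     nrow = nMotus,
                     dimnames = list(paste0("m", seq_len(nMotus)),
                                     paste0("s", seq_len(nSamples))))
    MotuExperiment(counts,
                   species = rep(c("A", "B"), length.out = nSamples))
}
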