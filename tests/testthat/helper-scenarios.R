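# Shared simulation scenarios for the verification studies.

# Desk-scale end-to-end scenario: 1 Mb genome, two rounds per allele,
# high coverage, no decoys, 30 genes under modest allele-specific
# selection (4-fold at most, so treatment counts stay well above the
# pseudo-abundance regime).
endToEndConfig <- function(seed = 11) {
    base <- SimulationConfig(seed = seed, genomeLength = 1e6,
                             nChromosomes = 2, nGenes = 150,
                             geneLengthRange = c(1000, 4000),
                             nRoundsA = 2, nRoundsB = 2,
                             insertionsPerRound = 250,
                             readsPerInsertion = 250)
    g <- simulateGenomePair(base)
    set.seed(seed + 7)
    selGenes <- sample(g$genes$gene_id, 30)
    folds <- sample(c(1 / 4, 1 / 2, 2, 4), 30, TRUE)
    onA <- rep(c(TRUE, FALSE), 15)
    sel <- data.frame(gene_id = selGenes,
                      fold_A = ifelse(onA, folds, 1),
                      fold_B = ifelse(onA, 1, folds))
    SimulationConfig(seed = seed, genomeLength = 1e6, nChromosomes = 2,
                     nGenes = 150, geneLengthRange = c(1000, 4000),
                     nRoundsA = 2, nRoundsB = 2, insertionsPerRound = 250,
                     readsPerInsertion = 250, selection = sel)
}

# Count-level calibration scenario: an abstract 20 Mb genome with 1000
# equal-length genes and full 12+11 rounds, giving ~15 insertions per
# gene and allele (a deep-coverage regime); selection optional.
calibrationConfig <- function(seed, selection = NULL) {
    args <- list(seed = seed, genomeLength = 2e7, nChromosomes = 4,
                 nGenes = 1000, geneLengthRange = c(6000, 6000),
                 nRoundsA = 12, nRoundsB = 11, insertionsPerRound = 4200,
                 readsPerInsertion = 100, minSeparation = 0)
    if (!is.null(selection)) args$selection <- selection
    do.call(SimulationConfig, args)
}

# Run the count-level chain: plant -> counts -> InsertionSet -> effects
# -> gene tests. Returns the results table.
calibrationResults <- function(cfg) {
    sim <- simulateGenomePair(cfg)
    truth <- drawCounts(plantInsertions(cfg, sim$genes), cfg)
    iset <- truthInsertionSet(truth, cfg)
    eff <- insertionEffects(iset)
    runGeneTests(eff, alleles = cfg@alleles)
}

# Simulate to disk and run the full pipeline; returns sim + run output.
simulateAndRun <- function(cfg, dir, ...) {
    sim <- simulateExperiment(cfg, dir)
    rc <- runConfig(fastq = sim$fastq, samples = sim$samples,
                    reference = sim$reference, vcf = sim$vcf,
                    gff3 = sim$gff3, outdir = file.path(dir, "out"), ...)
    list(sim = sim, res = suppressMessages(runPipeline(rc)))
}
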