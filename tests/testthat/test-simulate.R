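small_cfg <- function(seed = 1, ...) {
    SimulationConfig(seed = seed, genomeLength = 2e5, nChromosomes = 2,
                     nGenes = 30, geneLengthRange = c(800, 2000),
                     nRoundsA = 2, nRoundsB = 2, insertionsPerRound = 40,
                     readsPerInsertion = 40, ...)
}

test_that("simulateGenomePair is deterministic and respects snpRate", {
    cfg <- small_cfg()
    a <- simulateGenomePair(cfg)
    b <- simulateGenomePair(cfg)
    expect_identical(as.character(a$reference), as.character(b$reference))
    expect_identical(a$snps, b$snps)
    expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))

    # snpRate 0: no SNPs, pseudogenome == reference
    c0 <- simulateGenomePair(small_cfg(snpRate = 0))
    expect_equal(nrow(c0$snps), 0L)
    expect_identical(
        as.character(buildPseudogenome(c0$reference, c0$snps)),
        as.character(c0$reference))

    # SNP ref alleles always match the reference (pseudogenome builds)
    expect_s4_class(buildPseudogenome(a$reference, a$snps),
                    "DNAStringSet")
})

test_that("SNP count lands within 4 sigma of the binomial expectation", {
    cfg <- SimulationConfig(seed = 5, genomeLength = 1e6,
                            nChromosomes = 1, nGenes = 50,
                            snpRate = 1e-3)
    sim <- simulateGenomePair(cfg)
    expected <- 1e6 * 1e-3
    sigma <- sqrt(1e6 * 1e-3 * (1 - 1e-3))
    expect_lt(abs(nrow(sim$snps) - expected), 4 * sigma)
})

test_that("gene models are non-overlapping and inside chromosomes", {
    sim <- simulateGenomePair(small_cfg(seed = 2))
    genes <- sim$genes
    expect_equal(length(genes), 30L)
    bychr <- split(genes, as.character(GenomicRanges::seqnames(genes)))
    for (g in bychr) {
        if (length(g) < 2) next
        s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
        o <- order(s)
        expect_true(all(s[o][-1] > e[o][-length(e)]))
    }
    expect_true(all(GenomicRanges::end(genes) <=
                    Biostrings::width(sim$reference)[1]))
})

test_that("planted selection shifts treatment expectation by the fold", {
    sim <- simulateGenomePair(small_cfg(seed = 3))
    sel <- data.frame(gene_id = sim$genes$gene_id[1:3],
                      fold_A = c(0.1, 1, 1), fold_B = c(1, 1, 0.5))
    cfg <- small_cfg(seed = 3, selection = sel)
    truth <- plantInsertions(cfg, sim$genes)
    neutral <- truth$fold == 1
    expect_equal(truth$treatment_expect[neutral],
                 truth$control_expect[neutral])
    hitA <- truth$allele == "N2" &
        grepl(sel$gene_id[1], truth$gene_id, fixed = TRUE)
    if (any(hitA))
        expect_equal(truth$treatment_expect[hitA],
                     truth$control_expect[hitA] * 0.1)
    # fold applies only to the configured allele
    hitB <- truth$allele == "ED3077" &
        grepl(sel$gene_id[1], truth$gene_id, fixed = TRUE)
    if (any(hitB)) expect_true(all(truth$fold[hitB] == 1))
})

test_that("measured effects track a planted 10x depletion", {
    # a gene over ~1/5 of the chromosome; its N2 insertions are depleted
    # 10x in treatment, the rest are neutral
    genes <- GenomicRanges::GRanges("chrI", IRanges::IRanges(2000, 21000),
                                    gene_id = "gBig")
    names(genes) <- "gBig"
    cfg <- SimulationConfig(seed = 6, genomeLength = 1e5,
                            nChromosomes = 1, nGenes = 1,
                            nRoundsA = 1, nRoundsB = 1,
                            insertionsPerRound = 1200,
                            readsPerInsertion = 300, minSeparation = 0,
                            selection = data.frame(gene_id = "gBig",
                                                   fold_A = 0.1,
                                                   fold_B = 1))
    truth <- drawCounts(plantInsertions(cfg, genes,
                                        seqlens = c(chrI = 1e5)), cfg)
    iset <- truthInsertionSet(truth, cfg)
    eff <- insertionEffects(iset)
    inGene <- vapply(eff$gene_id, function(g) "gBig" %in% g, logical(1))
    isA <- eff$allele == "N2"
    measured <- eff$mean_effect[inGene & isA]
    neutral <- eff$mean_effect[!inGene & isA]
    expect_gt(length(measured), 150)
    # library-size normalization shifts all of a library's effects by a
    # common offset, which cancels in the within-allele contrast
    expect_equal(mean(measured) - mean(neutral), log2(10),
                 tolerance = 0.1)
})

test_that("emitted FASTQ is deterministic and planted decoys appear at
           their configured rates", {
    cfg <- small_cfg(seed = 4, decoyNoTagRate = 0.2)
    dir1 <- withr::local_tempdir()
    dir2 <- withr::local_tempdir()
    sim1 <- simulateExperiment(cfg, dir1)
    sim2 <- simulateExperiment(cfg, dir2)
    for (al in c("N2", "ED3077"))
        expect_identical(readLines(sim1$fastq[[al]]),
                         readLines(sim2$fastq[[al]]))

    samples <- sim1$sampleSheet
    out <- processLibrary(sim1$fastq[["N2"]], cfg@layout,
                          samples[samples$allele == "N2", ])
    st <- out$stats
    expect_equal(st$no_tag / st$input, 0.2 / 1.2, tolerance = 0.02)
    expect_equal(st$kept + st$no_tag, st$input)
})

test_that("with no decoys and no noise floor, planted junctions are
           recovered exactly from the reads", {
    cfg <- small_cfg(seed = 9)
    dir <- withr::local_tempdir()
    sim <- simulateExperiment(cfg, dir)
    truth <- sim$truthTable
    genomes <- list(N2 = sim$genome$reference,
                    ED3077 = buildPseudogenome(sim$genome$reference,
                                               sim$genome$snps))
    for (al in c("N2", "ED3077")) {
        pl <- processLibrary(sim$fastq[[al]], cfg@layout,
                             sim$sampleSheet[sim$sampleSheet$allele == al, ])
        mm <- mapFlanks(pl$reads$flank, genomes[[al]])
        expect_equal(unique(mm$status), "unique")
        got <- unique(paste(mm$chromosome, mm$junction_pos))
        want <- unique(paste(truth$chromosome, truth$position)[
            truth$allele == al &
            (truth$control_count > 0 | truth$treatment_count > 0)])
        expect_setequal(got, want)
    }
})
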