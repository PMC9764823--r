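make_genome <- function(lens, seed = 1) {
    set.seed(seed)
    g <- Biostrings::DNAStringSet(vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), ""))
    names(g) <- paste0("chr", seq_along(lens))
    g
}

test_that("buildPseudogenome substitutes exactly the SNP positions", {
    ref <- make_genome(1000, seed = 10)
    expect_equal(as.character(buildPseudogenome(ref,
        data.frame(chromosome = character(), position = integer(),
                   ref_allele = character(), alt_allele = character(),
                   quality = numeric(), depth = integer()))),
        as.character(ref))

    refStr <- as.character(ref[[1]])
    pos <- c(10L, 500L, 999L)
    refBase <- substring(refStr, pos, pos)
    altBase <- vapply(refBase, function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], "")
    snps <- data.frame(chromosome = "chr1", position = pos,
                       ref_allele = refBase, alt_allele = altBase,
                       quality = 50, depth = 30)
    pseudo <- buildPseudogenome(ref, snps)
    a <- strsplit(refStr, "")[[1]]
    b <- strsplit(as.character(pseudo[[1]]), "")[[1]]
    expect_equal(which(a != b), pos)
    expect_equal(b[pos], unname(altBase))
    expect_equal(S4Vectors::metadata(pseudo)$provenance, "pseudogenome")

    # reverse substitution restores the reference byte-exactly
    back <- buildPseudogenome(pseudo, data.frame(
        chromosome = "chr1", position = pos, ref_allele = altBase,
        alt_allele = refBase, quality = 50, depth = 30))
    expect_identical(as.character(back[[1]]), refStr)

    bad <- snps
    bad$ref_allele[2] <- altBase[2]
    expect_error(buildPseudogenome(ref, bad), "disagrees")
})

test_that("pseudogenomes preserve coordinates so gene assignment agrees", {
    ref <- make_genome(5000, seed = 11)
    set.seed(12)
    pos <- sort(sample(5000, 50))
    refBase <- substring(as.character(ref[[1]]), pos, pos)
    snps <- data.frame(chromosome = "chr1", position = pos,
                       ref_allele = refBase,
                       alt_allele = vapply(refBase, function(b)
                           sample(setdiff(c("A", "C", "G", "T"), b), 1), ""),
                       quality = 50, depth = 30)
    pseudo <- buildPseudogenome(ref, snps)
    expect_equal(names(pseudo), names(ref))
    expect_equal(Biostrings::width(pseudo), Biostrings::width(ref))
})

test_that("mapFlankUnique follows the junction coordinate convention", {
    g <- make_genome(5000, seed = 13)
    gs <- as.character(g[[1]])

    fl <- substr(gs, 1000, 1049)
    hit <- mapFlankUnique(fl, g)
    expect_equal(hit$status, "unique")
    expect_equal(hit$chromosome, "chr1")
    expect_equal(hit$strand, "+")
    expect_equal(hit$junction_pos, 1000L)

    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(substr(gs, 2000, 2049))))
    hit <- mapFlankUnique(rc, g)
    expect_equal(hit$strand, "-")
    expect_equal(hit$junction_pos, 2049L)

    # planted duplicate -> multimapped
    dup <- paste0(substr(gs, 1, 400), substr(gs, 3000, 3049),
                  substr(gs, 451, 2000), substr(gs, 3000, 3049))
    g2 <- Biostrings::DNAStringSet(c(chrA = dup))
    hit <- mapFlankUnique(substr(gs, 3000, 3049), g2)
    expect_equal(hit$status, "multimapped")

    expect_equal(mapFlankUnique(strrep("ACGT", 10), g)$status, "unmapped")
})

test_that("the exact mapper agrees with a naive all-offsets scan", {
    g <- make_genome(c(6000, 4000), seed = 14)
    gstr <- setNames(as.character(g), names(g))
    set.seed(15)
    flanks <- character(300)
    for (i in seq_along(flanks)) {
        kind <- sample(c("fwd", "rev", "random"), 1)
        chr <- sample(names(gstr), 1)
        s <- sample(nchar(gstr[[chr]]) - 60, 1)
        w <- sample(30:55, 1)
        flanks[i] <- switch(kind,
            fwd = substr(gstr[[chr]], s, s + w - 1),
            rev = as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(substr(gstr[[chr]], s,
                                                s + w - 1)))),
            random = paste(sample(c("A", "C", "G", "T"), w, TRUE),
                           collapse = ""))
    }
    res <- mapFlanks(flanks, g)
    for (i in seq_along(flanks)) {
        hits <- oracleScan(flanks[i], gstr)
        if (nrow(hits) == 0) {
            expect_equal(res$status[i], "unmapped")
        } else if (nrow(hits) == 1) {
            expect_equal(res$status[i], "unique")
            expect_equal(res$chromosome[i], hits$chromosome)
            expect_equal(res$strand[i], hits$strand)
            expect_equal(res$junction_pos[i], hits$junction)
        } else {
            expect_equal(res$status[i], "multimapped")
        }
    }
})

test_that("gene assignment respects boundaries, exclusions and overlap", {
    genes <- GenomicRanges::GRanges(
        c("chrI", "chrI", "chrII"),
        IRanges::IRanges(c(100, 150, 100), c(200, 400, 300)),
        gene_id = c("g1", "g2", "g3"))
    ids <- assignGene(c("chrI", "chrI", "chrI", "chrII", "chrI"),
                      c(150, 99, 300, 250, 175), genes)
    expect_equal(as.list(ids),
                 list(c("g1", "g2"), character(), "g2", "g3",
                      c("g1", "g2")))
    # excluded genes become intergenic
    ids <- assignGene("chrII", 250, genes, exclusions = "g3")
    expect_length(ids[[1]], 0)
    # unique-only mode drops ambiguous positions
    ids <- assignGene("chrI", 175, genes, multi = FALSE)
    expect_length(ids[[1]], 0)
})

test_that("PSL import applies identity and uniqueness filters", {
    psl <- data.frame(
        read_id = c("r1", "r2", "r2", "r3", "r4"),
        chromosome = "chrI",
        strand = c("+", "+", "+", "-", "+"),
        target_start = c(100L, 200L, 900L, 301L, 400L),
        target_end = c(150L, 250L, 950L, 350L, 450L),
        matches = c(51L, 51L, 51L, 50L, 40L),
        mismatches = c(0L, 0L, 0L, 0L, 2L),
        query_size = c(51L, 51L, 51L, 50L, 51L),
        block_count = 1L)
    out <- pslUniqueHits(psl)
    expect_equal(out$read_id, c("r1", "r3"))       # r2 multi, r4 imperfect
    expect_equal(out$junction_pos, c(100L, 350L))  # - strand: target end
})
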