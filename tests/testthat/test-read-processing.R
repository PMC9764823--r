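layout <- ReadLayout()
TAG <- transposonTag(layout)
ADAPTER <- layout@adapter3p

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("clipAdapter removes full and partial 3' adapter read-through", {
    set.seed(1)
    flank <- rand_dna(40)
    expect_equal(clipAdapter(paste0(flank, ADAPTER), layout), flank)
    expect_equal(clipAdapter(flank, layout), flank)
    # 10-nt prefix of the adapter at the read end
    expect_equal(clipAdapter(paste0(flank, substr(ADAPTER, 1, 10)),
                             layout), flank)
    # below the minimum overlap: untouched
    withTail <- paste0(flank, substr(ADAPTER, 1, 7))
    expect_equal(clipAdapter(withTail, layout), withTail)
})

test_that("clipAdapter agrees with the exhaustive suffix-prefix oracle", {
    set.seed(2)
    for (i in 1:200) {
        read <- rand_dna(sample(20:80, 1))
        k <- sample(0:41, 1)
        read <- paste0(read, substr(ADAPTER, 1, k))
        expect_equal(clipAdapter(read, layout),
                     oracleClip(read, ADAPTER, 8), info = read)
    }
})

test_that("demultiplexing trims the random prefix and matches exactly", {
    samples <- data.frame(sample_id = c("s1", "s2"),
                          barcode = c("ACGTAC", "GGGCCC"),
                          allele = "N2", round = 1L,
                          condition = c("treatment", "control"))
    out <- trimPrefixAndDemux(paste0("NNNNNN", "ACGTAC", "REST"),
                              layout, samples)
    expect_equal(out$sample_id, "s1")
    expect_equal(out$remainder, "REST")
    expect_equal(out$category, "assigned")

    # one mismatch away from s1: unassigned under exact matching
    out <- trimPrefixAndDemux(paste0("NNNNNN", "ACGTAA", "REST"),
                              layout, samples)
    expect_equal(out$category, "no_barcode")

    # but assigned under Hamming <= 1 matching
    lay1 <- ReadLayout(barcodeMaxMismatch = 1)
    out <- trimPrefixAndDemux(paste0("NNNNNN", "ACGTAA", "REST"),
                              lay1, samples)
    expect_equal(out$sample_id, "s1")

    # 11-nt read cannot contain prefix + barcode
    out <- trimPrefixAndDemux("ACGTACGTACG", layout, samples)
    expect_equal(out$category, "too_short")
})

test_that("extractFlank requires an exact tag and flags contamination", {
    set.seed(3)
    flank <- rand_dna(40)
    out <- extractFlank(paste0(TAG, flank), layout)
    expect_equal(out$flank, flank)
    expect_equal(out$category, "kept")

    mut <- paste0(substr(TAG, 1, 10), "N", substr(TAG, 12, nchar(TAG)))
    out <- extractFlank(paste0(mut, flank), layout)
    expect_equal(out$category, "no_tag")

    # tandem tag: flank taken after the FIRST occurrence still contains
    # the second tag -> rejected as contaminated
    out <- extractFlank(paste0(TAG, TAG, flank), layout)
    expect_equal(out$category, "contaminated")
})

test_that("a shorter configured tag match is honoured", {
    set.seed(4)
    flank <- rand_dna(35)
    lay <- ReadLayout(tagMatchLen = 12)
    # only the last 12 nt of the tag present
    out <- extractFlank(paste0(substr(TAG, nchar(TAG) - 11, nchar(TAG)),
                               flank), lay)
    expect_equal(out$flank, flank)
})

test_that("flank length filter keeps 30 and rejects 29", {
    expect_true(lengthFilter(strrep("A", 30), layout))
    expect_false(lengthFilter(strrep("A", 29), layout))
    expect_true(lengthFilter(strrep("A", 100), layout))
})

test_that("processLibrary accounts for every read exactly once", {
    set.seed(5)
    samples <- data.frame(sample_id = c("s1", "s2"),
                          barcode = c("ACGTAC", "GGGCCC"),
                          allele = "N2", round = 1L,
                          condition = c("treatment", "control"))
    mk <- function(barcode, tag = TAG, flankLen = 40)
        paste0(rand_dna(6), barcode, tag, rand_dna(flankLen))
    reads <- c(vapply(1:20, function(i) mk("ACGTAC"), ""),
               vapply(1:10, function(i) mk("GGGCCC"), ""),
               vapply(1:5, function(i) mk("TTTTTT"), ""),  # unknown barcode
               vapply(1:4, function(i) mk("ACGTAC", tag = rand_dna(26)), ""),
               vapply(1:3, function(i) mk("ACGTAC", flankLen = 10), ""),
               vapply(1:2, function(i) paste0(rand_dna(6), "ACGTAC",
                                              TAG, TAG, rand_dna(40)), ""),
               "ACGTACG")                                  # too short
    fq <- withr::local_tempfile(fileext = ".fq")
    writeFastq(S4Vectors::DataFrame(
        read_id = sprintf("r%02d", seq_along(reads)),
        sequence = reads, quality = strrep("I", nchar(reads))), fq)
    out <- processLibrary(fq, layout, samples)
    st <- out$stats
    expect_equal(st$input, 45L)
    expect_equal(st$kept, 30L)
    expect_equal(st$no_barcode, 5L)
    expect_equal(st$no_tag, 4L)
    expect_equal(st$short_flank, 3L)
    expect_equal(st$contaminated, 2L)
    expect_equal(st$too_short, 1L)
    expect_equal(st$kept + st$no_barcode + st$too_short + st$no_tag +
                 st$contaminated + st$short_flank, st$input)
    expect_equal(sum(out$reads$sample_id == "s1"), 20L)
    expect_true(all(out$reads$flank_len >= 30L))
    expect_false(any(grepl(TAG, out$reads$flank, fixed = TRUE)))
})

test_that("processLibrary is deterministic and handles empty input", {
    samples <- data.frame(sample_id = "s1", barcode = "ACGTAC",
                          allele = "N2", round = 1L,
                          condition = "treatment")
    fq <- withr::local_tempfile(fileext = ".fq")
    writeLines(character(), fq)
    out <- processLibrary(fq, layout, samples)
    expect_equal(out$stats$input, 0L)
    expect_equal(nrow(out$reads), 0L)

    set.seed(6)
    reads <- S4Vectors::DataFrame(
        read_id = sprintf("r%d", 1:30),
        sequence = vapply(1:30, function(i)
            paste0(rand_dna(6), "ACGTAC", TAG, rand_dna(45)), ""),
        quality = strrep("I", 83))
    writeFastq(reads, fq)
    a <- processLibrary(fq, layout, samples)
    b <- processLibrary(fq, layout, samples)
    expect_identical(as.data.frame(a$reads), as.data.frame(b$reads))
    expect_identical(a$stats, b$stats)
})
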