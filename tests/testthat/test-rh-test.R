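test_that("tunicamycinEffect computes log2 control/treatment with the
           pseudo-abundance rule", {
    expect_equal(tunicamycinEffect(4e-6, 1e-6), 2)
    expect_equal(tunicamycinEffect(0.5, 0.5), 0)
    # zero treatment observation: abundance replaced by 1
    expect_equal(tunicamycinEffect(8, 0), 3)
    expect_equal(tunicamycinEffect(5e-5, 0,
                                   controlCount = 10, treatmentCount = 0),
                 log2(5e-5))
    # zero rule keys on the raw count, not the normalized abundance
    expect_equal(tunicamycinEffect(2, 0.25,
                                   controlCount = 20, treatmentCount = 5),
                 3)
})

test_that("swapping conditions negates every effect exactly", {
    set.seed(30)
    ctl <- rpois(100, 40); trt <- rpois(100, 40)
    ca <- ctl / sum(ctl); ta <- trt / sum(trt)
    fwd <- tunicamycinEffect(ca, ta, ctl, trt)
    rev <- tunicamycinEffect(ta, ca, trt, ctl)
    expect_equal(fwd, -rev)
})

test_that("averageAcrossRounds is the arithmetic mean and rejects empties", {
    expect_equal(averageAcrossRounds(2), 2)
    expect_equal(averageAcrossRounds(c(1, 3)), 2)
    expect_equal(averageAcrossRounds(c(-1, 1)), 0)
    expect_error(averageAcrossRounds(numeric()), "no per-round")
})

test_that("mannWhitneyTest reproduces exact worked cases", {
    out <- mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))
    expect_equal(out$U, 0)
    expect_equal(out$p.value, 0.1)

    out <- mannWhitneyTest(1, 2)
    expect_equal(out$p.value, 1)

    x <- c(1.5, 2.5, 3.5)
    out <- mannWhitneyTest(x, x)
    expect_equal(out$U, length(x)^2 / 2)
    expect_equal(out$p.value, 1)

    expect_error(mannWhitneyTest(numeric(), 1), "non-empty")
})

test_that("exact branch agrees with full-enumeration and wilcox oracles", {
    set.seed(31)
    for (i in 1:80) {
        n <- sample(1:5, 1); m <- sample(1:5, 1)
        v <- sample(seq(0.1, 99.9, by = 0.1), n + m)  # distinct values
        x <- v[seq_len(n)]; y <- v[-seq_len(n)]
        got <- mannWhitneyTest(x, y)
        expect_equal(got$p.value, oracleMannWhitneyP(x, y))
        w <- wilcox.test(x, y, exact = TRUE)
        expect_equal(got$U, unname(w$statistic))
        expect_equal(got$p.value, w$p.value)
    }
})

test_that("approximate branch matches the tie-corrected continuity-corrected
           normal approximation", {
    set.seed(32)
    for (i in 1:40) {
        n <- sample(6:30, 1); m <- sample(6:30, 1)
        x <- sample(1:15, n, replace = TRUE)   # heavy ties
        y <- sample(1:15, m, replace = TRUE) + sample(0:3, 1)
        got <- mannWhitneyTest(x, y)
        w <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                          correct = TRUE))
        expect_equal(got$U, unname(w$statistic))
        expect_equal(got$p.value, w$p.value, tolerance = 1e-12)
    }
})

test_that("bhAdjust matches the independent step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

    set.seed(33)
    for (i in 1:100) {
        p <- runif(sample(1:200, 1))
        expect_equal(bhAdjust(p), oracleBH(p))
    }
})

make_effects <- function(df) {
    S4Vectors::DataFrame(
        chromosome = "chrI", position = seq_len(nrow(df)),
        allele = df$allele,
        gene_id = as(as.list(df$gene), "CharacterList"),
        round_effects = as(as.list(df$eff), "NumericList"),
        n_rounds = 1L, mean_effect = df$eff)
}

test_that("runGeneTests reproduces the toy reciprocal hemizygosity case", {
    df <- data.frame(
        gene = "g1",
        allele = rep(c("N2", "ED3077"), each = 3),
        eff = c(1.0, 1.2, 0.9, -1.1, -0.8, -1.0))
    res <- runGeneTests(make_effects(df), alleles = c("N2", "ED3077"))
    expect_equal(res$gene, "g1")
    expect_equal(res$p_value, 0.1)
    expect_equal(res$q_value, 0.1)
    expect_equal(res$n_insertions_A, 3L)
    expect_equal(res$n_insertions_B, 3L)
    expect_equal(res$direction, "N2_promotes")
})

test_that("genes lacking insertions in one allele are untested", {
    df <- data.frame(gene = "g1", allele = "N2", eff = c(1, 2, 3))
    res <- runGeneTests(make_effects(df), alleles = c("N2", "ED3077"))
    expect_true(is.na(res$p_value))
    expect_equal(res$direction, "none")
    expect_equal(attr(res, "n_tested"), 0L)
})

test_that("swapping allele labels preserves p and flips direction", {
    set.seed(34)
    df <- data.frame(
        gene = rep(c("g1", "g2"), each = 8),
        allele = rep(rep(c("N2", "ED3077"), each = 4), 2),
        eff = rnorm(16))
    fwd <- runGeneTests(make_effects(df), alleles = c("N2", "ED3077"))
    swp <- df; swp$allele <- ifelse(df$allele == "N2", "ED3077", "N2")
    rev <- runGeneTests(make_effects(swp), alleles = c("ED3077", "N2"))
    expect_equal(fwd$p_value, rev$p_value[match(fwd$gene, rev$gene)])
    ## the same underlying insertions now carry the other label, so the
    ## reported direction flips accordingly
    flip <- c(N2_promotes = "ED3077_promotes",
              ED3077_promotes = "N2_promotes", none = "none")
    expect_equal(unname(flip[fwd$direction]),
                 rev$direction[match(fwd$gene, rev$gene)])
})

test_that("condition swap (negated effects) preserves two-tailed p", {
    set.seed(35)
    df <- data.frame(
        gene = rep("g1", 10),
        allele = rep(c("N2", "ED3077"), each = 5),
        eff = rnorm(10))
    neg <- df; neg$eff <- -df$eff
    a <- runGeneTests(make_effects(df), alleles = c("N2", "ED3077"))
    b <- runGeneTests(make_effects(neg), alleles = c("N2", "ED3077"))
    expect_equal(a$p_value, b$p_value)
})

test_that("multi-gene insertions contribute to every overlapping gene", {
    eff <- S4Vectors::DataFrame(
        chromosome = "chrI", position = 1:4,
        allele = c("N2", "N2", "ED3077", "ED3077"),
        gene_id = as(list(c("g1", "g2"), c("g1", "g2"), "g1", "g1"),
                     "CharacterList"),
        round_effects = as(as.list(1:4), "NumericList"),
        n_rounds = 1L, mean_effect = c(2, 2.5, -1, -1.5))
    res <- runGeneTests(eff, alleles = c("N2", "ED3077"))
    expect_equal(res$n_insertions_A[res$gene == "g1"], 2L)
    expect_equal(res$n_insertions_A[res$gene == "g2"], 2L)
    expect_equal(res$n_insertions_B[res$gene == "g2"], 0L)
    expect_equal(attr(res, "n_tested"), 1L)
})
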