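## Per-insertion selection effects and the per-gene reciprocal
## hemizygosity test.

#' Per-insertion treatment effect (log2 control/treatment)
#'
#' The tunicamycin effect of an insertion in one round is the log2 ratio
#' of its normalized abundance in the control library over the treatment
#' library; positive values mean depletion under the drug. Whenever the
#' raw read count on either side is zero, that side's abundance is
#' replaced by `pseudoAbundance` (default 1) before forming the ratio, so
#' the ratio is always finite. Swapping the two conditions negates the
#' effect exactly.
#'
#' @param controlAbundance,treatmentAbundance normalized abundances.
#' @param controlCount,treatmentCount raw read counts used to detect
#'   zero observations; when omitted, a zero abundance counts as a zero
#'   observation.
#' @param pseudoAbundance replacement abundance for zero observations.
#' @return numeric vector of effects.
#' @examples
#' tunicamycinEffect(4e-6, 1e-6)   # 2
#' @export
tunicamycinEffect <- function(controlAbundance, treatmentAbundance,
                              controlCount = NULL, treatmentCount = NULL,
                              pseudoAbundance = 1) {
    if (is.null(controlCount)) controlCount <- controlAbundance
    if (is.null(treatmentCount)) treatmentCount <- treatmentAbundance
    stopifnot(all(controlAbundance >= 0), all(treatmentAbundance >= 0))
    ctl <- ifelse(controlCount == 0, pseudoAbundance, controlAbundance)
    trt <- ifelse(treatmentCount == 0, pseudoAbundance, treatmentAbundance)
    log2(ctl / trt)
}

#' Average an insertion's effect across rounds
#'
#' Insertions detected in multiple mutagenesis rounds get the arithmetic
#' mean of their per-round effects.
#'
#' @param effects numeric vector of per-round effects (non-empty).
#' @return the mean effect.
#' @export
averageAcrossRounds <- function(effects) {
    if (length(effects) == 0L)
        stop("no per-round effects to average")
    mean(effects)
}

#' Per-insertion effects from an InsertionSet
#'
#' Computes, for each insertion, the per-round effect in every round where
#' the insertion was detected (non-zero raw count in at least one of that
#' round's two condition libraries), applies the zero-observation
#' pseudo-abundance rule, and averages across the observed rounds.
#'
#' @param iset an [InsertionSet-class], gene-annotated via [assignGenes()].
#' @param pseudoAbundance see [tunicamycinEffect()].
#' @return a [S4Vectors::DataFrame] with one row per insertion:
#'   `chromosome`, `position`, `allele`, `gene_id` (CharacterList),
#'   `round_effects` (NumericList), `n_rounds`, `mean_effect`. Insertions
#'   never detected in a complete round pair are dropped.
#' @export
insertionEffects <- function(iset, pseudoAbundance = 1) {
    counts <- assay(iset, "counts")
    abund <- assay(iset, "abundance")
    cd <- colData(iset)
    n <- nrow(iset)
    roundEff <- vector("list", n)
    for (al in unique(cd$allele)) {
        rsel <- which(rowData(iset)$allele == al)
        if (!length(rsel)) next
        for (r in sort(unique(cd$round[cd$allele == al]))) {
            ctl <- which(cd$allele == al & cd$round == r &
                         cd$condition == "control")
            trt <- which(cd$allele == al & cd$round == r &
                         cd$condition == "treatment")
            if (length(ctl) != 1L || length(trt) != 1L) next
            seen <- rsel[counts[rsel, ctl] > 0 | counts[rsel, trt] > 0]
            if (!length(seen)) next
            eff <- tunicamycinEffect(abund[seen, ctl], abund[seen, trt],
                                     counts[seen, ctl], counts[seen, trt],
                                     pseudoAbundance = pseudoAbundance)
            for (kk in seq_along(seen))
                roundEff[[seen[kk]]] <- c(roundEff[[seen[kk]]], eff[kk])
        }
    }
    keep <- which(lengths(roundEff) > 0L)
    gene <- if (!is.null(rowData(iset)$gene_id))
        rowData(iset)$gene_id[keep]
    else as(rep(list(character()), length(keep)), "CharacterList")
    DataFrame(
        chromosome = as.character(seqnames(rowRanges(iset)))[keep],
        position = start(rowRanges(iset))[keep],
        allele = rowData(iset)$allele[keep],
        gene_id = gene,
        round_effects = as(roundEff[keep], "NumericList"),
        n_rounds = lengths(roundEff[keep]),
        mean_effect = vapply(roundEff[keep], averageAcrossRounds,
                             numeric(1)),
        row.names = names(rowRanges(iset))[keep])
}

#' Two-sample two-tailed Mann-Whitney test
#'
#' Computes the Mann-Whitney U statistic for the first sample (rank sum
#' with midranks for ties) and a two-tailed p-value. For small samples
#' (`n + m <= exactThreshold`, default 10) without ties, the p-value is
#' computed by exhaustive enumeration of all `choose(n + m, n)` group
#' assignments; otherwise by normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exactThreshold maximum `n + m` for the exact enumeration.
#' @return a list with `U` (statistic for `x`) and `p.value`.
#' @examples
#' mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))   # U = 0, p = 0.1
#' @export
mannWhitneyTest <- function(x, y, exactThreshold = 10L) {
    n <- length(x); m <- length(y)
    if (n == 0L || m == 0L) stop("both samples must be non-empty")
    v <- c(x, y)
    rk <- rank(v)
    U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
    ties <- anyDuplicated(v) > 0L
    if (!ties && n + m <= exactThreshold) {
        ## exact: enumerate every assignment of n ranks to sample x
        combs <- combn(n + m, n)
        Us <- colSums(matrix(rk[combs], nrow = n)) - n * (n + 1) / 2
        lo <- min(U, n * m - U)
        hi <- max(U, n * m - U)
        p <- min(1, (sum(Us <= lo) + sum(Us >= hi)) / ncol(combs))
    } else {
        N <- n + m
        tieTab <- table(v)
        sigma2 <- n * m / 12 * ((N + 1) -
            sum(tieTab^3 - tieTab) / (N * (N - 1)))
        if (sigma2 <= 0) return(list(U = U, p.value = 1))
        z0 <- U - n * m / 2
        z <- (z0 - sign(z0) * 0.5) / sqrt(sigma2)   # continuity correction
        p <- min(1, 2 * min(pnorm(z), 1 - pnorm(z)))
    }
    list(U = U, p.value = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate control across the per-gene tests;
#' order-preserving with the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values parallel to `p`.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Per-gene reciprocal hemizygosity tests
#'
#' For every gene, collects the round-averaged effects of all insertions
#' disrupting its A allele and its B allele (across all rounds), and, when
#' both sets have at least `minPerAllele` insertions, compares them with a
#' two-tailed Mann-Whitney test; q-values are Benjamini-Hochberg adjusted
#' across all tested genes. The reported direction names the allele whose
#' disruption causes the stronger depletion under treatment: hemizygotes
#' left with only the other allele do worse, so the named allele is the
#' resistance-promoting one.
#'
#' @param effects per-insertion effects from [insertionEffects()].
#' @param alleles length-2 character giving the (A, B) allele labels; the
#'   default takes the order of first appearance in `effects$allele`.
#' @param minPerAllele minimum insertions per allele for a gene to be
#'   tested (default 2); untested genes are reported with NA statistics.
#' @param exactThreshold passed to [mannWhitneyTest()].
#' @return a data.frame sorted by p-value (untested genes last):
#'   `gene`, `n_insertions_A`, `n_insertions_B`, `mean_effect_A`,
#'   `mean_effect_B`, `U`, `p_value`, `q_value`, `direction`.
#' @export
runGeneTests <- function(effects, alleles = NULL, minPerAllele = 2L,
                         exactThreshold = 10L) {
    if (is.null(alleles)) alleles <- unique(effects$allele)
    stopifnot(length(alleles) == 2L)
    ## one (insertion, gene) pair per row; multi-gene insertions
    ## contribute to every overlapping gene's test
    nG <- lengths(effects$gene_id)
    idx <- rep(seq_len(nrow(effects)), nG)
    gene <- unlist(effects$gene_id, use.names = FALSE)
    eff <- effects$mean_effect[idx]
    allele <- effects$allele[idx]
    genes <- sort(unique(gene))
    res <- data.frame(gene = genes,
                      n_insertions_A = 0L, n_insertions_B = 0L,
                      mean_effect_A = NA_real_, mean_effect_B = NA_real_,
                      U = NA_real_, p_value = NA_real_,
                      q_value = NA_real_, direction = "none",
                      stringsAsFactors = FALSE)
    effA <- split(eff[allele == alleles[1L]], gene[allele == alleles[1L]])
    effB <- split(eff[allele == alleles[2L]], gene[allele == alleles[2L]])
    for (i in seq_along(genes)) {
        g <- genes[i]
        ea <- effA[[g]]; eb <- effB[[g]]
        res$n_insertions_A[i] <- length(ea)
        res$n_insertions_B[i] <- length(eb)
        if (length(ea)) res$mean_effect_A[i] <- mean(ea)
        if (length(eb)) res$mean_effect_B[i] <- mean(eb)
        if (length(ea) >= minPerAllele && length(eb) >= minPerAllele) {
            mw <- mannWhitneyTest(ea, eb, exactThreshold = exactThreshold)
            res$U[i] <- mw$U
            res$p_value[i] <- mw$p.value
            res$direction[i] <- if (mean(ea) > mean(eb))
                paste0(alleles[1L], "_promotes")
            else if (mean(eb) > mean(ea)) paste0(alleles[2L], "_promotes")
            else "none"
        }
    }
    tested <- !is.na(res$p_value)
    res$q_value[tested] <- bhAdjust(res$p_value[tested])
    res <- res[order(res$p_value, res$gene, na.last = TRUE), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "n_tested") <- sum(tested)
    attr(res, "min_per_allele") <- minPerAllele
    res
}
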