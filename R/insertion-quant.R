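## Collapse mapped junction reads into insertion sites and quantify them.

#' Collapse junction positions into insertion-site clusters
#'
#' Single-linkage clustering on one chromosome of one library: after
#' sorting, adjacent positions no more than `window` bp apart join the
#' same cluster (so a chain 0-90-180 merges even though its ends are more
#' than `window` apart — the only order-independent reading of "within
#' `window` bp of each other"). Each cluster is reported at its modal
#' position — the member with the most reads, ties broken towards the
#' lowest coordinate — with the summed count, so total counts are
#' conserved.
#'
#' @param positions integer vector of junction positions (one chromosome,
#'   one library).
#' @param counts read counts parallel to `positions`.
#' @param rule a [ClusterRule-class].
#' @return a data.frame with `position` (modal) and `count` (cluster sum),
#'   ordered by position.
#' @examples
#' collapsePositions(c(100, 150, 300), c(5, 10, 2))
#' @export
collapsePositions <- function(positions, counts, rule = ClusterRule()) {
    stopifnot(length(positions) == length(counts))
    if (length(positions) == 0L)
        return(data.frame(position = integer(), count = numeric()))
    if (anyDuplicated(positions)) {
        agg <- rowsum(as.numeric(counts), positions)
        positions <- as.integer(rownames(agg))
        counts <- as.numeric(agg[, 1L])
    }
    ord <- order(positions)
    p <- positions[ord]
    k <- counts[ord]
    cl <- cumsum(c(1L, as.integer(diff(p) > rule@window)))
    ## modal member: max count, ties -> lowest coordinate (p sorted asc)
    modal <- vapply(split(seq_along(p), cl), function(i)
        p[i][which.max(k[i])], numeric(1))
    total <- vapply(split(k, cl), sum, numeric(1))
    data.frame(position = as.integer(modal), count = total,
               row.names = NULL)
}

#' Normalize insertion counts by library size
#'
#' Divides each raw count by the library's total read count and multiplies
#' by `scale` (default 1, a pure fraction; set e.g. `1e6` for a
#' counts-per-million scale).
#'
#' @param counts numeric vector/matrix of raw counts.
#' @param libraryTotal total reads in the library (scalar, or one per
#'   column of a matrix); must be positive.
#' @param scale scale factor (default 1).
#' @return normalized abundances, same shape as `counts`.
#' @export
normalizeAbundances <- function(counts, libraryTotal, scale = 1) {
    if (any(libraryTotal <= 0))
        stop("libraryTotal must be positive")
    if (is.matrix(counts)) {
        stopifnot(length(libraryTotal) %in% c(1L, ncol(counts)))
        sweep(counts, 2L, libraryTotal, "/") * scale
    } else {
        counts / libraryTotal * scale
    }
}

## unify per-library cluster positions of one (allele, chromosome) group:
## returns the unified modal position for each input row
.unifyPositions <- function(position, count, window) {
    up <- sort(unique(position))
    grpOfUp <- cumsum(c(1L, as.integer(diff(up) > window)))
    memberGrp <- grpOfUp[match(position, up)]
    unifiedPos <- vapply(split(seq_along(position), memberGrp),
        function(j) {
            tot <- rowsum(as.numeric(count[j]), position[j])
            as.integer(rownames(tot))[which.max(tot[, 1L])]
        }, integer(1))
    unifiedPos[match(memberGrp, sort(unique(memberGrp)))]
}

#' Build an InsertionSet from mapped junction reads
#'
#' Per library and chromosome, junction positions are collapsed with
#' [collapsePositions()]; clusters from different libraries of the same
#' allele are then unified into one insertion when their modal positions
#' fall within the same single-linkage window (the clone-identity window
#' is reused for cross-library matching). The unified insertion position
#' is the member position with the largest read count summed over
#' libraries (ties towards the lowest coordinate). Each insertion carries
#' its per-library raw count (0 where unobserved) and an abundance
#' normalized by the library's total uniquely mapped reads.
#'
#' @param mapped a data.frame/DataFrame of uniquely mapped junction reads,
#'   one row per read, with columns `sample_id`, `chromosome`,
#'   `junction_pos`.
#' @param samples sample sheet data.frame (see [readSampleSheet()]); its
#'   row order fixes the column order of the result.
#' @param rule a [ClusterRule-class].
#' @param scale normalization scale factor (see [normalizeAbundances()]).
#' @param libraryTotals optional named numeric (by sample_id): totals to
#'   normalize by; default is each library's uniquely mapped read count
#'   computed from `mapped`.
#' @return an [InsertionSet-class].
#' @export
buildInsertionSet <- function(mapped, samples, rule = ClusterRule(),
                              scale = 1, libraryTotals = NULL) {
    mapped <- as.data.frame(mapped)
    stopifnot(all(c("sample_id", "chromosome", "junction_pos") %in%
                  colnames(mapped)))
    if (!all(mapped$sample_id %in% samples$sample_id))
        stop("mapped reads reference sample_id(s) absent from the sheet")
    allele <- samples$allele[match(mapped$sample_id, samples$sample_id)]

    ## 1) per-library, per-chromosome collapse
    key <- interaction(mapped$sample_id, mapped$chromosome, drop = TRUE)
    clusters <- do.call(rbind, lapply(split(seq_len(nrow(mapped)), key),
        function(i) {
            cp <- collapsePositions(mapped$junction_pos[i],
                                    rep(1L, length(i)), rule)
            data.frame(sample_id = mapped$sample_id[i[1L]],
                       allele = allele[i[1L]],
                       chromosome = mapped$chromosome[i[1L]],
                       position = cp$position, count = cp$count,
                       stringsAsFactors = FALSE)
        }))
    rownames(clusters) <- NULL

    ## 2) cross-library unification per (allele, chromosome)
    ukey <- interaction(clusters$allele, clusters$chromosome, drop = TRUE)
    clusters$u_position <- NA_integer_
    for (i in split(seq_len(nrow(clusters)), ukey))
        clusters$u_position[i] <- .unifyPositions(clusters$position[i],
                                                  clusters$count[i],
                                                  rule@window)

    ## 3) insertion x library count matrix (absent observations = 0)
    alleleLevels <- unique(samples$allele)
    rows <- unique(clusters[, c("allele", "chromosome", "u_position")])
    rows <- rows[order(match(rows$allele, alleleLevels), rows$chromosome,
                       rows$u_position), , drop = FALSE]
    rowKey <- paste(rows$allele, rows$chromosome, rows$u_position)
    counts <- matrix(0, nrow = nrow(rows), ncol = nrow(samples),
                     dimnames = list(rowKey, samples$sample_id))
    ri <- match(paste(clusters$allele, clusters$chromosome,
                      clusters$u_position), rowKey)
    ci <- match(clusters$sample_id, samples$sample_id)
    for (j in seq_len(nrow(clusters)))
        counts[ri[j], ci[j]] <- counts[ri[j], ci[j]] + clusters$count[j]

    if (is.null(libraryTotals)) {
        tt <- table(factor(mapped$sample_id, levels = samples$sample_id))
        libraryTotals <- setNames(as.numeric(tt), samples$sample_id)
    } else {
        libraryTotals <- libraryTotals[samples$sample_id]
    }
    ## a library with no mapped reads has all-zero counts; give it a unit
    ## denominator so its (all-zero) abundances stay defined
    zero <- libraryTotals == 0
    if (any(zero)) {
        message(sum(zero), " library(ies) with no mapped reads")
        libraryTotals[zero] <- 1
    }
    abundance <- normalizeAbundances(counts, libraryTotals, scale = scale)

    rr <- GRanges(rows$chromosome,
                  IRanges(rows$u_position, width = 1L),
                  allele = rows$allele)
    names(rr) <- rowKey
    cd <- DataFrame(samples, total_reads = as.numeric(libraryTotals),
                    row.names = samples$sample_id)
    se <- SummarizedExperiment(
        assays = list(counts = counts, abundance = abundance),
        rowRanges = rr, colData = cd)
    metadata(se)$scale <- scale
    metadata(se)$window <- rule@window
    metadata(se)$alleles <- alleleLevels
    new("InsertionSet", se)
}

#' Annotate an InsertionSet with gene assignments
#'
#' Adds a `gene_id` CharacterList column to `rowData` via [assignGene()].
#'
#' @param iset an [InsertionSet-class].
#' @param genes gene models ([readGff3Genes()]).
#' @param exclusions gene_ids to treat as intergenic (annotation
#'   ambiguities etc.).
#' @param multi assign insertions inside overlapping genes to all of them.
#' @return the annotated InsertionSet.
#' @export
assignGenes <- function(iset, genes, exclusions = character(),
                        multi = TRUE) {
    rowData(iset)$gene_id <- assignGene(
        as.character(seqnames(rowRanges(iset))), start(rowRanges(iset)),
        genes, exclusions = exclusions, multi = multi)
    iset
}

#' Keep only genic insertions
#'
#' @param iset an [InsertionSet-class] annotated by [assignGenes()].
#' @return the subset of insertions assigned to at least one gene.
#' @export
genicFilter <- function(iset) {
    if (is.null(rowData(iset)$gene_id))
        stop("run assignGenes() first")
    iset[lengths(rowData(iset)$gene_id) > 0L, ]
}

#' Long-format per-round insertion table
#'
#' One row per (insertion, round) in which the insertion was detected in
#' either condition, with both condition counts side by side (the on-disk
#' schema of [writeInsertionTable()]). Multi-gene assignments are
#' comma-joined; unassigned insertions are reported as `intergenic`.
#'
#' @param iset an [InsertionSet-class].
#' @param assay `"counts"` (default) or `"abundance"`.
#' @return a data.frame with columns `gene`, `chromosome`, `position`,
#'   `allele`, `control_count`, `treatment_count`, `round`.
#' @export
insertionTable <- function(iset, assay = "counts") {
    a <- assay(iset, assay)
    raw <- assay(iset, "counts")
    cd <- colData(iset)
    gene <- if (!is.null(rowData(iset)$gene_id)) {
        g <- vapply(rowData(iset)$gene_id, paste, "", collapse = ",")
        ifelse(g == "", "intergenic", g)
    } else rep("intergenic", nrow(iset))
    out <- list()
    for (al in metadata(iset)$alleles) {
        rsel <- which(rowData(iset)$allele == al)
        for (r in sort(unique(cd$round[cd$allele == al]))) {
            ctl <- which(cd$allele == al & cd$round == r &
                         cd$condition == "control")
            trt <- which(cd$allele == al & cd$round == r &
                         cd$condition == "treatment")
            if (length(ctl) != 1L || length(trt) != 1L) next
            seen <- rsel[raw[rsel, ctl] > 0 | raw[rsel, trt] > 0]
            if (!length(seen)) next
            out[[length(out) + 1L]] <- data.frame(
                gene = gene[seen],
                chromosome = as.character(seqnames(rowRanges(iset)))[seen],
                position = start(rowRanges(iset))[seen],
                allele = al,
                control_count = a[seen, ctl],
                treatment_count = a[seen, trt],
                round = r,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(gene = character(), chromosome = character(),
                          position = integer(), allele = character(),
                          control_count = numeric(),
                          treatment_count = numeric(), round = integer()))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' @describeIn InsertionSet-class summary of insertions and libraries.
#' @param object the object to display.
#' @export
setMethod("show", "InsertionSet", function(object) {
    cat(sprintf("InsertionSet: %d insertion(s) x %d library(ies)\n",
                nrow(object), ncol(object)))
    tab <- table(rowData(object)$allele)
    cat("  insertions per allele:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    if (!is.null(rowData(object)$gene_id))
        cat(sprintf("  genic: %d\n",
                    sum(lengths(rowData(object)$gene_id) > 0L)))
    cat(sprintf("  normalization scale: %s\n",
                format(metadata(object)$scale)))
})
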