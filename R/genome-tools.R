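## Pseudogenome construction, exact unique flank mapping, gene assignment.

#' Build a SNP-substituted pseudogenome
#'
#' Replaces the reference base with the alternate allele at every SNP
#' position, preserving chromosome names and lengths (substitution only,
#' no indels), so gene annotations apply unchanged to both genomes. Every
#' SNP's `ref_allele` must match the reference base at its position;
#' mismatches are a hard error listing the offending positions.
#' Substituting alt back to ref on the result recovers the reference
#' exactly.
#'
#' @param reference a named [Biostrings::DNAStringSet] (one entry per
#'   chromosome).
#' @param snps data.frame as returned by [readVcfSnps()].
#' @return a [Biostrings::DNAStringSet] with `metadata()$provenance ==
#'   "pseudogenome"`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chrI = "ACGTACGT"))
#' snps <- data.frame(chromosome = "chrI", position = 3,
#'                    ref_allele = "G", alt_allele = "T",
#'                    quality = 60, depth = 30)
#' as.character(buildPseudogenome(ref, snps))
#' @export
buildPseudogenome <- function(reference, snps) {
    out <- reference
    if (nrow(snps) > 0L) {
        bad <- !snps$chromosome %in% names(reference)
        if (any(bad))
            stop("SNP chromosome(s) absent from reference: ",
                 paste(unique(snps$chromosome[bad]), collapse = ", "))
        for (chr in unique(snps$chromosome)) {
            s <- snps[snps$chromosome == chr, , drop = FALSE]
            if (any(s$position < 1L | s$position > width(reference[chr])))
                stop("SNP position out of range on ", chr)
            chrStr <- as.character(reference[[chr]])
            have <- substring(chrStr, s$position, s$position)
            mism <- have != s$ref_allele
            if (any(mism))
                stop("SNP ref allele disagrees with reference at: ",
                     paste(sprintf("%s:%d (ref %s, vcf %s)", chr,
                                   s$position[mism], have[mism],
                                   s$ref_allele[mism])[seq_len(min(10,
                                   sum(mism)))], collapse = ", "))
            out[[chr]] <- replaceLetterAt(out[[chr]], s$position,
                                          paste(s$alt_allele, collapse = ""))
        }
    }
    metadata(out)$provenance <- "pseudogenome"
    out
}

#' Map genomic flanks by exact unique full-length matching
#'
#' The built-in mapper searches each flank as an exact full-length
#' substring of the genome on both strands (forward flank, and
#' reverse-complemented flank). A flank with exactly one hit genome-wide is
#' mapped; zero hits is `"unmapped"`; two or more hits (across positions,
#' chromosomes and strands) is `"multimapped"` and discarded downstream.
#' The junction coordinate is the genomic position of the flank's first
#' base in read orientation: the alignment start on the + strand, the
#' alignment end on the - strand.
#'
#' @param flanks character vector of flank sequences (A/C/G/T; anything
#'   else is unmappable).
#' @param genome a named [Biostrings::DNAStringSet].
#' @return a data.frame aligned with `flanks`: `status` ("unique",
#'   "unmapped", "multimapped"), `chromosome`, `strand`, `junction_pos`,
#'   `aligned_len` (NA unless unique).
#' @export
mapFlanks <- function(flanks, genome) {
    n <- length(flanks)
    res <- data.frame(status = rep("unmapped", n),
                      chromosome = NA_character_,
                      strand = NA_character_,
                      junction_pos = NA_integer_,
                      aligned_len = NA_integer_,
                      stringsAsFactors = FALSE)
    mappable <- grepl("^[ACGT]+$", flanks)
    uf <- unique(flanks[mappable])
    if (length(uf) == 0L) return(res)

    nh <- setNames(integer(length(uf)), uf)
    first <- setNames(vector("list", length(uf)), uf)

    widths <- nchar(uf)
    for (w in unique(widths)) {
        grp <- uf[widths == w]
        fset <- DNAStringSet(grp)
        rset <- reverseComplement(fset)
        ## PDict (Aho-Corasick) pays a fixed construction cost; plain
        ## matchPattern is cheaper for a handful of patterns
        usePDict <- length(grp) >= 8L
        if (usePDict) {
            pdFwd <- PDict(fset)
            pdRev <- PDict(rset)
        }
        for (chr in names(genome)) {
            subj <- genome[[chr]]
            if (usePDict) {
                sF <- startIndex(matchPDict(pdFwd, subj))
                sR <- startIndex(matchPDict(pdRev, subj))
            } else {
                sF <- lapply(seq_along(grp), function(i)
                    start(matchPattern(fset[[i]], subj)))
                sR <- lapply(seq_along(grp), function(i)
                    start(matchPattern(rset[[i]], subj)))
            }
            for (i in seq_along(grp)) {
                f <- grp[i]
                stF <- sF[[i]]
                stR <- sR[[i]]
                k <- length(stF) + length(stR)
                if (k == 0L) next
                if (nh[[f]] == 0L) {
                    ## record the first hit found (only used if unique)
                    if (length(stF)) {
                        first[[f]] <- list(chr = chr, strand = "+",
                                           pos = stF[1L])
                    } else {
                        first[[f]] <- list(chr = chr, strand = "-",
                                           pos = stR[1L] + w - 1L)
                    }
                }
                nh[[f]] <- nh[[f]] + k
            }
        }
    }

    idx <- match(flanks, uf)
    status <- rep("unmapped", n)
    status[mappable & !is.na(idx) & nh[idx] == 1L] <- "unique"
    status[mappable & !is.na(idx) & nh[idx] >= 2L] <- "multimapped"
    res$status <- status
    uq <- which(status == "unique")
    if (length(uq)) {
        hit <- first[idx[uq]]
        res$chromosome[uq] <- vapply(hit, `[[`, "", "chr")
        res$strand[uq] <- vapply(hit, `[[`, "", "strand")
        res$junction_pos[uq] <- vapply(hit, function(h)
            as.integer(h$pos), integer(1))
        res$aligned_len[uq] <- nchar(flanks[uq])
    }
    res
}

#' @rdname mapFlanks
#' @param flank a single flank sequence.
#' @return `mapFlankUnique()` returns a one-row data.frame (same columns).
#' @export
mapFlankUnique <- function(flank, genome) {
    stopifnot(length(flank) == 1L)
    mapFlanks(flank, genome)
}

#' Filter externally produced PSL alignments to unique perfect hits
#'
#' Alternative to the built-in mapper: accepts a table of BLAT alignments
#' (see [readPsl()]) and applies the same rules — 100% identity over the
#' full query, single-block, and genome-wide uniqueness; reads with more
#' than one perfect hit are discarded as multimapped. Junction coordinates
#' follow the built-in convention (+ strand: target start; - strand:
#' target end).
#'
#' @param psl data.frame from [readPsl()].
#' @return a data.frame with `read_id`, `chromosome`, `strand`,
#'   `junction_pos`, `aligned_len` — one row per uniquely mapped read.
#' @export
pslUniqueHits <- function(psl) {
    perfect <- psl$mismatches == 0L & psl$matches == psl$query_size &
        psl$block_count == 1L
    p <- psl[perfect, , drop = FALSE]
    multi <- unique(p$read_id[duplicated(p$read_id)])
    p <- p[!p$read_id %in% multi, , drop = FALSE]
    data.frame(read_id = p$read_id,
               chromosome = p$chromosome,
               strand = p$strand,
               junction_pos = ifelse(p$strand == "+", p$target_start,
                                     p$target_end),
               aligned_len = p$query_size,
               stringsAsFactors = FALSE)
}

#' Assign insertion positions to genes
#'
#' An insertion is genic when its junction position falls within a gene
#' body ([start, end], introns included). Positions inside excluded genes
#' are intergenic. A position inside several overlapping genes is, by
#' default, assigned to all of them (each can be tested); set
#' `multi = FALSE` to keep only positions inside exactly one gene.
#'
#' @param chromosome,position vectors of junction coordinates.
#' @param genes [GenomicRanges::GRanges] from [readGff3Genes()].
#' @param exclusions character vector of gene_ids to treat as intergenic.
#' @param multi assign a position to all overlapping genes (default TRUE).
#' @return an [IRanges::CharacterList] parallel to the input; empty
#'   elements are intergenic.
#' @export
assignGene <- function(chromosome, position, genes,
                       exclusions = character(), multi = TRUE) {
    stopifnot(length(chromosome) == length(position))
    keep <- !genes$gene_id %in% exclusions
    g <- genes[keep]
    q <- GRanges(chromosome, IRanges(position, width = 1L))
    ov <- findOverlaps(q, g, ignore.strand = TRUE)
    ids <- unname(S4Vectors::splitAsList(g$gene_id[subjectHits(ov)],
        factor(queryHits(ov), levels = seq_along(q))))
    ids <- as(ids, "CharacterList")
    if (!multi) {
        l <- as.list(ids)
        l[lengths(l) > 1L] <- list(character())
        ids <- as(l, "CharacterList")
    }
    ids
}
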