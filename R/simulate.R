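## Synthetic RH-seq experiment generator. Everything is driven by one
## SimulationConfig; the master seed fixes all randomness, stage by stage
## (seed, seed+1, ... are used for genome, planting, counts, reads).

.BASES <- c("A", "C", "G", "T")

.randomDna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

.randomDnaVec <- function(nSeq, len) {
    if (nSeq == 0L) return(character())
    m <- matrix(sample(.BASES, nSeq * len, replace = TRUE), ncol = len)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a parental genome pair with SNPs and gene models
#'
#' Generates a uniform-random reference genome split into equal-length
#' chromosomes, inter-strain SNPs drawn at `snpRate` per bp (with the
#' reference base read from the reference, so pseudogenome construction is
#' always applicable), and non-overlapping gene models placed with random
#' gaps.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `reference` ([Biostrings::DNAStringSet]), `snps`
#'   (data.frame as from [readVcfSnps()]), and `genes`
#'   ([GenomicRanges::GRanges]).
#' @export
simulateGenomePair <- function(config) {
    set.seed(config@seed)
    nChr <- config@nChromosomes
    chrLen <- as.integer(round(config@genomeLength / nChr))
    chrNames <- paste0("chr", as.character(utils::as.roman(seq_len(nChr))))
    reference <- DNAStringSet(vapply(seq_len(nChr),
        function(i) .randomDna(chrLen), character(1)))
    names(reference) <- chrNames

    ## non-overlapping genes, allocated round-robin across chromosomes
    nPerChr <- tabulate(rep(seq_len(nChr), length.out = config@nGenes),
                        nbins = nChr)
    genes <- list()
    gid <- 0L
    for (i in seq_len(nChr)) {
        ng <- nPerChr[i]
        if (ng == 0L) next
        lens <- as.integer(round(runif(ng, config@geneLengthRange[1L],
                                       config@geneLengthRange[2L])))
        free <- chrLen - sum(lens)
        if (free < ng)
            stop("infeasible gene packing on ", chrNames[i],
                 ": genes need ", sum(lens), " bp of ", chrLen)
        gaps <- diff(c(0, sort(runif(ng, 0, free))))
        starts <- as.integer(floor(cumsum(gaps))) +
            cumsum(c(0L, lens[-ng])) + 1L
        ids <- sprintf("gene%05d", gid + seq_len(ng))
        gid <- gid + ng
        genes[[i]] <- GRanges(factor(chrNames[i], levels = chrNames),
                              IRanges(starts, width = lens),
                              strand = sample(c("+", "-"), ng, TRUE),
                              gene_id = ids)
    }
    genes <- do.call(c, genes)
    genes <- genes[order(match(as.character(seqnames(genes)), chrNames),
                         start(genes))]
    names(genes) <- genes$gene_id

    ## SNPs at snpRate per bp
    snps <- list()
    for (i in seq_len(nChr)) {
        pos <- which(runif(chrLen) < config@snpRate)
        if (!length(pos)) next
        chrStr <- as.character(reference[[i]])
        ref <- substring(chrStr, pos, pos)
        alt <- vapply(ref, function(b)
            sample(setdiff(.BASES, b), 1L), character(1), USE.NAMES = FALSE)
        snps[[i]] <- data.frame(
            chromosome = chrNames[i], position = pos,
            ref_allele = ref, alt_allele = alt,
            quality = round(runif(length(pos), 30, 60), 1),
            depth = sample(20:60, length(pos), replace = TRUE),
            stringsAsFactors = FALSE)
    }
    snps <- if (length(snps)) do.call(rbind, snps) else
        data.frame(chromosome = character(), position = integer(),
                   ref_allele = character(), alt_allele = character(),
                   quality = numeric(), depth = integer())
    rownames(snps) <- NULL
    list(reference = reference, snps = snps, genes = genes)
}

## draw n positions uniformly over chromosomes (length-weighted), keeping
## `margin` bp off both ends and, if minSep > 0, at least minSep bp apart
.drawSeparatedPositions <- function(n, seqlens, minSep, margin) {
    lens <- as.numeric(seqlens) - 2 * margin
    if (any(lens <= 0)) stop("chromosomes too short for the flank margin")
    chrNames <- names(seqlens)
    if (minSep == 0L) {
        chr <- sample(chrNames, n, replace = TRUE, prob = lens)
        pos <- margin + ceiling(runif(n) * lens[match(chr, chrNames)])
        return(data.frame(chromosome = chr, position = as.integer(pos),
                          stringsAsFactors = FALSE))
    }
    capacity <- sum(floor(lens / minSep))
    if (n > 0.8 * capacity)
        stop("cannot place ", n, " junctions ", minSep,
             " bp apart on this genome")
    occ <- setNames(vector("list", length(chrNames)), chrNames)
    got <- 0L
    outChr <- character(n)
    outPos <- integer(n)
    for (iter in seq_len(200L)) {
        need <- n - got
        if (need == 0L) break
        chr <- sample(chrNames, 2L * need, replace = TRUE, prob = lens)
        pos <- margin + ceiling(runif(2L * need) * lens[match(chr,
                                                              chrNames)])
        for (cn in unique(chr)) {
            if (got == n) break
            cand <- sort(unique(as.integer(pos[chr == cn])))
            o <- occ[[cn]]
            if (length(o)) {
                k <- findInterval(cand, o)
                dLeft <- ifelse(k >= 1L, cand - o[pmax(k, 1L)], Inf)
                dRight <- ifelse(k < length(o), o[pmin(k + 1L,
                    length(o))] - cand, Inf)
                cand <- cand[dLeft >= minSep & dRight >= minSep]
            }
            if (!length(cand)) next
            keep <- cand[1L]
            last <- cand[1L]
            for (p in cand[-1L]) {
                if (p - last >= minSep) { keep <- c(keep, p); last <- p }
            }
            keep <- keep[seq_len(min(length(keep), n - got))]
            if (!length(keep)) next
            occ[[cn]] <- sort(c(o, keep))
            outChr[got + seq_along(keep)] <- cn
            outPos[got + seq_along(keep)] <- keep
            got <- got + length(keep)
        }
    }
    if (got < n)
        stop("failed to place ", n, " separated junctions after 200 ",
             "batches")
    data.frame(chromosome = outChr, position = outPos,
               stringsAsFactors = FALSE)
}

#' Plant hemizygote insertions and apply allele-specific selection
#'
#' For each parental allele and mutagenesis round, junction positions are
#' drawn uniformly over the genome (length-weighted across chromosomes,
#' keeping a flank-length margin off chromosome ends and, by default, a
#' minimum separation between junctions of the same allele so distinct
#' clones stay distinguishable after window collapsing). Each insertion
#' gets a log-normal clone-size factor; its expected control abundance is
#' `readsPerInsertion * factor`, and its expected treatment abundance is
#' the control expectation times the selection fold-change of the
#' disrupted gene's allele (1 for neutral genes and intergenic
#' insertions).
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene models (from [simulateGenomePair()]).
#' @param seqlens named chromosome lengths (defaults to equal-length
#'   chromosomes per the config).
#' @return the truth table: one row per planted insertion with
#'   `insertion_id`, `allele`, `round`, `chromosome`, `position`,
#'   `strand`, `gene_id`, `fold`, `control_expect`, `treatment_expect`.
#' @export
plantInsertions <- function(config, genes, seqlens = NULL) {
    set.seed(config@seed + 1L)
    if (is.null(seqlens)) {
        chrLen <- as.integer(round(config@genomeLength /
                                   config@nChromosomes))
        seqlens <- setNames(rep(chrLen, config@nChromosomes),
            paste0("chr", as.character(utils::as.roman(
                seq_len(config@nChromosomes)))))
    }
    sel <- config@selection
    out <- list()
    for (ai in 1:2) {
        al <- config@alleles[ai]
        nRounds <- if (ai == 1L) config@nRoundsA else config@nRoundsB
        nTot <- nRounds * config@insertionsPerRound
        posTab <- .drawSeparatedPositions(nTot, seqlens,
                                          config@minSeparation,
                                          margin = config@flankLen + 1L)
        gidList <- assignGene(posTab$chromosome, posTab$position, genes)
        gid <- vapply(gidList, function(g)
            if (length(g)) paste(g, collapse = ",") else "intergenic", "")
        fold <- rep(1, nTot)
        if (nrow(sel)) {
            foldCol <- if (ai == 1L) sel$fold_A else sel$fold_B
            for (j in seq_len(nrow(sel))) {
                hit <- vapply(gidList, function(g)
                    sel$gene_id[j] %in% g, logical(1))
                fold[hit] <- fold[hit] * foldCol[j]
            }
        }
        clone <- rlnorm(nTot, meanlog = -config@cloneSdLog^2 / 2,
                        sdlog = config@cloneSdLog)
        ctl <- config@readsPerInsertion * clone
        out[[ai]] <- data.frame(
            insertion_id = sprintf("%s_ins%06d", al, seq_len(nTot)),
            allele = al,
            round = rep(seq_len(nRounds),
                        each = config@insertionsPerRound),
            chromosome = posTab$chromosome,
            position = posTab$position,
            strand = sample(c("+", "-"), nTot, replace = TRUE),
            gene_id = gid,
            fold = fold,
            control_expect = ctl,
            treatment_expect = ctl * fold,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Draw observed read counts for a truth table
#'
#' Adds `control_count` and `treatment_count` columns by sampling the
#' configured noise model (Poisson, or negative binomial with size
#' `nbDispersion`) around the expected abundances.
#'
#' @param truth truth table from [plantInsertions()].
#' @param config a [SimulationConfig-class].
#' @return the truth table with observed count columns.
#' @export
drawCounts <- function(truth, config) {
    set.seed(config@seed + 2L)
    n <- nrow(truth)
    if (config@noiseModel == "poisson") {
        truth$control_count <- rpois(n, truth$control_expect)
        truth$treatment_count <- rpois(n, truth$treatment_expect)
    } else {
        truth$control_count <- rnbinom(n, size = config@nbDispersion,
                                       mu = truth$control_expect)
        truth$treatment_count <- rnbinom(n, size = config@nbDispersion,
                                         mu = truth$treatment_expect)
    }
    truth
}

#' Deterministic sample sheet for a simulated experiment
#'
#' One treatment and one control library per (allele, round), with
#' distinct 6-nt barcodes taken from a fixed enumeration (independent of
#' the seed).
#'
#' @param config a [SimulationConfig-class].
#' @return a sample sheet data.frame (see [readSampleSheet()]).
#' @export
makeSampleSheet <- function(config) {
    rounds <- c(config@nRoundsA, config@nRoundsB)
    rows <- list()
    k <- 0L
    for (ai in 1:2) for (r in seq_len(rounds[ai]))
        for (cond in c("treatment", "control")) {
            k <- k + 1L
            rows[[k]] <- data.frame(
                sample_id = sprintf("%s_r%02d_%s", config@alleles[ai], r,
                                    substr(cond, 1L, 1L)),
                barcode = .nthBarcode(k),
                allele = config@alleles[ai],
                round = r,
                condition = cond,
                stringsAsFactors = FALSE)
        }
    do.call(rbind, rows)
}

## k-th barcode of a fixed stride-17 walk through the 4^6 code space
.nthBarcode <- function(k, len = 6L) {
    idx <- (k * 17L) %% (4L^len)
    digits <- integer(len)
    for (i in seq_len(len)) {
        digits[i] <- idx %% 4L
        idx <- idx %/% 4L
    }
    paste(.BASES[digits + 1L], collapse = "")
}

.flankSeq <- function(truth, genome, flankLen) {
    chrStr <- setNames(as.character(genome), names(genome))
    fwd <- truth$strand == "+"
    flank <- character(nrow(truth))
    flank[fwd] <- substring(chrStr[truth$chromosome[fwd]],
                            truth$position[fwd],
                            truth$position[fwd] + flankLen - 1L)
    if (any(!fwd)) {
        rc <- substring(chrStr[truth$chromosome[!fwd]],
                        truth$position[!fwd] - flankLen + 1L,
                        truth$position[!fwd])
        flank[!fwd] <- as.character(reverseComplement(DNAStringSet(rc)))
    }
    flank
}

#' Emit raw FASTQ reads for a simulated experiment
#'
#' Writes one multiplexed FASTQ per parental allele (all rounds and both
#' conditions, distinguished by barcode) plus `samples.tsv`. Each junction
#' read is `6 random nt + barcode + transposon tag + genomic flank`, with
#' 3' adapter read-through filling the read up to `readLength`. Flanks are
#' drawn from the correct genome: insertions in the B allele flank the
#' SNP-substituted pseudogenome. Reads are emitted error-free (the exact
#' tag filter tolerates no mismatches); decoy reads without a tag, with an
#' unknown barcode, or with a sub-minimum flank are mixed in at the
#' configured rates.
#'
#' @param truth truth table with counts (see [drawCounts()]).
#' @param genomes list with one genome per allele label, e.g.
#'   `list(N2 = reference, ED3077 = pseudogenome)`.
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return list with `fastq` (named paths per allele), `samples` (sheet),
#'   `samples_path`.
#' @export
emitFastq <- function(truth, genomes, config, dir) {
    set.seed(config@seed + 3L)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    stopifnot(all(config@alleles %in% names(genomes)))
    samples <- makeSampleSheet(config)
    layout <- config@layout
    tag <- layout@transposonTag
    adapter <- layout@adapter3p
    badBarcode <- .nthBarcode(nrow(samples) + 1L)
    paths <- setNames(file.path(dir, sprintf("reads_%s.fastq",
                                             config@alleles)),
                      config@alleles)
    for (al in config@alleles) {
        tr <- truth[truth$allele == al, , drop = FALSE]
        flankIns <- .flankSeq(tr, genomes[[al]], config@flankLen)
        recs <- list()
        for (cond in c("treatment", "control")) {
            cnt <- if (cond == "treatment") tr$treatment_count else
                tr$control_count
            idx <- rep(seq_len(nrow(tr)), cnt)
            if (!length(idx)) next
            sid <- sprintf("%s_r%02d_%s", al, tr$round[idx],
                           substr(cond, 1L, 1L))
            bc <- samples$barcode[match(sid, samples$sample_id)]
            core <- paste0(.randomDnaVec(length(idx), layout@randomPrefixLen),
                           bc, tag, flankIns[idx])
            fill <- pmax(0L, pmin(config@readLength - nchar(core),
                                  nchar(adapter)))
            seqs <- substr(paste0(core, substr(adapter, 1L, max(fill))),
                           1L, config@readLength)
            recs[[cond]] <- DataFrame(
                read_id = sprintf("%s:%s:%d", tr$insertion_id[idx], cond,
                                  seq_along(idx)),
                sequence = seqs,
                quality = strrep("I", nchar(seqs)))
        }
        reads <- do.call(rbind, recs)
        nReal <- nrow(reads)
        ## decoys
        decoys <- list()
        mkDecoy <- function(n, kind) {
            if (n == 0L) return(NULL)
            bcs <- sample(samples$barcode[samples$allele == al], n,
                          replace = TRUE)
            sq <- switch(kind,
                no_tag = paste0(.randomDnaVec(n, layout@randomPrefixLen),
                                bcs, .randomDnaVec(n, config@readLength)),
                bad_barcode = paste0(.randomDnaVec(n,
                                layout@randomPrefixLen), badBarcode,
                                tag, .randomDnaVec(n, config@flankLen)),
                short_flank = paste0(.randomDnaVec(n,
                                layout@randomPrefixLen), bcs, tag,
                                .randomDnaVec(n, 10L)))
            sq <- substr(sq, 1L, config@readLength)
            DataFrame(read_id = sprintf("decoy:%s:%s:%d", al, kind,
                                        seq_len(n)),
                      sequence = sq, quality = strrep("I", nchar(sq)))
        }
        decoys$no_tag <- mkDecoy(round(config@decoyNoTagRate * nReal),
                                 "no_tag")
        decoys$bad_barcode <- mkDecoy(round(config@decoyBadBarcodeRate *
                                            nReal), "bad_barcode")
        decoys$short_flank <- mkDecoy(round(config@decoyShortFlankRate *
                                            nReal), "short_flank")
        reads <- do.call(rbind, c(list(reads),
                                  decoys[!vapply(decoys, is.null,
                                                 logical(1))]))
        writeFastq(reads, paths[[al]])
    }
    samplesPath <- file.path(dir, "samples.tsv")
    write.table(samples, samplesPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(fastq = paths, samples = samples, samples_path = samplesPath)
}

## minimal VCF 4.2 writer for simulated SNPs (QUAL + INFO DP)
writeSnpVcf <- function(snps, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=rhemiseq-simulator",
             '##INFO=<ID=DP,Number=1,Type=Integer,Description="Combined depth">',
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rows <- if (nrow(snps)) sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d",
        snps$chromosome, snps$position, snps$ref_allele, snps$alt_allele,
        format(snps$quality, trim = TRUE), snps$depth) else character()
    writeLines(c(hdr, rows), path)
    invisible(path)
}

## minimal GFF3 writer for simulated gene models
writeGeneGff3 <- function(genes, path) {
    rows <- sprintf("%s\trhemiseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    as.character(seqnames(genes)), start(genes),
                    end(genes), as.character(strand(genes)),
                    genes$gene_id)
    writeLines(c("##gff-version 3", rows), path)
    invisible(path)
}

#' Generate a complete synthetic RH-seq experiment on disk
#'
#' Runs the whole generator: genome pair, SNP VCF, gene GFF3, planted
#' insertions under selection, observed counts, multiplexed FASTQ per
#' allele, sample sheet, and the machine-readable truth table.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory.
#' @return list with all file paths (`reference`, `vcf`, `gff3`,
#'   `samples`, `fastq`, `truth`) and the in-memory objects (`genome`,
#'   `truthTable`, `sampleSheet`).
#' @export
simulateExperiment <- function(config, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sim <- simulateGenomePair(config)
    refPath <- file.path(dir, "ref.fa")
    writeXStringSet(sim$reference, refPath)
    vcfPath <- file.path(dir, "snps.vcf")
    writeSnpVcf(sim$snps, vcfPath)
    gffPath <- file.path(dir, "genes.gff3")
    writeGeneGff3(sim$genes, gffPath)

    truth <- plantInsertions(config, sim$genes)
    truth <- drawCounts(truth, config)
    pseudo <- buildPseudogenome(sim$reference, sim$snps)
    genomes <- setNames(list(sim$reference, pseudo), config@alleles)
    em <- emitFastq(truth, genomes, config, dir)

    truthPath <- file.path(dir, "truth.tsv")
    write.table(truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(reference = refPath, vcf = vcfPath, gff3 = gffPath,
         samples = em$samples_path, fastq = em$fastq, truth = truthPath,
         genome = sim, truthTable = truth, sampleSheet = em$samples)
}

#' Build an InsertionSet directly from a simulated truth table
#'
#' Count-level shortcut that bypasses read emission and mapping: each
#' planted insertion becomes one row, with its observed counts placed in
#' its (allele, round) treatment and control libraries. Useful for
#' statistical calibration studies at scales where emitting reads is
#' unnecessary.
#'
#' @param truth truth table with counts (see [drawCounts()]).
#' @param config a [SimulationConfig-class].
#' @param scale normalization scale (see [normalizeAbundances()]).
#' @return an [InsertionSet-class].
#' @export
truthInsertionSet <- function(truth, config, scale = 1) {
    samples <- makeSampleSheet(config)
    n <- nrow(truth)
    counts <- matrix(0, nrow = n, ncol = nrow(samples),
                     dimnames = list(truth$insertion_id,
                                     samples$sample_id))
    trtCol <- match(sprintf("%s_r%02d_t", truth$allele, truth$round),
                    samples$sample_id)
    ctlCol <- match(sprintf("%s_r%02d_c", truth$allele, truth$round),
                    samples$sample_id)
    counts[cbind(seq_len(n), trtCol)] <- truth$treatment_count
    counts[cbind(seq_len(n), ctlCol)] <- truth$control_count
    totals <- pmax(colSums(counts), 1)
    abundance <- normalizeAbundances(counts, totals, scale = scale)
    rr <- GRanges(truth$chromosome, IRanges(truth$position, width = 1L),
                  allele = truth$allele)
    names(rr) <- truth$insertion_id
    gl <- strsplit(truth$gene_id, ",", fixed = TRUE)
    gl[truth$gene_id == "intergenic"] <- list(character())
    se <- SummarizedExperiment(
        assays = list(counts = counts, abundance = abundance),
        rowRanges = rr,
        colData = DataFrame(samples, total_reads = as.numeric(totals),
                            row.names = samples$sample_id))
    metadata(se)$scale <- scale
    metadata(se)$alleles <- config@alleles
    iset <- new("InsertionSet", se)
    rowData(iset)$gene_id <- as(gl, "CharacterList")
    iset
}
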