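## Readers/writers for the external formats the pipeline touches.
## Internal coordinates are 1-based inclusive everywhere; conversions happen
## only at format boundaries (PSL is 0-based half-open).

#' Read a FASTQ file into a validated table of reads
#'
#' Strict 4-line-record FASTQ reader. Sequences are uppercased; a
#' sequence/quality length mismatch is a hard error naming the offending
#' record. Base qualities are carried along but never used in filtering
#' (junction reads are filtered on transposon-tag identity, not quality).
#'
#' @param path path to an uncompressed FASTQ file (phred+33).
#' @return a [S4Vectors::DataFrame] with columns `read_id`, `sequence`,
#'   `quality`; zero rows for an empty file.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "acgt", "+", "IIII"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path) {
    if (!file.exists(path)) stop("FASTQ file not found: ", path)
    lines <- readLines(path)
    if (length(lines) == 0L)
        return(DataFrame(read_id = character(), sequence = character(),
                         quality = character()))
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ (", path, "): line count ", length(lines),
             " is not a multiple of 4")
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seqs <- toupper(lines[idx + 1L])
    plus <- lines[idx + 2L]
    qual <- lines[idx + 3L]
    bad <- which(substr(hdr, 1L, 1L) != "@")
    if (length(bad))
        stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 1L,
             ": header does not start with '@'")
    bad <- which(substr(plus, 1L, 1L) != "+")
    if (length(bad))
        stop("malformed FASTQ record '", sub("^@", "", hdr[bad[1L]]),
             "': separator line does not start with '+'")
    ids <- sub("\\s.*$", "", sub("^@", "", hdr))
    bad <- which(nchar(seqs) != nchar(qual))
    if (length(bad))
        stop("malformed FASTQ record '", ids[bad[1L]],
             "': sequence and quality lengths differ (",
             nchar(seqs[bad[1L]]), " vs ", nchar(qual[bad[1L]]), ")")
    DataFrame(read_id = ids, sequence = seqs, quality = qual)
}

#' Write reads to FASTQ
#'
#' @param reads a data.frame/DataFrame with `read_id`, `sequence`, `quality`.
#' @param path output path.
#' @return invisibly, the number of records written.
#' @export
writeFastq <- function(reads, path) {
    n <- nrow(reads)
    if (n == 0L) { writeLines(character(), path); return(invisible(0L)) }
    out <- character(4L * n)
    out[seq(1L, 4L * n, 4L)] <- paste0("@", reads$read_id)
    out[seq(2L, 4L * n, 4L)] <- reads$sequence
    out[seq(3L, 4L * n, 4L)] <- "+"
    out[seq(4L, 4L * n, 4L)] <- reads$quality
    writeLines(out, path)
    invisible(n)
}

#' Read gene models from a GFF3 file
#'
#' Retains only rows of type `gene`, as annotated gene bodies (including
#' introns) are what decides whether an insertion is genic. Coordinates are
#' kept 1-based inclusive as in the file.
#'
#' @param path path to a GFF3 file.
#' @return a [GenomicRanges::GRanges] with a `gene_id` metadata column,
#'   named by gene_id.
#' @export
readGff3Genes <- function(path) {
    if (!file.exists(path)) stop("GFF3 file not found: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "gene"]
    if (length(gr) == 0L) {
        out <- GRanges()
        mcols(out)$gene_id <- character()
        return(out)
    }
    ids <- as.character(gr$ID)
    if (any(is.na(ids) | ids == ""))
        stop("GFF3 gene row(s) without an ID attribute in ", path)
    if (anyDuplicated(ids))
        stop("duplicate gene ID(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    out <- granges(gr)
    mcols(out)$gene_id <- ids
    names(out) <- ids
    out
}

#' Read and filter biallelic SNPs from a VCF
#'
#' Keeps biallelic single-nucleotide rows with `QUAL > minQual` and
#' `minDepth < DP < maxDepth` (strict inequalities). Indels and
#' multiallelic rows are dropped with a message; rows lacking a usable DP
#' are skipped with a warning, since the depth filter cannot be evaluated
#' on them.
#'
#' @param path path to a VCF (4.x) file.
#' @param minQual,minDepth,maxDepth filter thresholds (defaults 20, 5, 71).
#' @param depthSource `"auto"` (INFO DP if present, else summed sample
#'   FORMAT DP), `"info"`, or `"format"`. The source of the "combined
#'   depth" is configurable because either convention is defensible.
#' @return a data.frame with columns `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`, `quality`, `depth`.
#' @export
readVcfSnps <- function(path, minQual = 20, minDepth = 5, maxDepth = 71,
                        depthSource = c("auto", "info", "format")) {
    if (!file.exists(path)) stop("VCF file not found: ", path)
    depthSource <- match.arg(depthSource)
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    altL <- rr$ALT
    nalt <- lengths(altL)
    alt1 <- rep(NA_character_, length(rr))
    alt1[nalt == 1L] <- as.character(unlist(altL[nalt == 1L]))
    isSnp <- nalt == 1L & nchar(ref) == 1L & !is.na(alt1) &
        nchar(alt1) == 1L & alt1 %in% c("A", "C", "G", "T") & alt1 != ref
    nDropped <- sum(!isSnp)
    if (nDropped > 0L)
        message(nDropped, " non-SNP (indel/multiallelic) row(s) dropped")

    dp <- rep(NA_real_, length(rr))
    infoDP <- if ("DP" %in% colnames(VariantAnnotation::info(vcf)))
        as.numeric(VariantAnnotation::info(vcf)$DP) else NULL
    fmtDP <- if ("DP" %in% rownames(VariantAnnotation::geno(
                     VariantAnnotation::header(vcf)))) {
        g <- VariantAnnotation::geno(vcf)$DP
        if (!is.null(g)) rowSums(matrix(as.numeric(g), nrow = nrow(g)),
                                 na.rm = FALSE) else NULL
    } else NULL
    if (depthSource %in% c("auto", "info") && !is.null(infoDP)) dp <- infoDP
    if (depthSource == "format" && !is.null(fmtDP)) dp <- fmtDP
    if (depthSource == "auto" && !is.null(fmtDP)) dp[is.na(dp)] <-
        fmtDP[is.na(dp)]

    snps <- data.frame(
        chromosome = as.character(seqnames(rr)),
        position = start(rr),
        ref_allele = ref,
        alt_allele = alt1,
        quality = as.numeric(rr$QUAL),
        depth = dp,
        stringsAsFactors = FALSE)[isSnp, , drop = FALSE]
    noDp <- is.na(snps$depth)
    if (any(noDp)) {
        warning(sum(noDp), " SNP row(s) without DP skipped")
        snps <- snps[!noDp, , drop = FALSE]
    }
    rownames(snps) <- NULL
    filterSnps(snps, minQual = minQual, minDepth = minDepth,
               maxDepth = maxDepth)
}

#' Apply the SNP quality/depth filter
#'
#' Strict inequalities: `quality > minQual`, `minDepth < depth < maxDepth`.
#' Idempotent: filtering an already-filtered set changes nothing.
#'
#' @param snps a data.frame as returned by [readVcfSnps()].
#' @inheritParams readVcfSnps
#' @return the filtered data.frame.
#' @export
filterSnps <- function(snps, minQual = 20, minDepth = 5, maxDepth = 71) {
    keep <- snps$quality > minQual & snps$depth > minDepth &
        snps$depth < maxDepth
    out <- snps[keep, , drop = FALSE]
    if (anyDuplicated(out[, c("chromosome", "position")]))
        stop("duplicate SNP positions after filtering")
    rownames(out) <- NULL
    out
}

## insertion tables ---------------------------------------------------------

.INSERTION_COLS <- c("gene", "chromosome", "position", "allele",
                     "control_count", "treatment_count", "round")

#' Write / read the per-round insertion abundance table
#'
#' Tab-separated table with one row per (insertion, round) in which the
#' insertion was detected, with the read counts of both selection
#' conditions side by side: columns `gene`, `chromosome`, `position`,
#' `allele`, `control_count`, `treatment_count`, `round`.
#' `readInsertionTable(writeInsertionTable(x))` is the identity.
#'
#' @param insertions an [InsertionSet-class] or a data.frame already in the
#'   table schema.
#' @param path output (input) path.
#' @param assay which assay of an InsertionSet to report
#'   (`"counts"` or `"abundance"`).
#' @param alleles optional character vector of valid allele labels; on
#'   read, any other label is an error.
#' @return `readInsertionTable()` returns the table as a data.frame.
#' @export
writeInsertionTable <- function(insertions, path, assay = "counts") {
    tab <- if (is(insertions, "InsertionSet"))
        insertionTable(insertions, assay = assay) else insertions
    if (!identical(colnames(tab), .INSERTION_COLS))
        stop("insertion table must have columns: ",
             paste(.INSERTION_COLS, collapse = ", "))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeInsertionTable
#' @export
readInsertionTable <- function(path, alleles = NULL) {
    tab <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(gene = "character",
                                     chromosome = "character",
                                     allele = "character"))
    if (!identical(colnames(tab), .INSERTION_COLS))
        stop("unexpected insertion table columns in ", path)
    tab$position <- as.integer(tab$position)
    tab$round <- as.integer(tab$round)
    tab$control_count <- as.numeric(tab$control_count)
    tab$treatment_count <- as.numeric(tab$treatment_count)
    if (any(is.na(tab$allele) | tab$allele == ""))
        stop("missing allele label in ", path)
    if (!is.null(alleles)) {
        bad <- setdiff(unique(tab$allele), alleles)
        if (length(bad))
            stop("unknown allele label(s) in ", path, ": ",
                 paste(bad, collapse = ", "))
    }
    tab
}

#' Read a BLAT PSL alignment file
#'
#' Accepts PSL with or without the 5-line `psLayout` header. Target
#' coordinates are converted from PSL's 0-based half-open convention to
#' the package's 1-based inclusive convention.
#'
#' @param path path to a 21-column PSL file.
#' @return a data.frame with `read_id`, `chromosome`, `strand`,
#'   `target_start`, `target_end` (1-based inclusive), `matches`,
#'   `mismatches`, `query_size`, `block_count`.
#' @export
readPsl <- function(path) {
    if (!file.exists(path)) stop("PSL file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(psLayout|match\\b|\\s*$|-+)", lines)
    ## the header's column-label lines start with "match"/"     match"
    keep <- keep & !grepl("^\\s*match", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
        return(data.frame(read_id = character(), chromosome = character(),
                          strand = character(), target_start = integer(),
                          target_end = integer(), matches = integer(),
                          mismatches = integer(), query_size = integer(),
                          block_count = integer()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 21L))
        stop("PSL line ", lineno[which(nf != 21L)[1L]],
             " has ", nf[nf != 21L][1L], " columns (expected 21)")
    m <- do.call(rbind, fields)
    data.frame(
        read_id = m[, 10L],
        chromosome = m[, 14L],
        strand = m[, 9L],
        target_start = as.integer(m[, 16L]) + 1L,
        target_end = as.integer(m[, 17L]),
        matches = as.integer(m[, 1L]),
        mismatches = as.integer(m[, 2L]),
        query_size = as.integer(m[, 11L]),
        block_count = as.integer(m[, 18L]),
        stringsAsFactors = FALSE)
}

#' Read a sample sheet mapping barcodes to libraries
#'
#' Tab-separated columns `sample_id`, `barcode`, `allele`, `round`,
#' `condition`. Enforces: 6-nt A/C/G/T barcodes unique within the sheet;
#' conditions in {treatment, control}; at most one treatment and one
#' control library per (allele, round).
#'
#' @param path path to the sample sheet TSV.
#' @param barcodeLen expected barcode length (default 6).
#' @return a data.frame of validated sample records.
#' @export
readSampleSheet <- function(path, barcodeLen = 6L) {
    if (!file.exists(path)) stop("sample sheet not found: ", path)
    s <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
    need <- c("sample_id", "barcode", "allele", "round", "condition")
    miss <- setdiff(need, colnames(s))
    if (length(miss))
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    s$round <- as.integer(s$round)
    validateSamples(s, barcodeLen = barcodeLen)
    s
}

## shared sample-sheet invariants; also used by validateRunConfig
validateSamples <- function(s, barcodeLen = 6L, stopOnError = TRUE) {
    v <- character()
    if (anyDuplicated(s$sample_id))
        v <- c(v, "duplicate sample_id")
    badBc <- !grepl(sprintf("^[ACGT]{%d}$", barcodeLen), s$barcode)
    if (any(badBc))
        v <- c(v, paste0("invalid barcode(s): ",
                         paste(s$barcode[badBc], collapse = ", ")))
    if (anyDuplicated(s$barcode))
        v <- c(v, paste0("duplicate barcode(s): ",
                         paste(unique(s$barcode[duplicated(s$barcode)]),
                               collapse = ", ")))
    if (!all(s$condition %in% c("treatment", "control")))
        v <- c(v, "condition must be 'treatment' or 'control'")
    if (any(is.na(s$round) | s$round < 1L))
        v <- c(v, "round must be a positive integer")
    key <- paste(s$allele, s$round, s$condition)
    if (anyDuplicated(key))
        v <- c(v, paste0("more than one library for (allele, round, condition): ",
                         paste(unique(key[duplicated(key)]), collapse = "; ")))
    for (al in unique(s$allele)) for (r in unique(s$round[s$allele == al])) {
        have <- s$condition[s$allele == al & s$round == r]
        missing <- setdiff(c("treatment", "control"), have)
        if (length(missing))
            v <- c(v, sprintf("allele %s round %d lacks a %s library",
                              al, r, paste(missing, collapse = " and ")))
    }
    if (stopOnError && length(v))
        stop("invalid sample sheet:\n  ", paste(v, collapse = "\n  "))
    invisible(v)
}

#' Write gene-level reciprocal hemizygosity test results
#'
#' Writes a TSV with optional `#`-prefixed metadata header lines (run
#' parameters, tested/untested gene counts) followed by the results table.
#'
#' @param results data.frame from [runGeneTests()].
#' @param path output path.
#' @param metadata named list written as `# key=value` header lines.
#' @return invisibly, `path`.
#' @export
writeResultsTable <- function(results, path, metadata = list()) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (k in names(metadata))
        writeLines(sprintf("# %s=%s", k, as.character(metadata[[k]])), con)
    write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
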