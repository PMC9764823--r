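## Raw reads -> demultiplexed genomic flanks.
## All operations are vectorized over character vectors of sequences and are
## purely deterministic: identical input yields byte-identical output.

#' Clip 3' adapter read-through
#'
#' If the configured 3' adapter occurs anywhere in a read, the read is
#' truncated at the adapter's first occurrence. Otherwise, if a read suffix
#' equals a prefix of the adapter of at least `adapterMinOverlap` nt
#' (partial read-through at the very end of the read), that suffix is
#' removed; the longest such overlap wins. Non-matching reads pass
#' unchanged. Matching is exact (0 mismatches).
#'
#' @param sequences character vector of read sequences (uppercase DNA).
#' @param layout a [ReadLayout-class].
#' @return character vector of clipped sequences.
#' @export
clipAdapter <- function(sequences, layout = ReadLayout()) {
    adapter <- layout@adapter3p
    out <- sequences
    pos <- regexpr(adapter, out, fixed = TRUE)
    hit <- pos > 0L
    out[hit] <- substr(out[hit], 1L, pos[hit] - 1L)
    ## partial read-through: read suffix == adapter prefix, longest first
    todo <- !hit
    for (k in seq(nchar(adapter) - 1L,
                  min(layout@adapterMinOverlap, nchar(adapter) - 1L))) {
        if (!any(todo)) break
        pref <- substr(adapter, 1L, k)
        m <- todo & endsWith(out, pref)
        out[m] <- substr(out[m], 1L, nchar(out[m]) - k)
        todo <- todo & !m
    }
    out
}

#' Trim the random prefix and demultiplex by barcode
#'
#' Discards the first `randomPrefixLen` nt of each read (random PCR
#' diversity bases, not used for deduplication), reads the next
#' `barcodeLen` nt as the sample barcode, and assigns the read to the
#' matching sample. Matching is exact by default
#' (`barcodeMaxMismatch = 0`); Hamming distance <= 1 assignment is
#' available, in which case a barcode within distance 1 of more than one
#' sample is left unassigned.
#'
#' @param sequences character vector of (adapter-clipped) read sequences.
#' @param layout a [ReadLayout-class].
#' @param samples sample sheet data.frame (see [readSampleSheet()]).
#' @return a list with `sample_id` (character, NA where unassigned),
#'   `remainder` (sequence after the barcode), and `category` (one of
#'   `"assigned"`, `"no_barcode"`, `"too_short"`).
#' @export
trimPrefixAndDemux <- function(sequences, layout = ReadLayout(),
                               samples) {
    np <- layout@randomPrefixLen
    nb <- layout@barcodeLen
    n <- length(sequences)
    category <- rep("no_barcode", n)
    sampleId <- rep(NA_character_, n)
    tooShort <- nchar(sequences) <= np + nb
    category[tooShort] <- "too_short"
    bc <- substr(sequences, np + 1L, np + nb)
    idx <- match(bc, samples$barcode)
    if (layout@barcodeMaxMismatch >= 1L && anyNA(idx)) {
        unk <- which(is.na(idx) & !tooShort)
        if (length(unk)) {
            ubc <- unique(bc[unk])
            near <- vapply(ubc, function(b) {
                d <- .hammingToSet(b, samples$barcode)
                w <- which(d <= 1L)
                if (length(w) == 1L) w else NA_integer_
            }, integer(1))
            idx[unk] <- near[match(bc[unk], ubc)]
        }
    }
    ok <- !tooShort & !is.na(idx)
    category[ok] <- "assigned"
    sampleId[ok] <- samples$sample_id[idx[ok]]
    remainder <- rep(NA_character_, n)
    remainder[ok] <- substr(sequences[ok], np + nb + 1L,
                            nchar(sequences[ok]))
    list(sample_id = sampleId, remainder = remainder, category = category)
}

.hammingToSet <- function(b, set) {
    bs <- strsplit(b, "")[[1L]]
    vapply(strsplit(set, ""), function(s)
        if (length(s) != length(bs)) length(bs) else sum(s != bs),
        integer(1))
}

#' Locate the transposon tag and excise the genomic flank
#'
#' Retains only reads containing the transposon tag exactly (the last
#' `tagMatchLen` nt of `transposonTag`, zero mismatches); everything 3' of
#' the tag's first occurrence is the genomic flank. Reads without an exact
#' tag occurrence are rejected (`"no_tag"`); flanks that still contain a
#' tag occurrence (chimeric/tandem artifacts) are rejected
#' (`"contaminated"`).
#'
#' @param remainders character vector of post-barcode read remainders.
#' @param layout a [ReadLayout-class].
#' @return list with `flank` (character, NA where rejected) and `category`
#'   (`"kept"`, `"no_tag"`, or `"contaminated"`).
#' @export
extractFlank <- function(remainders, layout = ReadLayout()) {
    tag <- layout@transposonTag
    tag <- substr(tag, nchar(tag) - layout@tagMatchLen + 1L, nchar(tag))
    n <- length(remainders)
    category <- rep("no_tag", n)
    flank <- rep(NA_character_, n)
    pos <- regexpr(tag, remainders, fixed = TRUE)
    hit <- pos > 0L
    flank[hit] <- substr(remainders[hit], pos[hit] + nchar(tag),
                         nchar(remainders[hit]))
    contam <- hit & grepl(tag, flank, fixed = TRUE)
    category[hit] <- "kept"
    category[contam] <- "contaminated"
    flank[!hit | contam] <- NA_character_
    list(flank = flank, category = category)
}

#' Minimum genomic-flank length filter
#'
#' Keeps flanks of at least `minFlankLen` nt (default 30; a 30-nt flank is
#' kept, a 29-nt flank is eliminated).
#'
#' @param flanks character vector of genomic flanks.
#' @param layout a [ReadLayout-class].
#' @return logical vector, TRUE where kept.
#' @export
lengthFilter <- function(flanks, layout = ReadLayout()) {
    !is.na(flanks) & nchar(flanks) >= layout@minFlankLen
}

#' Process one multiplexed junction-sequencing library
#'
#' Runs the full read-processing chain on one FASTQ: adapter clipping,
#' random-prefix trimming, barcode demultiplexing, exact transposon-tag
#' filtering, flank excision, and the minimum flank-length filter. Every
#' input read is accounted for in exactly one statistics category.
#'
#' @param fastq path to the FASTQ file, or a reads DataFrame from
#'   [readFastq()].
#' @param layout a [ReadLayout-class].
#' @param samples sample sheet data.frame (see [readSampleSheet()]).
#' @return a list with
#'   \describe{
#'     \item{reads}{DataFrame of junction reads: `read_id`, `sample_id`,
#'       `allele`, `round`, `condition`, `flank`, `flank_len`.}
#'     \item{stats}{one-row data.frame: `input`, `kept`, `no_barcode`,
#'       `too_short`, `no_tag`, `contaminated`, `short_flank`.}
#'   }
#' @export
processLibrary <- function(fastq, layout = ReadLayout(), samples) {
    reads <- if (is.character(fastq)) readFastq(fastq) else fastq
    n <- nrow(reads)
    stats <- data.frame(input = n, kept = 0L, no_barcode = 0L,
                        too_short = 0L, no_tag = 0L, contaminated = 0L,
                        short_flank = 0L)
    empty <- DataFrame(read_id = character(), sample_id = character(),
                       allele = character(), round = integer(),
                       condition = character(), flank = character(),
                       flank_len = integer())
    if (n == 0L) return(list(reads = empty, stats = stats))

    seqs <- clipAdapter(reads$sequence, layout)
    dm <- trimPrefixAndDemux(seqs, layout, samples)
    stats$too_short <- sum(dm$category == "too_short")
    stats$no_barcode <- sum(dm$category == "no_barcode")
    aidx <- which(dm$category == "assigned")

    fl <- extractFlank(dm$remainder[aidx], layout)
    stats$no_tag <- sum(fl$category == "no_tag")
    stats$contaminated <- sum(fl$category == "contaminated")
    keepTag <- fl$category == "kept"
    keepLen <- lengthFilter(fl$flank, layout)
    stats$short_flank <- sum(keepTag & !keepLen)
    keep <- aidx[keepTag & keepLen]
    stats$kept <- length(keep)
    stopifnot(stats$kept + stats$no_barcode + stats$too_short +
              stats$no_tag + stats$contaminated + stats$short_flank ==
              stats$input)

    sidx <- match(dm$sample_id[keep], samples$sample_id)
    flank <- fl$flank[keepTag & keepLen]
    out <- DataFrame(read_id = reads$read_id[keep],
                     sample_id = dm$sample_id[keep],
                     allele = samples$allele[sidx],
                     round = as.integer(samples$round[sidx]),
                     condition = samples$condition[sidx],
                     flank = flank,
                     flank_len = nchar(flank))
    list(reads = out, stats = stats)
}
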