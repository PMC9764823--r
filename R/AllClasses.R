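## S4 classes shared across the package.

.DNA_RE <- "^[ACGT]+$"

#' Read layout of a transposon-junction sequencing library
#'
#' Describes the architecture of a single-end RH-seq read: a random prefix
#' (PCR diversity bases, discarded), a sample barcode, the 3' tail of the
#' Mos1 transposon carried over from the amplification primer, the genomic
#' flank abutting the insertion, and possibly read-through into the
#' 3' sequencing adapter.
#'
#' @slot randomPrefixLen integer, length of the random prefix (default 6).
#' @slot barcodeLen integer, sample barcode length (default 6).
#' @slot transposonTag DNA string: the transposon tail expected immediately
#'   after the barcode. Default is the 26-nt Mos1 3'-tail segment of the
#'   amplification primer.
#' @slot tagMatchLen integer, how many terminal bases of `transposonTag`
#'   must match exactly (default: the full tag).
#' @slot adapter3p DNA string: 3' adapter whose read-through is clipped.
#' @slot adapterMinOverlap integer, minimum suffix-prefix overlap for
#'   adapter clipping (default 8).
#' @slot minFlankLen integer, minimum genomic flank length kept (default 30).
#' @slot barcodeMaxMismatch integer, allowed barcode mismatches (0 = exact,
#'   the default; 1 enables Hamming<=1 assignment).
#'
#' @export
setClass("ReadLayout", representation(
    randomPrefixLen = "integer",
    barcodeLen = "integer",
    transposonTag = "character",
    tagMatchLen = "integer",
    adapter3p = "character",
    adapterMinOverlap = "integer",
    minFlankLen = "integer",
    barcodeMaxMismatch = "integer"
))

setValidity("ReadLayout", function(object) {
    msg <- character()
    for (s in c("randomPrefixLen", "barcodeLen", "tagMatchLen",
                "adapterMinOverlap", "minFlankLen"))
        if (length(slot(object, s)) != 1L || is.na(slot(object, s)) ||
            slot(object, s) < 1L)
            msg <- c(msg, sprintf("'%s' must be a single positive integer", s))
    if (length(object@barcodeMaxMismatch) != 1L ||
        !object@barcodeMaxMismatch %in% c(0L, 1L))
        msg <- c(msg, "'barcodeMaxMismatch' must be 0 or 1")
    if (!grepl(.DNA_RE, object@transposonTag))
        msg <- c(msg, "'transposonTag' must be a non-empty A/C/G/T string")
    if (!grepl(.DNA_RE, object@adapter3p))
        msg <- c(msg, "'adapter3p' must be a non-empty A/C/G/T string")
    if (grepl(.DNA_RE, object@transposonTag) &&
        object@tagMatchLen > nchar(object@transposonTag))
        msg <- c(msg, "'tagMatchLen' cannot exceed the tag length")
    if (length(msg)) msg else TRUE
})

#' @param randomPrefixLen,barcodeLen,transposonTag,tagMatchLen,adapter3p
#'   see the class slots.
#' @param adapterMinOverlap,minFlankLen,barcodeMaxMismatch see the class slots.
#' @return `ReadLayout()` returns a validated ReadLayout object.
#' @examples
#' layout <- ReadLayout()
#' minFlankLen(layout)
#' @rdname ReadLayout-class
#' @export
ReadLayout <- function(randomPrefixLen = 6L,
                       barcodeLen = 6L,
                       transposonTag = "GATTTAAAAAAAACGACATTTCATAC",
                       tagMatchLen = nchar(transposonTag),
                       adapter3p = "GGGCGTAGATTACCGTCCGCGACTCGTACTGTGGCGCGCCT",
                       adapterMinOverlap = 8L,
                       minFlankLen = 30L,
                       barcodeMaxMismatch = 0L) {
    new("ReadLayout",
        randomPrefixLen = as.integer(randomPrefixLen),
        barcodeLen = as.integer(barcodeLen),
        transposonTag = toupper(transposonTag),
        tagMatchLen = as.integer(tagMatchLen),
        adapter3p = toupper(adapter3p),
        adapterMinOverlap = as.integer(adapterMinOverlap),
        minFlankLen = as.integer(minFlankLen),
        barcodeMaxMismatch = as.integer(barcodeMaxMismatch))
}

#' Insertion-site collapsing rule
#'
#' Reads mapping within `window` bp of each other are taken to originate
#' from the same transposon mutant clone and are collapsed by
#' single-linkage clustering; each cluster is reported at its modal
#' position (the member position with the most reads; ties broken towards
#' the lowest coordinate).
#'
#' @slot window integer, clustering window in bp (default 100).
#' @slot tieBreak character, modal-position tie rule ("lowest_coordinate").
#' @export
setClass("ClusterRule", representation(
    window = "integer",
    tieBreak = "character"
))

setValidity("ClusterRule", function(object) {
    msg <- character()
    if (length(object@window) != 1L || is.na(object@window) ||
        object@window < 1L)
        msg <- c(msg, "'window' must be a single positive integer")
    if (!identical(object@tieBreak, "lowest_coordinate"))
        msg <- c(msg, "only tieBreak == 'lowest_coordinate' is implemented")
    if (length(msg)) msg else TRUE
})

#' @param window,tieBreak see the class slots.
#' @return `ClusterRule()` returns a validated ClusterRule object.
#' @rdname ClusterRule-class
#' @export
ClusterRule <- function(window = 100L, tieBreak = "lowest_coordinate") {
    new("ClusterRule", window = as.integer(window), tieBreak = tieBreak)
}

#' Container for quantified transposon insertions
#'
#' An `InsertionSet` extends
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are collapsed
#' insertion sites (width-1 GRanges at the modal junction position, with an
#' `allele` column giving the parental homolog carrying the insertion, and
#' after [assignGenes()] a `gene_id` CharacterList). Columns are sequencing
#' libraries with `sample_id`, `barcode`, `allele`, `round`, `condition`
#' and `total_reads` in `colData`. Assays: `counts` (raw collapsed read
#' counts, absent observations as 0) and `abundance` (counts normalized by
#' per-library total reads times a scale factor).
#'
#' @export
setClass("InsertionSet", contains = "RangedSummarizedExperiment")

setValidity("InsertionSet", function(object) {
    msg <- character()
    if (!all(c("counts", "abundance") %in% assayNames(object)))
        msg <- c(msg, "assays must include 'counts' and 'abundance'")
    need <- c("sample_id", "allele", "round", "condition", "total_reads")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!"allele" %in% colnames(mcols(rowRanges(object))))
        msg <- c(msg, "rowRanges must carry an 'allele' column")
    if ("counts" %in% assayNames(object) &&
        any(assay(object, "counts") < 0))
        msg <- c(msg, "'counts' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic RH-seq experiment
#'
#' Defines the full generative model: a random genome split into
#' chromosomes, inter-strain SNPs at a fixed per-bp rate, non-overlapping
#' gene models, per-round pools of hemizygote insertions for each parental
#' allele with log-normal clone-size heterogeneity, gene-wise
#' allele-specific selection fold-changes applied to treatment abundances,
#' count noise (Poisson or negative binomial), and the read layout used to
#' emit raw FASTQ.
#'
#' @slot seed integer master seed; fixes all downstream randomness.
#' @slot genomeLength total genome length in bp over all chromosomes.
#' @slot nChromosomes number of equal-length chromosomes.
#' @slot nGenes number of non-overlapping gene models.
#' @slot geneLengthRange length-2 integer range of gene lengths (bp).
#' @slot snpRate per-bp probability of an inter-strain SNP.
#' @slot alleles length-2 character: parental allele labels, order (A, B).
#' @slot nRoundsA,nRoundsB mutagenesis rounds per parental allele
#'   (the screen this emulates used 12 and 11).
#' @slot insertionsPerRound planted insertions per (allele, round) pool.
#' @slot readsPerInsertion mean control-condition reads per insertion.
#' @slot cloneSdLog sdlog of the log-normal clone-size factor.
#' @slot minSeparation minimum distance (bp) between planted junctions of
#'   the same allele; 0 disables the constraint (used for abstract
#'   count-level scenarios that never emit reads).
#' @slot selection data.frame(gene_id, fold_A, fold_B): treatment-abundance
#'   fold-changes applied to insertions disrupting that gene's A or B
#'   allele; genes not listed (and intergenic insertions) are neutral.
#' @slot noiseModel "poisson" or "nb".
#' @slot nbDispersion negative-binomial size parameter (ignored for poisson).
#' @slot flankLen genomic flank length carried by each emitted read.
#' @slot readLength emitted read length (adapter read-through fills the
#'   remainder beyond the flank).
#' @slot decoyNoTagRate,decoyBadBarcodeRate,decoyShortFlankRate fractions of
#'   extra decoy reads mixed in.
#' @slot layout a [ReadLayout-class] describing the emitted reads.
#' @export
setClass("SimulationConfig", representation(
    seed = "integer",
    genomeLength = "numeric",
    nChromosomes = "integer",
    nGenes = "integer",
    geneLengthRange = "integer",
    snpRate = "numeric",
    alleles = "character",
    nRoundsA = "integer",
    nRoundsB = "integer",
    insertionsPerRound = "integer",
    readsPerInsertion = "numeric",
    cloneSdLog = "numeric",
    minSeparation = "integer",
    selection = "data.frame",
    noiseModel = "character",
    nbDispersion = "numeric",
    flankLen = "integer",
    readLength = "integer",
    decoyNoTagRate = "numeric",
    decoyBadBarcodeRate = "numeric",
    decoyShortFlankRate = "numeric",
    layout = "ReadLayout"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@genomeLength < 1000)
        msg <- c(msg, "'genomeLength' must be at least 1 kb")
    if (object@nChromosomes < 1L)
        msg <- c(msg, "'nChromosomes' must be positive")
    if (object@snpRate < 0 || object@snpRate > 1)
        msg <- c(msg, "'snpRate' must be in [0, 1]")
    for (s in c("decoyNoTagRate", "decoyBadBarcodeRate",
                "decoyShortFlankRate"))
        if (slot(object, s) < 0 || slot(object, s) > 1)
            msg <- c(msg, sprintf("'%s' must be in [0, 1]", s))
    if (length(object@alleles) != 2L || anyDuplicated(object@alleles))
        msg <- c(msg, "'alleles' must be two distinct labels")
    if (nrow(object@selection)) {
        if (!all(c("gene_id", "fold_A", "fold_B") %in%
                 colnames(object@selection)))
            msg <- c(msg, "'selection' needs gene_id, fold_A, fold_B columns")
        else if (any(object@selection$fold_A <= 0) ||
                 any(object@selection$fold_B <= 0))
            msg <- c(msg, "selection fold-changes must be > 0")
    }
    if (!object@noiseModel %in% c("poisson", "nb"))
        msg <- c(msg, "'noiseModel' must be 'poisson' or 'nb'")
    if (object@minSeparation < 0L)
        msg <- c(msg, "'minSeparation' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @param seed,genomeLength,nChromosomes,nGenes,geneLengthRange,snpRate see
#'   the class slots.
#' @param alleles,nRoundsA,nRoundsB,insertionsPerRound,readsPerInsertion see
#'   the class slots.
#' @param cloneSdLog,minSeparation,selection,noiseModel,nbDispersion see the
#'   class slots.
#' @param flankLen,readLength,decoyNoTagRate,decoyBadBarcodeRate see the
#'   class slots.
#' @param decoyShortFlankRate,layout see the class slots.
#' @return `SimulationConfig()` returns a validated SimulationConfig.
#' @examples
#' cfg <- SimulationConfig(seed = 1, genomeLength = 2e5, nGenes = 20,
#'                         nRoundsA = 2, nRoundsB = 2,
#'                         insertionsPerRound = 50)
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(seed = 1L,
                             genomeLength = 5e6,
                             nChromosomes = 2L,
                             nGenes = 200L,
                             geneLengthRange = c(1000L, 5000L),
                             snpRate = 1e-3,
                             alleles = c("N2", "ED3077"),
                             nRoundsA = 12L,
                             nRoundsB = 11L,
                             insertionsPerRound = 500L,
                             readsPerInsertion = 100,
                             cloneSdLog = 0.5,
                             minSeparation = 201L,
                             selection = data.frame(gene_id = character(),
                                                    fold_A = numeric(),
                                                    fold_B = numeric()),
                             noiseModel = "poisson",
                             nbDispersion = 10,
                             flankLen = 50L,
                             readLength = 100L,
                             decoyNoTagRate = 0,
                             decoyBadBarcodeRate = 0,
                             decoyShortFlankRate = 0,
                             layout = ReadLayout()) {
    new("SimulationConfig",
        seed = as.integer(seed),
        genomeLength = as.numeric(genomeLength),
        nChromosomes = as.integer(nChromosomes),
        nGenes = as.integer(nGenes),
        geneLengthRange = as.integer(geneLengthRange),
        snpRate = snpRate,
        alleles = as.character(alleles),
        nRoundsA = as.integer(nRoundsA),
        nRoundsB = as.integer(nRoundsB),
        insertionsPerRound = as.integer(insertionsPerRound),
        readsPerInsertion = as.numeric(readsPerInsertion),
        cloneSdLog = cloneSdLog,
        minSeparation = as.integer(minSeparation),
        selection = selection,
        noiseModel = noiseModel,
        nbDispersion = nbDispersion,
        flankLen = as.integer(flankLen),
        readLength = as.integer(readLength),
        decoyNoTagRate = decoyNoTagRate,
        decoyBadBarcodeRate = decoyBadBarcodeRate,
        decoyShortFlankRate = decoyShortFlankRate,
        layout = layout)
}

#' @describeIn ReadLayout-class compact one-line summary.
#' @param object the object to display.
#' @export
setMethod("show", "ReadLayout", function(object) {
    cat("ReadLayout:",
        sprintf("prefix %d nt | barcode %d nt | tag %s (match last %d) | min flank %d",
                object@randomPrefixLen, object@barcodeLen,
                object@transposonTag, object@tagMatchLen,
                object@minFlankLen), "\n")
})

#' @describeIn ClusterRule-class compact one-line summary.
#' @param object the object to display.
#' @export
setMethod("show", "ClusterRule", function(object) {
    cat(sprintf("ClusterRule: single-linkage, window %d bp, ties -> %s\n",
                object@window, object@tieBreak))
})

#' @describeIn SimulationConfig-class summary of the scenario.
#' @param object the object to display.
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  genome: %.3g bp over %d chromosome(s); %d genes; SNP rate %g\n",
                object@genomeLength, object@nChromosomes, object@nGenes,
                object@snpRate))
    cat(sprintf("  screen: alleles %s/%s, %d+%d rounds, %d insertions/round, ~%g reads/insertion (%s noise)\n",
                object@alleles[1], object@alleles[2], object@nRoundsA,
                object@nRoundsB, object@insertionsPerRound,
                object@readsPerInsertion, object@noiseModel))
    cat(sprintf("  selection: %d gene(s) under allele-specific selection; seed %d\n",
                nrow(object@selection), object@seed))
})

## simple accessors ---------------------------------------------------------

#' Accessors for layout and rule parameters
#'
#' @param x a [ReadLayout-class] or [ClusterRule-class] object.
#' @return the requested parameter value.
#' @name layout-accessors
NULL

#' @rdname layout-accessors
#' @export
minFlankLen <- function(x) x@minFlankLen

#' @rdname layout-accessors
#' @export
transposonTag <- function(x) x@transposonTag

#' @rdname layout-accessors
#' @export
clusterWindow <- function(x) x@window
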