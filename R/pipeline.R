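## End-to-end orchestration: demux -> pseudogenome -> map -> quantify ->
## test, from one run configuration, with a reproducibility manifest.

#' Assemble a pipeline run configuration
#'
#' @param fastq named character vector/list of FASTQ paths, one per
#'   parental allele, named by allele label; the first name is the A
#'   allele (the one mapped against the reference), the second the B
#'   allele (mapped against the SNP-substituted pseudogenome).
#' @param samples path to the sample sheet TSV.
#' @param reference path to the reference genome FASTA.
#' @param vcf path to the inter-strain SNP VCF (pseudogenome input).
#' @param gff3 path to the gene annotation GFF3.
#' @param outdir output directory.
#' @param layout a [ReadLayout-class].
#' @param rule a [ClusterRule-class].
#' @param scale normalization scale (see [normalizeAbundances()]).
#' @param pseudoAbundance zero-observation replacement abundance.
#' @param minPerAllele minimum insertions per allele for a gene test.
#' @param exclusions gene_ids excluded from gene assignment.
#' @param mapper `"builtin"` (exact unique mapper) or `"psl"` (import
#'   external BLAT alignments from `psl`).
#' @param psl named paths to PSL files per allele (mapper = "psl").
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a validated `rhemiseqRunConfig` list.
#' @export
runConfig <- function(fastq, samples, reference, vcf, gff3, outdir,
                      layout = ReadLayout(), rule = ClusterRule(),
                      scale = 1, pseudoAbundance = 1, minPerAllele = 2L,
                      exclusions = character(), mapper = "builtin",
                      psl = NULL, seed = 1L) {
    cfg <- list(fastq = as.list(fastq), samples = samples,
                reference = reference, vcf = vcf, gff3 = gff3,
                outdir = outdir, layout = layout, rule = rule,
                scale = scale, pseudoAbundance = pseudoAbundance,
                minPerAllele = as.integer(minPerAllele),
                exclusions = exclusions, mapper = mapper, psl = psl,
                seed = as.integer(seed))
    class(cfg) <- "rhemiseqRunConfig"
    cfg
}

#' Read / write a run configuration as YAML
#'
#' The on-disk representation is a flat key-value YAML mirroring
#' [runConfig()]'s arguments (layout and clustering parameters inlined);
#' a config round-trips losslessly.
#'
#' @param path YAML path.
#' @param config a config from [runConfig()].
#' @return `readRunConfig()` returns the config list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    lay <- do.call(ReadLayout, y$layout %||% list())
    rule <- do.call(ClusterRule, y$rule %||% list())
    runConfig(fastq = y$fastq, samples = y$samples,
              reference = y$reference, vcf = y$vcf, gff3 = y$gff3,
              outdir = y$outdir, layout = lay, rule = rule,
              scale = y$scale %||% 1,
              pseudoAbundance = y$pseudoAbundance %||% 1,
              minPerAllele = y$minPerAllele %||% 2L,
              exclusions = y$exclusions %||% character(),
              mapper = y$mapper %||% "builtin", psl = y$psl,
              seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    lay <- config$layout
    y <- list(fastq = config$fastq, samples = config$samples,
              reference = config$reference, vcf = config$vcf,
              gff3 = config$gff3, outdir = config$outdir,
              layout = list(randomPrefixLen = lay@randomPrefixLen,
                            barcodeLen = lay@barcodeLen,
                            transposonTag = lay@transposonTag,
                            tagMatchLen = lay@tagMatchLen,
                            adapter3p = lay@adapter3p,
                            adapterMinOverlap = lay@adapterMinOverlap,
                            minFlankLen = lay@minFlankLen,
                            barcodeMaxMismatch = lay@barcodeMaxMismatch),
              rule = list(window = config$rule@window,
                          tieBreak = config$rule@tieBreak),
              scale = config$scale,
              pseudoAbundance = config$pseudoAbundance,
              minPerAllele = config$minPerAllele,
              exclusions = config$exclusions,
              mapper = config$mapper, psl = config$psl,
              seed = config$seed)
    yaml::write_yaml(y, path)
    invisible(path)
}

#' Validate a run configuration
#'
#' Checks input-file existence, sample-sheet invariants (barcode
#' uniqueness and validity, one treatment and one control library per
#' (allele, round)), allele consistency between FASTQ names and the
#' sheet, and parameter ranges. Violations are returned, not thrown.
#'
#' @param config a config from [runConfig()].
#' @return character vector of violations; empty means valid.
#' @export
validateRunConfig <- function(config) {
    v <- character()
    for (f in c("samples", "reference", "vcf", "gff3"))
        if (!is.character(config[[f]]) || !file.exists(config[[f]]))
            v <- c(v, sprintf("%s file missing: %s", f,
                              as.character(config[[f]])[1L]))
    if (length(config$fastq) != 2L || is.null(names(config$fastq)))
        v <- c(v, "fastq must be two paths named by allele label")
    for (al in names(config$fastq))
        if (!file.exists(config$fastq[[al]]))
            v <- c(v, sprintf("fastq[%s] file missing: %s", al,
                              config$fastq[[al]]))
    if (!config$mapper %in% c("builtin", "psl"))
        v <- c(v, "mapper must be 'builtin' or 'psl'")
    if (config$mapper == "psl" &&
        (length(config$psl) != 2L ||
         !all(file.exists(unlist(config$psl)))))
        v <- c(v, "mapper 'psl' requires two existing psl paths")
    if (config$scale <= 0) v <- c(v, "scale must be positive")
    if (config$pseudoAbundance <= 0)
        v <- c(v, "pseudoAbundance must be positive")
    if (config$minPerAllele < 1L)
        v <- c(v, "minPerAllele must be >= 1")
    if (is.character(config$samples) && file.exists(config$samples)) {
        s <- tryCatch(read.delim(config$samples,
                                 colClasses = "character"),
                      error = function(e) NULL)
        if (is.null(s) || !all(c("sample_id", "barcode", "allele",
                                 "round", "condition") %in% colnames(s)))
            v <- c(v, "sample sheet unreadable or lacks required columns")
        else {
            s$round <- as.integer(s$round)
            v <- c(v, validateSamples(s, config$layout@barcodeLen,
                                      stopOnError = FALSE))
            if (!is.null(names(config$fastq)) &&
                !setequal(names(config$fastq), unique(s$allele)))
                v <- c(v, "fastq allele names do not match the sheet")
        }
    }
    v
}

#' Run the full RH-seq pipeline
#'
#' Stages: read processing per allele FASTQ (demux, tag filter, flank
#' excision), pseudogenome construction for the B allele, unique exact
#' flank mapping of each allele's reads against its genome, insertion
#' collapsing/unification/normalization, gene assignment and genic
#' filtering, per-insertion effects, and per-gene reciprocal hemizygosity
#' tests. All intermediate tables are written as plain TSV under
#' `config$outdir`, together with a `manifest.json` recording the package
#' version, a config hash, input checksums, and per-stage record counts.
#' The pipeline is deterministic: identical inputs produce byte-identical
#' outputs.
#'
#' @param config a validated config from [runConfig()] /
#'   [readRunConfig()].
#' @return invisibly, a list with `results` (gene-test data.frame),
#'   `iset` (the genic [InsertionSet-class]), `isetAll` (all insertions,
#'   pre-filter), `effects`, `stats`, `mapStats` and `manifest`.
#' @export
runPipeline <- function(config) {
    v <- validateRunConfig(config)
    if (length(v))
        stop("invalid run config:\n  ", paste(v, collapse = "\n  "))
    outdir <- config$outdir
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    samples <- readSampleSheet(config$samples,
                               barcodeLen = config$layout@barcodeLen)
    alleles <- names(config$fastq)
    counts <- list()

    ## stage 1: read processing per allele
    stats <- list()
    flanksByAllele <- list()
    for (al in alleles) {
        pl <- processLibrary(config$fastq[[al]], config$layout,
                             samples[samples$allele == al, , drop = FALSE])
        flanksByAllele[[al]] <- pl$reads
        stats[[al]] <- cbind(data.frame(allele = al), pl$stats)
    }
    stats <- do.call(rbind, stats)
    write.table(stats, file.path(outdir, "stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ## stage 2: genomes (reference for allele A, pseudogenome for B)
    reference <- readDNAStringSet(config$reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    snps <- readVcfSnps(config$vcf)
    pseudo <- buildPseudogenome(reference, snps)
    genomes <- setNames(list(reference, pseudo), alleles)

    ## stage 3: unique exact mapping per allele
    mapped <- list()
    mapStats <- list()
    for (al in alleles) {
        fr <- flanksByAllele[[al]]
        mm <- if (config$mapper == "builtin") {
            cbind(as.data.frame(fr[, c("read_id", "sample_id")]),
                  mapFlanks(fr$flank, genomes[[al]]))
        } else {
            psl <- pslUniqueHits(readPsl(config$psl[[al]]))
            hit <- match(fr$read_id, psl$read_id)
            data.frame(read_id = fr$read_id, sample_id = fr$sample_id,
                       status = ifelse(is.na(hit), "unmapped", "unique"),
                       chromosome = psl$chromosome[hit],
                       strand = psl$strand[hit],
                       junction_pos = psl$junction_pos[hit],
                       aligned_len = psl$aligned_len[hit],
                       stringsAsFactors = FALSE)
        }
        mapStats[[al]] <- data.frame(allele = al,
            unique = sum(mm$status == "unique"),
            unmapped = sum(mm$status == "unmapped"),
            multimapped = sum(mm$status == "multimapped"))
        mapped[[al]] <- mm[mm$status == "unique", , drop = FALSE]
    }
    mapped <- do.call(rbind, mapped)
    rownames(mapped) <- NULL
    write.table(mapped[, c("read_id", "sample_id", "chromosome", "strand",
                           "junction_pos")],
                file.path(outdir, "mapped.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mapStats <- do.call(rbind, mapStats)

    ## stage 4: collapse, unify, normalize; gene assignment
    iset <- buildInsertionSet(mapped, samples, rule = config$rule,
                              scale = config$scale)
    genes <- readGff3Genes(config$gff3)
    iset <- assignGenes(iset, genes, exclusions = config$exclusions)
    writeInsertionTable(iset, file.path(outdir, "insertions.tsv"))
    gset <- genicFilter(iset)

    ## stage 5: effects and gene tests
    effects <- insertionEffects(gset,
                                pseudoAbundance = config$pseudoAbundance)
    results <- runGeneTests(effects, alleles = alleles,
                            minPerAllele = config$minPerAllele)
    writeResultsTable(results, file.path(outdir, "results.tsv"),
        metadata = list(
            package = paste0("rhemiseq ", packageVersion("rhemiseq")),
            min_per_allele = config$minPerAllele,
            scale = config$scale,
            pseudo_abundance = config$pseudoAbundance,
            window = config$rule@window,
            n_genes_tested = attr(results, "n_tested"),
            n_genes_untested = nrow(results) - attr(results, "n_tested")))

    ## manifest
    cfgPath <- file.path(outdir, "config.yaml")
    writeRunConfig(config, cfgPath)
    inputs <- c(config$samples, config$reference, config$vcf, config$gff3,
                unlist(config$fastq))
    manifest <- list(
        package_version = as.character(packageVersion("rhemiseq")),
        config_md5 = unname(tools::md5sum(cfgPath)),
        input_md5 = as.list(tools::md5sum(inputs)),
        seed = config$seed,
        stage_counts = list(
            reads_input = sum(stats$input),
            reads_kept = sum(stats$kept),
            reads_mapped_unique = sum(mapStats$unique),
            reads_multimapped = sum(mapStats$multimapped),
            insertions = nrow(iset),
            insertions_genic = nrow(gset),
            insertions_with_effect = nrow(effects),
            genes_tested = attr(results, "n_tested")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(results = results, iset = gset, isetAll = iset,
                   effects = effects, stats = stats,
                   mapStats = mapStats, manifest = manifest))
}
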