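#' Run the full one-bulk (MutMap-style) analysis
#'
#' From-VCF entry point: read, filter, compute per-variant SNP-indices,
#' build the depth-indexed null CI table by simulation, classify, window
#' scan, and write every output into `outDir`:
#' `snp_index.tsv`, `windows.tsv`, `ci_table.tsv`, `candidates.tsv`,
#' `scan.png` and a machine-readable `run_log.json` with every parameter,
#' the seed and per-reason filter counts.
#'
#' @param vcf path to the multi-sample VCF.
#' @param parent,bulk sample names of the parent and the selected bulk.
#' @param n number of pooled individuals in the bulk (one-bulk crosses are
#'   F2 by design: the bulk pools selected F2 progeny).
#' @param outDir output directory (created if needed).
#' @param genome optional [GenomeMap-class]; when NULL it is taken from
#'   the VCF contig headers (falling back to the last variant position per
#'   chromosome).
#' @param param [FilterParam-class] thresholds.
#' @param windowBp,stepBp,minVariants window-scan settings
#'   (see [windowScan()]).
#' @param levels genome-wide confidence levels (default 0.95, 0.99).
#' @param reps simulation replicates per depth.
#' @param seed RNG seed for the CI simulation (recorded in the log).
#' @param depthCap depths above this use the cap's bounds (default 400).
#' @param correction optional list(nChromosomes, genomeSizeBp, totalCM);
#'   when given, `levels` are Sidak-adjusted via [correctedLevels()]
#'   before the quantiles are drawn, and the adjusted values are recorded
#'   in the log.
#' @return invisibly, a list with the output paths, the classified
#'   variant table, the window table, the [CITable-class] and the filter
#'   summary.
#' @export
runOneBulk <- function(vcf, parent, bulk, n, outDir,
                       genome = NULL, param = filterParam(),
                       windowBp = 2e6, stepBp = 1e5, minVariants = 3L,
                       levels = c(0.95, 0.99), reps = 10000L, seed = 42L,
                       depthCap = 400L, correction = NULL) {
    design <- bulkDesign(n, 2L)
    .runPipeline(vcf, parent, bulks = bulk, designs = list(design),
                 outDir = outDir, genome = genome, param = param,
                 windowBp = windowBp, stepBp = stepBp,
                 minVariants = minVariants, levels = levels, reps = reps,
                 seed = seed, depthCap = depthCap, correction = correction)
}

#' Run the full two-bulk (QTL-seq-style) analysis
#'
#' As [runOneBulk()] but with two opposite-phenotype bulks and the delta
#' SNP-index as the scanned statistic. `generation` (the -F of the
#' original tooling) sets the selfed generation for both bulks: 2 for F2
#' progeny, 6 for F6 RILs, etc.
#'
#' @inheritParams runOneBulk
#' @param bulk1,bulk2 bulk sample names (delta = index1 - index2).
#' @param n1,n2 pooled individuals per bulk.
#' @param generation selfed generation k >= 2 shared by both bulks.
#' @export
runTwoBulk <- function(vcf, parent, bulk1, bulk2, n1, n2, generation,
                       outDir, genome = NULL, param = filterParam(),
                       windowBp = 2e6, stepBp = 1e5, minVariants = 3L,
                       levels = c(0.95, 0.99), reps = 10000L, seed = 42L,
                       depthCap = 400L, correction = NULL) {
    if (generation < 2)
        stop("'generation' must be >= 2 (2 = F2)")
    designs <- list(bulkDesign(n1, generation), bulkDesign(n2, generation))
    .runPipeline(vcf, parent, bulks = c(bulk1, bulk2), designs = designs,
                 outDir = outDir, genome = genome, param = param,
                 windowBp = windowBp, stepBp = stepBp,
                 minVariants = minVariants, levels = levels, reps = reps,
                 seed = seed, depthCap = depthCap, correction = correction)
}

.runPipeline <- function(vcf, parent, bulks, designs, outDir, genome,
                         param, windowBp, stepBp, minVariants, levels,
                         reps, seed, depthCap, correction) {
    t0 <- proc.time()[["elapsed"]]
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    x <- readBsaVcf(vcf, parent, bulks)
    verdict <- applyFilters(x, param)
    counts <- filterSummary(verdict)
    if (sum(verdict$keep) == 0L)
        stop("no variants survive filtering; counts per reason: ",
             paste(names(counts), counts, sep = "=", collapse = ", "))
    y <- x[which(verdict$keep)]
    tab <- snpIndexTable(y)
    if (is.null(genome)) genome <- .genomeFromVariants(x)

    useLevels <- levels
    if (!is.null(correction))
        useLevels <- unname(correctedLevels(levels,
            correction$nChromosomes, correction$genomeSizeBp,
            correction$totalCM))

    depths <- if (length(bulks) == 1L)
        pmin(tab$DEPTH1, depthCap)
    else
        cbind(pmin(tab$DEPTH1, depthCap), pmin(tab$DEPTH2, depthCap))
    ci <- buildCITable(depths, designs, levels = useLevels, reps = reps,
                       seed = seed)
    ctab <- classifyVariants(tab, ci)
    win <- windowScan(tab, genome, windowBp = windowBp, stepBp = stepBp,
                      minVariants = minVariants, ciTable = ci)

    paths <- list(
        snpIndex = file.path(outDir, "snp_index.tsv"),
        windows = file.path(outDir, "windows.tsv"),
        ciTable = file.path(outDir, "ci_table.tsv"),
        candidates = file.path(outDir, "candidates.tsv"),
        plot = file.path(outDir, "scan.png"),
        log = file.path(outDir, "run_log.json"))
    writeSnpIndexTable(ctab, paths$snpIndex)
    .writeTsv(win, paths$windows)
    writeCITable(ci, paths$ciTable)
    candidateTable(ctab, level = min(ciLevels(ci)), file = paths$candidates)
    plotScan(tab, win, file = paths$plot)

    log <- list(
        mode = ifelse(length(bulks) == 1L, "onebulk", "twobulk"),
        vcf = vcf, parent = parent, bulks = as.list(bulks),
        designs = lapply(designs, function(d)
            list(n = d@n, generation = d@generation)),
        filter = as.list(c(
            minMQ = param@minMQ, minDepth = param@minDepth,
            maxDepth = param@maxDepth,
            strandBiasPhredMax = param@strandBiasPhredMax,
            minIndexEitherBulk = param@minIndexEitherBulk,
            excludeIndels = param@excludeIndels,
            parentHomRequired = param@parentHomRequired)),
        windowBp = windowBp, stepBp = stepBp, minVariants = minVariants,
        levels = as.list(levels), effectiveLevels = as.list(useLevels),
        reps = reps, seed = seed, depthCap = depthCap,
        correction = correction,
        filterCounts = as.list(counts),
        runtimeSec = round(proc.time()[["elapsed"]] - t0, 3))
    jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(list(paths = paths, variants = ctab, windows = win,
                   ciTable = ci, filterCounts = counts))
}

# genome from VCF contig headers, else last observed position per chrom
.genomeFromVariants <- function(x) {
    sl <- GenomeInfoDb::seqlengths(x@gr)
    if (any(is.na(sl))) {
        pos <- tapply(GenomicRanges::start(x@gr),
                      as.character(GenomeInfoDb::seqnames(x@gr)), max)
        sl[is.na(sl)] <- pos[names(sl)[is.na(sl)]]
    }
    genomeMap(names(sl), as.numeric(sl))
}
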