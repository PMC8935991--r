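#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges
NULL

#' Bulk design: pool size and cross generation
#'
#' Describes one sequenced bulk: how many segregating individuals were pooled
#' (`n`) and the selfed generation of the cross (`generation`; 2 means F2,
#' k means F_k with per-individual heterozygosity 0.5^(k-1)). Ploidy is
#' fixed at 2.
#'
#' @slot n integer(1), number of pooled individuals (>= 1).
#' @slot generation integer(1), selfed generation k (>= 2).
#' @export
setClass("BulkDesign",
    slots = c(n = "integer", generation = "integer"))

setValidity("BulkDesign", function(object) {
    msg <- character()
    if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
        msg <- c(msg, "'n' must be a single integer >= 1")
    if (length(object@generation) != 1L || is.na(object@generation) ||
        object@generation < 2L)
        msg <- c(msg, "'generation' must be a single integer >= 2 (F2 or later)")
    if (length(msg)) msg else TRUE
})

#' @param n number of pooled individuals.
#' @param generation selfed generation k (2 = F2). Default 2.
#' @rdname BulkDesign-class
#' @examples
#' bulkDesign(20)            # 20 F2 individuals (MutMap-style bulk)
#' bulkDesign(20, 6)         # 20 F6 RILs (QTL-seq RIL bulk)
#' @export
bulkDesign <- function(n, generation = 2L) {
    new("BulkDesign", n = as.integer(n), generation = as.integer(generation))
}

setMethod("show", "BulkDesign", function(object) {
    cat(sprintf("BulkDesign: n = %d individuals, generation = F%d (het = %.5g)\n",
        object@n, object@generation, 0.5^(object@generation - 1L)))
})

#' Genome metadata for window scans and multiple-testing correction
#'
#' Ordered chromosome names and lengths, plus the optional total genetic map
#' length in centimorgans needed by [correctedLevels()].
#'
#' @slot chrom character, chromosome names.
#' @slot length numeric, chromosome lengths in bp.
#' @slot totalCM numeric(1), total map length in cM (NA if unknown).
#' @export
setClass("GenomeMap",
    slots = c(chrom = "character", length = "numeric", totalCM = "numeric"))

setValidity("GenomeMap", function(object) {
    msg <- character()
    if (length(object@chrom) != length(object@length))
        msg <- c(msg, "'chrom' and 'length' must have equal length")
    if (anyDuplicated(object@chrom))
        msg <- c(msg, "duplicated chromosome names")
    if (any(object@length < 1))
        msg <- c(msg, "chromosome lengths must be >= 1 bp")
    if (length(object@totalCM) != 1L)
        msg <- c(msg, "'totalCM' must be a single value (possibly NA)")
    if (length(msg)) msg else TRUE
})

#' @param chrom chromosome names, or a named numeric vector of lengths.
#' @param length chromosome lengths in bp (omit when `chrom` is named).
#' @param totalCM total genetic map length in centimorgans, if known.
#' @rdname GenomeMap-class
#' @examples
#' genomeMap(c(chr1 = 10e6, chr2 = 10e6), totalCM = 80)
#' @export
genomeMap <- function(chrom, length = NULL, totalCM = NA_real_) {
    if (is.null(length)) {
        stopifnot(is.numeric(chrom), !is.null(names(chrom)))
        length <- unname(as.numeric(chrom))
        chrom <- names(chrom)
    }
    new("GenomeMap", chrom = as.character(chrom),
        length = as.numeric(length), totalCM = as.numeric(totalCM))
}

setMethod("show", "GenomeMap", function(object) {
    cat(sprintf("GenomeMap: %d chromosome(s), %.4g bp total, totalCM = %s\n",
        length(object@chrom), sum(object@length),
        ifelse(is.na(object@totalCM), "NA", format(object@totalCM))))
})

#' Variant set for bulked-segregant analysis
#'
#' One record per VCF site with the parent call and one (MutMap mode) or two
#' (QTL-seq mode) bulk calls. Positions live in a GRanges; per-site REF, ALT
#' (all alternates preserved), QUAL, MQ and the raw ANN string are metadata
#' columns; per-sample genotype and allele depths (with per-strand counts
#' when the VCF carried ADF/ADR) are DataFrames aligned row-for-row with the
#' ranges.
#'
#' @slot gr GRanges of variant positions with mcols REF, ALT (CharacterList),
#'   QUAL, MQ, ANN.
#' @slot parent DataFrame with columns gt, adRef, adAlt, adfRef, adfAlt,
#'   adrRef, adrAlt.
#' @slot bulks list of 1 or 2 DataFrames with the same columns, named by
#'   sample.
#' @export
setClass("BsaVariants",
    slots = c(gr = "GRanges", parent = "DataFrame", bulks = "list"))

.callCols <- c("gt", "adRef", "adAlt", "adfRef", "adfAlt", "adrRef", "adrAlt")

setValidity("BsaVariants", function(object) {
    msg <- character()
    n <- length(object@gr)
    need <- c("REF", "ALT", "QUAL", "MQ", "ANN")
    if (!all(need %in% colnames(mcols(object@gr))))
        msg <- c(msg, paste("gr mcols must contain", paste(need, collapse = ", ")))
    if (!all(.callCols %in% colnames(object@parent)) || nrow(object@parent) != n)
        msg <- c(msg, "parent DataFrame malformed")
    if (!(length(object@bulks) %in% 1:2))
        msg <- c(msg, "must have 1 (one-bulk mode) or 2 (two-bulk mode) bulks")
    for (b in object@bulks)
        if (!all(.callCols %in% colnames(b)) || nrow(b) != n)
            msg <- c(msg, "bulk DataFrame malformed")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BsaVariants", function(object) {
    cat(sprintf("BsaVariants: %d variant(s), %s mode (%d bulk%s)\n",
        length(object@gr), bsaMode(object), length(object@bulks),
        ifelse(length(object@bulks) > 1L, "s", "")))
    cat("  seqnames:", paste(GenomeInfoDb::seqlevels(object@gr), collapse = ", "), "\n")
    cat("  bulks:", paste(names(object@bulks), collapse = ", "), "\n")
})

setMethod("length", "BsaVariants", function(x) length(x@gr))

setMethod("[", "BsaVariants", function(x, i, j, ..., drop = FALSE) {
    initialize(x, gr = x@gr[i], parent = x@parent[i, , drop = FALSE],
        bulks = lapply(x@bulks, function(b) b[i, , drop = FALSE]))
})

#' Depth-indexed confidence bounds for the null statistic
#'
#' Empirical quantile bounds of the SNP-index (one-bulk mode) or delta
#' SNP-index (two-bulk mode) under the no-linkage null, per read depth and
#' confidence level, from Monte-Carlo simulation ([buildCITable()]).
#'
#' @slot depths integer matrix, one row per table entry; 1 column (one-bulk)
#'   or 2 (two-bulk, per-bulk depths).
#' @slot levels numeric, confidence levels.
#' @slot lower,upper numeric matrices, rows matching `depths`, columns
#'   matching `levels`.
#' @slot designs list of 1 or 2 BulkDesign.
#' @slot reps integer(1), simulation replicates per depth.
#' @slot seed integer(1), RNG seed the table was built with.
#' @export
setClass("CITable",
    slots = c(depths = "matrix", levels = "numeric", lower = "matrix",
              upper = "matrix", designs = "list", reps = "integer",
              seed = "integer"))

setValidity("CITable", function(object) {
    msg <- character()
    if (!ncol(object@depths) %in% 1:2)
        msg <- c(msg, "'depths' must have 1 or 2 columns")
    if (length(object@designs) != ncol(object@depths))
        msg <- c(msg, "one BulkDesign per depth column required")
    d <- dim(object@lower)
    if (!identical(d, dim(object@upper)) ||
        d[1L] != nrow(object@depths) || d[2L] != length(object@levels))
        msg <- c(msg, "bound matrices must be depths x levels")
    if (any(object@lower > object@upper, na.rm = TRUE))
        msg <- c(msg, "lower bound exceeds upper bound")
    if (length(object@levels) > 1L) {
        o <- order(object@levels)
        # higher confidence must enclose lower at every depth
        lo <- object@lower[, o, drop = FALSE]; up <- object@upper[, o, drop = FALSE]
        for (j in seq_len(length(o) - 1L)) {
            if (any(lo[, j + 1L] > lo[, j] + 1e-12) ||
                any(up[, j + 1L] < up[, j] - 1e-12)) {
                msg <- c(msg, "bounds at a higher level must enclose lower-level bounds")
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CITable", function(object) {
    cat(sprintf(
        "CITable (%s): %d depth entr%s, levels %s, reps = %d, seed = %d\n",
        ifelse(ncol(object@depths) == 1L, "SNP-index", "delta SNP-index"),
        nrow(object@depths), ifelse(nrow(object@depths) == 1L, "y", "ies"),
        paste(object@levels, collapse = "/"), object@reps, object@seed))
})

#' Variant-filter thresholds
#'
#' Exclusion rules applied before SNP-index analysis. Every rule is
#' evaluated for every variant; see [applyFilters()] for the rejection
#' codes.
#'
#' @slot minMQ mapping-quality cutoff (INFO MQ; default 40).
#' @slot minDepth,maxDepth per-bulk depth bounds (defaults 8, 250).
#' @slot strandBiasPhredMax Phred-scaled Fisher strand-bias cutoff, applied
#'   only when per-strand depths are available (default 40).
#' @slot minIndexEitherBulk two-bulk spurious-SNP cutoff: reject when the
#'   SNP-index of every bulk is below this (default 0.3).
#' @slot excludeIndels drop non-SNP alleles (default TRUE).
#' @slot parentHomRequired drop parent-heterozygous sites (default TRUE).
#' @export
setClass("FilterParam",
    slots = c(minMQ = "numeric", minDepth = "numeric", maxDepth = "numeric",
              strandBiasPhredMax = "numeric", minIndexEitherBulk = "numeric",
              excludeIndels = "logical", parentHomRequired = "logical"))

setValidity("FilterParam", function(object) {
    msg <- character()
    if (object@minDepth < 0 || object@maxDepth < object@minDepth)
        msg <- c(msg, "need 0 <= minDepth <= maxDepth")
    if (object@minMQ < 0 || object@strandBiasPhredMax < 0 ||
        object@minIndexEitherBulk < 0)
        msg <- c(msg, "thresholds must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @param minMQ,minDepth,maxDepth,strandBiasPhredMax,minIndexEitherBulk
#'   numeric thresholds, see slots.
#' @param excludeIndels,parentHomRequired logical flags, see slots.
#' @rdname FilterParam-class
#' @export
filterParam <- function(minMQ = 40, minDepth = 8, maxDepth = 250,
                        strandBiasPhredMax = 40, minIndexEitherBulk = 0.3,
                        excludeIndels = TRUE, parentHomRequired = TRUE) {
    new("FilterParam", minMQ = minMQ, minDepth = minDepth, maxDepth = maxDepth,
        strandBiasPhredMax = strandBiasPhredMax,
        minIndexEitherBulk = minIndexEitherBulk,
        excludeIndels = excludeIndels, parentHomRequired = parentHomRequired)
}

setMethod("show", "FilterParam", function(object) {
    cat("FilterParam:\n")
    cat(sprintf("  minMQ = %g, depth in [%g, %g], strand-bias Phred <= %g\n",
        object@minMQ, object@minDepth, object@maxDepth,
        object@strandBiasPhredMax))
    cat(sprintf("  minIndexEitherBulk = %g, excludeIndels = %s, parentHomRequired = %s\n",
        object@minIndexEitherBulk, object@excludeIndels,
        object@parentHomRequired))
})

#' Synthetic cross scenario
#'
#' Everything needed to simulate a diploid biparental cross with a planted
#' causal locus, phenotype-selected bulk(s), Haldane linkage decay with
#' distance, and binomial read sampling; [writeScenarioVcf()] turns it into
#' a parent + bulk VCF plus a truth table.
#'
#' @slot genome GenomeMap.
#' @slot cmPerMb recombination rate (cM per Mb, default 4).
#' @slot causalChrom,causalPos the planted causal locus.
#' @slot mode "onebulk" (selected homozygous non-parental bulk) or "twobulk"
#'   (high vs low bulk fixed in opposite directions at the causal locus).
#' @slot designs list of BulkDesign, one per bulk.
#' @slot nVariants number of markers.
#' @slot placement "random" (uniform) or "grid" (evenly spaced).
#' @slot meanDepth,depthOverdispersion per-site sequencing depth model; with
#'   overdispersion 0 the depth is fixed at `meanDepth`, otherwise depth ~
#'   NegBin(mean = meanDepth, size = meanDepth/overdispersion), floored at 1.
#' @slot errorRate per-read miscall probability in [0, 0.1].
#' @slot seed integer RNG seed.
#' @export
setClass("BsaScenario",
    slots = c(genome = "GenomeMap", cmPerMb = "numeric",
              causalChrom = "character", causalPos = "numeric",
              mode = "character", designs = "list",
              nVariants = "integer", placement = "character",
              meanDepth = "numeric", depthOverdispersion = "numeric",
              errorRate = "numeric", seed = "integer"))

setValidity("BsaScenario", function(object) {
    msg <- character()
    i <- match(object@causalChrom, object@genome@chrom)
    if (is.na(i))
        msg <- c(msg, "causal chromosome not in genome")
    else if (object@causalPos < 1 || object@causalPos > object@genome@length[i])
        msg <- c(msg, "causal position outside its chromosome")
    if (!object@mode %in% c("onebulk", "twobulk"))
        msg <- c(msg, "mode must be 'onebulk' or 'twobulk'")
    if (length(object@designs) != ifelse(object@mode == "onebulk", 1L, 2L))
        msg <- c(msg, "number of designs must match mode")
    if (object@errorRate < 0 || object@errorRate > 0.1)
        msg <- c(msg, "errorRate must be in [0, 0.1]")
    if (!object@placement %in% c("random", "grid"))
        msg <- c(msg, "placement must be 'random' or 'grid'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BsaScenario", function(object) {
    cat(sprintf(
        "BsaScenario (%s): causal %s:%d, %d markers, depth ~ %g, seed %d\n",
        object@mode, object@causalChrom, as.integer(object@causalPos),
        object@nVariants, object@meanDepth, object@seed))
})
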