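#' SNP-index from allele depths
#'
#' The SNP-index of a bulk at a site is the fraction of reads carrying the
#' allele absent from the (homozygous) parent: `adAlt / (adRef + adAlt)`,
#' with depths already polarized so that "alt" is the non-parental allele.
#' 0.5 is expected at unlinked loci in an unselected F2 bulk; 1 at a causal
#' locus in a bulk selected homozygous for the non-parental allele.
#'
#' @param adRef,adAlt non-negative read counts; total depth must be >= 1 at
#'   every site (zero-depth sites must have been filtered).
#' @return values in \[0, 1\], vectorised.
#' @examples
#' snpIndex(0, 18)   # 1: every read carries the non-parental allele
#' snpIndex(10, 10)  # 0.5
#' @export
snpIndex <- function(adRef, adAlt) {
    depth <- adRef + adAlt
    if (any(is.na(depth)) || any(depth < 1))
        stop("SNP-index undefined at depth 0; filter such sites first")
    adAlt / depth
}

#' Delta SNP-index between two bulks
#'
#' Difference of SNP-indices, bulk1 minus bulk2 (bulk1 being the
#' first-configured bulk). 0 is expected under no linkage; +/-1 at a locus
#' fixed in opposite directions in the two bulks.
#'
#' @param index1,index2 SNP-indices in \[0, 1\].
#' @return values in \[-1, 1\], vectorised.
#' @export
deltaSnpIndex <- function(index1, index2) {
    stopifnot(all(index1 >= 0 & index1 <= 1, na.rm = TRUE),
              all(index2 >= 0 & index2 <= 1, na.rm = TRUE))
    index1 - index2
}

#' Per-variant SNP-index table
#'
#' Turns a (filtered) BsaVariants object into the tidy per-variant table
#' the downstream steps work on: CHROM, POS, REF, ALT, ANN, then per bulk
#' DEPTH<i> and SNP_INDEX<i>, and DELTA_SNP_INDEX in two-bulk mode.
#' Depths are polarized against the parent genotype (if the parent is
#' homozygous for the alternate allele, ref and alt depths swap roles so
#' the index always measures the non-parental allele).
#'
#' All variants must be biallelic with positive depth in every bulk —
#' i.e. [applyFilters()] verdicts already applied.
#'
#' @param x a filtered [BsaVariants-class] object.
#' @return a data.frame, one row per variant, ordered as in `x`.
#' @export
snpIndexTable <- function(x) {
    stopifnot(is(x, "BsaVariants"))
    mc <- mcols(x@gr)
    if (any(lengths(mc$ALT) != 1L))
        stop("multi-allelic records present; apply filters first")
    tab <- data.frame(
        CHROM = as.character(GenomeInfoDb::seqnames(x@gr)),
        POS = GenomicRanges::start(x@gr),
        REF = mc$REF,
        ALT = unlist(mc$ALT),
        ANN = mc$ANN,
        stringsAsFactors = FALSE)
    for (i in seq_len(nBulks(x))) {
        b <- x@bulks[[i]]
        depth <- b$adRef + b$adAlt
        alt <- .polarizedAlt(x@parent$gt, b$adRef, b$adAlt)
        ref <- depth - alt
        tab[[paste0("DEPTH", i)]] <- as.integer(depth)
        tab[[paste0("SNP_INDEX", i)]] <- snpIndex(ref, alt)
    }
    if (nBulks(x) == 2L)
        tab$DELTA_SNP_INDEX <- deltaSnpIndex(tab$SNP_INDEX1, tab$SNP_INDEX2)
    tab
}

#' Sliding-window genome scan
#'
#' Summarises per-variant statistics in sliding windows for the classic
#' genome-scan presentation. Windows are anchored at position 1 on every
#' chromosome and advance by `stepBp` (the final windows are truncated at
#' the chromosome end); a variant at position p belongs to the window
#' `[s, s + windowBp - 1]` iff `s <= p <= s + windowBp - 1`. Window means
#' are unweighted arithmetic means over member variants; windows with
#' fewer than `minVariants` members are emitted with `MASKED = TRUE` and
#' NA means. When a [CITable-class] is supplied, per-level bounds are
#' looked up at the (rounded) mean depth of each window.
#'
#' @param tab per-variant table from [snpIndexTable()], sorted by
#'   (CHROM, POS).
#' @param genome a [GenomeMap-class] providing chromosome lengths.
#' @param windowBp,stepBp window and step sizes in bp (defaults 2 Mb /
#'   100 kb); `windowBp >= stepBp >= 1`.
#' @param minVariants minimum variants per window for an unmasked mean
#'   (default 3).
#' @param ciTable optional [CITable-class] for per-window bounds.
#' @return a data.frame with one row per window: CHROM, START, END,
#'   CENTER, N_VARIANTS, per-bulk MEAN_DEPTH and MEAN_INDEX, MEAN_DELTA
#'   (two-bulk input), CI bound columns per level (if `ciTable`), MASKED.
#' @export
windowScan <- function(tab, genome, windowBp = 2e6, stepBp = 1e5,
                       minVariants = 3L, ciTable = NULL) {
    stopifnot(is(genome, "GenomeMap"), windowBp >= stepBp, stepBp >= 1)
    if (is.unsorted(order(match(tab$CHROM, genome@chrom), tab$POS)))
        stop("variant table must be sorted by (CHROM, POS)")
    twoBulk <- "DELTA_SNP_INDEX" %in% names(tab)

    # windows are anchored at 1 and advance by stepBp until the start
    # passes the chromosome end; trailing windows truncate at the end
    starts <- lapply(genome@length, function(len) seq(1, len, by = stepBp))
    win <- GRanges(rep(genome@chrom, lengths(starts)),
                   IRanges::IRanges(unlist(starts),
                       pmin(unlist(starts) + windowBp - 1,
                            rep(genome@length, lengths(starts)))))
    vGr <- GRanges(tab$CHROM, IRanges::IRanges(tab$POS, width = 1L))
    hits <- GenomicRanges::findOverlaps(win, vGr)
    grp <- factor(S4Vectors::queryHits(hits), levels = seq_along(win))

    meanBy <- function(v) {
        s <- tapply(v[S4Vectors::subjectHits(hits)], grp, mean)
        as.numeric(s)
    }
    nv <- as.integer(table(grp))
    out <- data.frame(
        CHROM = as.character(GenomeInfoDb::seqnames(win)),
        START = GenomicRanges::start(win),
        END = GenomicRanges::end(win),
        stringsAsFactors = FALSE)
    out$CENTER <- (out$START + out$END) / 2
    out$N_VARIANTS <- nv
    masked <- nv < minVariants
    nb <- if (twoBulk) 2L else 1L
    for (i in seq_len(nb)) {
        out[[paste0("MEAN_DEPTH", i)]] <- meanBy(tab[[paste0("DEPTH", i)]])
        out[[paste0("MEAN_INDEX", i)]] <- meanBy(tab[[paste0("SNP_INDEX", i)]])
    }
    if (twoBulk) out$MEAN_DELTA <- meanBy(tab$DELTA_SNP_INDEX)
    statCols <- grep("^MEAN_", names(out), value = TRUE)
    for (cc in statCols) out[[cc]][masked] <- NA_real_

    if (!is.null(ciTable)) {
        d <- round(cbind(out$MEAN_DEPTH1,
                         if (twoBulk) out$MEAN_DEPTH2 else NULL))
        bounds <- ciBoundsAt(ciTable, d, nearest = TRUE)
        for (lv in ciLevels(ciTable)) {
            tag <- .levelTag(lv)
            out[[paste0("CI_LOWER_", tag)]] <- bounds$lower[, as.character(lv)]
            out[[paste0("CI_UPPER_", tag)]] <- bounds$upper[, as.character(lv)]
        }
    }
    out$MASKED <- masked
    out
}

.levelTag <- function(level) sub("^0\\.", "", format(level))
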