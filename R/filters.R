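#' Phred-scaled Fisher strand-bias statistic
#'
#' Strand bias — imbalance of forward/reverse read support between the two
#' alleles — is a classic sequencing-artifact signature. The statistic is
#' -10 log10 of the two-sided Fisher exact test p-value on the 2x2 table
#' rows = (ref, alt), columns = (forward, reverse). When any table margin
#' is zero the test carries no information and 0 is returned (no evidence
#' of bias). Vectorised over the four count vectors.
#'
#' @param adfRef,adrRef,adfAlt,adrAlt non-negative per-strand read counts.
#' @return non-negative Phred-scaled values, one per site.
#' @examples
#' strandBiasPhred(10, 10, 9, 11)   # balanced: ~0
#' strandBiasPhred(20, 0, 0, 20)    # complete segregation: > 40
#' @export
strandBiasPhred <- function(adfRef, adrRef, adfAlt, adrAlt) {
    m <- cbind(adfRef, adrRef, adfAlt, adrAlt)
    if (any(is.na(m)))
        stop("strand counts must not be NA")
    if (any(m < 0))
        stop("strand counts must be non-negative")
    apply(m, 1L, function(v) {
        refTot <- v[1L] + v[2L]; altTot <- v[3L] + v[4L]
        fwdTot <- v[1L] + v[3L]; revTot <- v[2L] + v[4L]
        if (refTot == 0 || altTot == 0 || fwdTot == 0 || revTot == 0)
            return(0)
        p <- stats::fisher.test(matrix(v, nrow = 2L, byrow = TRUE))$p.value
        -10 * log10(max(p, .Machine$double.xmin))
    })
}

#' Apply the variant-level exclusion rules
#'
#' Evaluates every rule for every variant (no short-circuiting) and returns
#' a verdict table with a logical `keep` column and a `reasons` column
#' (CharacterList of machine-readable rejection codes). A variant is kept
#' iff its reason list is empty. Codes:
#'
#' * `MISSING_PARENT` — parent genotype missing or parent depth 0 (sites
#'   missing in the parental sample are always ignored);
#' * `PARENT_HET` — parent carries both alleles (only when
#'   `parentHomRequired`);
#' * `MULTIALLELIC` — more than one alternate allele;
#' * `INDEL` — ref or any alt allele longer than 1 bp (only when
#'   `excludeIndels`);
#' * `LOW_MQ` — INFO MQ below `minMQ` (sites without MQ pass);
#' * `STRAND_BIAS` — Phred-scaled Fisher strand bias above the cutoff in
#'   any bulk (only evaluated where per-strand depths are present);
#' * `LOW_DEPTH` / `HIGH_DEPTH` — any bulk depth outside
#'   `[minDepth, maxDepth]`;
#' * `LOW_INDEX_BOTH_BULKS` — two-bulk mode only: the SNP-index of every
#'   bulk is below `minIndexEitherBulk` (spurious-SNP rule).
#'
#' @param x a [BsaVariants-class] object.
#' @param param a [FilterParam-class]; defaults via [filterParam()].
#' @return a DataFrame with columns `keep` (logical) and `reasons`
#'   (CharacterList), one row per variant.
#' @examples
#' vcf <- system.file("extdata", "toy_mutmap.vcf", package = "BSAscan")
#' x <- readBsaVcf(vcf, parent = "PARENT", bulks = "BULK1")
#' v <- applyFilters(x)
#' table(v$keep)
#' @export
applyFilters <- function(x, param = filterParam()) {
    stopifnot(is(x, "BsaVariants"), is(param, "FilterParam"))
    n <- length(x)
    mc <- mcols(x@gr)
    p <- x@parent
    bulkDepth <- matrix(vapply(x@bulks, function(b)
        as.numeric(b$adRef + b$adAlt), numeric(n)), nrow = n)

    bad <- list()
    parentDepth <- p$adRef + p$adAlt
    bad$MISSING_PARENT <- is.na(p$gt) | parentDepth == 0L
    bad$PARENT_HET <- if (param@parentHomRequired)
        !is.na(p$gt) & .isHet(p$gt) else rep(FALSE, n)
    bad$MULTIALLELIC <- lengths(mc$ALT) > 1L
    bad$INDEL <- if (param@excludeIndels)
        nchar(mc$REF) > 1L |
            vapply(mc$ALT, function(a) any(nchar(a) > 1L), logical(1))
        else rep(FALSE, n)
    bad$LOW_MQ <- !is.na(mc$MQ) & mc$MQ < param@minMQ
    sb <- rep(FALSE, n)
    for (b in x@bulks) {
        hasStrand <- !is.na(b$adfRef) & !is.na(b$adrRef) &
            !is.na(b$adfAlt) & !is.na(b$adrAlt)
        if (any(hasStrand)) {
            phred <- strandBiasPhred(b$adfRef[hasStrand], b$adrRef[hasStrand],
                                     b$adfAlt[hasStrand], b$adrAlt[hasStrand])
            sb[hasStrand] <- sb[hasStrand] | phred > param@strandBiasPhredMax
        }
    }
    bad$STRAND_BIAS <- sb
    bad$LOW_DEPTH <- apply(bulkDepth < param@minDepth, 1L, any)
    bad$HIGH_DEPTH <- apply(bulkDepth > param@maxDepth, 1L, any)
    if (nBulks(x) == 2L) {
        idx <- vapply(x@bulks, function(b) {
            d <- b$adRef + b$adAlt
            alt <- .polarizedAlt(p$gt, b$adRef, b$adAlt)
            ifelse(d > 0L, alt / d, NA_real_)
        }, numeric(n))
        idx <- matrix(idx, nrow = n)
        bad$LOW_INDEX_BOTH_BULKS <-
            apply(idx < param@minIndexEitherBulk, 1L, all) %in% TRUE
    } else {
        bad$LOW_INDEX_BOTH_BULKS <- rep(FALSE, n)
    }

    codes <- names(bad)
    reasons <- IRanges::CharacterList(lapply(seq_len(n), function(i)
        codes[vapply(bad, `[`, logical(1), i)]))
    DataFrame(keep = lengths(reasons) == 0L, reasons = reasons)
}

#' Summarise filter verdicts
#'
#' Counts per rejection reason plus kept/total, suitable for the run log.
#'
#' @param verdict output of [applyFilters()].
#' @return named integer vector.
#' @export
filterSummary <- function(verdict) {
    codes <- sort(unique(unlist(verdict$reasons)))
    counts <- vapply(codes, function(cd)
        sum(vapply(verdict$reasons, function(r) cd %in% r, logical(1))),
        integer(1))
    c(TOTAL = nrow(verdict), KEPT = sum(verdict$keep), counts)
}

.isHet <- function(gt) {
    a <- .gtAlleles(gt)
    !is.na(a[, 1L]) & !is.na(a[, 2L]) & a[, 1L] != a[, 2L]
}

.isHomAlt <- function(gt) {
    a <- .gtAlleles(gt)
    !is.na(a[, 1L]) & !is.na(a[, 2L]) & a[, 1L] == a[, 2L] & a[, 1L] > 0L
}

# two allele indices from an unphased/phased diploid GT string
.gtAlleles <- function(gt) {
    parts <- strsplit(ifelse(is.na(gt), "./.", gt), "[/|]")
    t(vapply(parts, function(v) {
        v <- suppressWarnings(as.integer(v))
        c(v, NA_integer_, NA_integer_)[1:2]
    }, integer(2)))
}

# depth of the non-parental allele: when the parent is homozygous ALT the
# ref/alt roles are swapped so the index always tracks the allele the
# parent does not carry
.polarizedAlt <- function(parentGt, adRef, adAlt) {
    ifelse(.isHomAlt(parentGt), adRef, adAlt)
}
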