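#' Read a multi-sample VCF into a BsaVariants object
#'
#' Reads a VCF 4.x file (plain or bgzipped) produced by an upstream variant
#' caller (typically bcftools mpileup) and maps the configured samples onto
#' the parent / bulk roles of a bulked-segregant design. Every record is
#' kept in file order; filtering is a separate step ([applyFilters()]).
#'
#' Per sample the genotype (GT) and allele depths (AD, as ref then
#' alternates per the VCF spec) are extracted; per-strand depths (ADF/ADR)
#' are carried along when present, and when AD itself is absent it is
#' reconstructed as ADF + ADR. Records lacking any depth information for a
#' role get depth-0 calls (they are rejected downstream). Multi-allelic
#' records keep all alternate alleles in the ALT metadata column; the
#' per-sample `adAlt` is the depth of the first alternate (such records are
#' rejected by the MULTIALLELIC filter rule before any index is computed).
#' INFO fields MQ (mapping quality) and ANN (SnpEff annotation, raw string)
#' are honoured when present.
#'
#' @param file path to a VCF (.vcf or .vcf.gz); no index required.
#' @param parent sample name of the parent.
#' @param bulks character vector of 1 (MutMap mode) or 2 (QTL-seq mode)
#'   bulk sample names, in bulk1/bulk2 order.
#' @return a [BsaVariants-class] object.
#' @examples
#' vcf <- system.file("extdata", "toy_mutmap.vcf", package = "BSAscan")
#' readBsaVcf(vcf, parent = "PARENT", bulks = "BULK1")
#' @export
readBsaVcf <- function(file, parent, bulks) {
    stopifnot(length(parent) == 1L, length(bulks) %in% 1:2)
    vcf <- VariantAnnotation::readVcf(file)
    have <- colnames(vcf)
    roles <- c(parent, bulks)
    if (!all(roles %in% have))
        stop("sample(s) not in VCF header: ",
             paste(setdiff(roles, have), collapse = ", "),
             " (header has: ", paste(have, collapse = ", "), ")")
    if (anyDuplicated(roles))
        stop("parent and bulk samples must be distinct")

    gr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- .altList(vcf)
    qual <- as.numeric(VariantAnnotation::qual(vcf))
    info <- VariantAnnotation::info(vcf)
    mq <- if ("MQ" %in% colnames(info)) as.numeric(info$MQ) else
        rep(NA_real_, length(vcf))
    ann <- if ("ANN" %in% colnames(info))
        .collapseList(info$ANN) else rep(NA_character_, length(vcf))

    out <- GRanges(GenomeInfoDb::seqnames(gr), IRanges::ranges(gr))
    names(out) <- NULL
    mcols(out) <- DataFrame(REF = ref, ALT = alt, QUAL = qual, MQ = mq,
                            ANN = ann)
    new("BsaVariants", gr = out,
        parent = .sampleCalls(vcf, parent),
        bulks = stats::setNames(lapply(bulks, function(s)
            .sampleCalls(vcf, s)), bulks))
}

.altList <- function(vcf) {
    a <- VariantAnnotation::alt(vcf)
    if (is(a, "DNAStringSetList") || is(a, "CharacterList"))
        IRanges::CharacterList(lapply(a, as.character))
    else IRanges::CharacterList(as.list(as.character(a)))
}

.collapseList <- function(x) {
    if (is(x, "CharacterList") || is.list(x)) {
        out <- vapply(x, function(e)
            if (length(e) == 0L || all(is.na(e))) NA_character_
            else paste(e, collapse = ","), character(1))
        out
    } else as.character(x)
}

# one sample's GT + allele depths as a DataFrame aligned with the records
.sampleCalls <- function(vcf, sample) {
    n <- nrow(vcf)
    g <- VariantAnnotation::geno(vcf)
    gt <- if ("GT" %in% names(g)) as.character(g$GT[, sample]) else
        rep(NA_character_, n)
    gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
    na2 <- list(ref = rep(NA_integer_, n), alt = rep(NA_integer_, n))
    adf <- .alleleDepths(g, "ADF", sample, n) %||% na2
    adr <- .alleleDepths(g, "ADR", sample, n) %||% na2
    ad <- .alleleDepths(g, "AD", sample, n) %||% na2
    # records lacking AD fall back to DP4-style strand sums; with neither,
    # depth 0 (rejected downstream)
    zero <- function(v) { v[is.na(v)] <- 0L; v }
    for (al in c("ref", "alt")) {
        fromStrand <- is.na(ad[[al]]) & !(is.na(adf[[al]]) & is.na(adr[[al]]))
        ad[[al]][fromStrand] <- zero(adf[[al]])[fromStrand] +
            zero(adr[[al]])[fromStrand]
        ad[[al]] <- zero(ad[[al]])
    }
    DataFrame(gt = gt, adRef = ad$ref, adAlt = ad$alt,
              adfRef = adf$ref, adfAlt = adf$alt,
              adrRef = adr$ref, adrAlt = adr$alt)
}

# ref / first-alt depths (NA preserved) from a Number=R FORMAT field,
# which readVcf returns as a 3-d array or a matrix of lists
.alleleDepths <- function(g, field, sample, n) {
    if (!field %in% names(g)) return(NULL)
    x <- g[[field]]
    if (is.array(x) && length(dim(x)) == 3L) {
        list(ref = as.integer(x[, sample, 1L]),
             alt = as.integer(x[, sample, 2L]))
    } else {
        cells <- x[, sample]
        pick <- function(k) vapply(cells, function(v)
            if (length(v) >= k) as.integer(v[k]) else NA_integer_,
            integer(1))
        list(ref = unname(pick(1L)), alt = unname(pick(2L)))
    }
}

#' Write a SNP-index table as TSV
#'
#' Writes one row per variant with CHROM, POS, REF, ALT, then per-bulk
#' DEPTH and SNP_INDEX columns, DELTA_SNP_INDEX in two-bulk mode, and any
#' confidence-bound / flag columns present in the table. Floating-point
#' values are rendered with 4 decimal places. An empty table yields a
#' header-only file.
#'
#' @param tab a data.frame from [snpIndexTable()] (possibly after
#'   [classifyVariants()]).
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSnpIndexTable <- function(tab, file) {
    .writeTsv(tab, file)
}

.writeTsv <- function(tab, file) {
    out <- tab
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- sprintf("%.4f", out[[j]])
    utils::write.table(out, file = file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(file)
}
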