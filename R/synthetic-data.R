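#' Construct a synthetic cross scenario
#'
#' The default scenario is a desk-scale two-chromosome genome (10 Mb
#' carrying the causal locus at 5 Mb, plus a 10 Mb unlinked chromosome),
#' a single bulk of 20 selected F2 individuals sequenced at fixed depth
#' 100 with 2000 markers and no read errors — a miniature of a typical
#' MutMap experiment in which linkage decay, window scans and confidence
#' calls are all observable.
#'
#' @param genome a [GenomeMap-class]; default two 10 Mb chromosomes.
#' @param causalChrom,causalPos planted causal locus (default chr1:5e6).
#' @param mode "onebulk" or "twobulk".
#' @param designs list of [BulkDesign-class], one per bulk; default a
#'   single `bulkDesign(20)` (onebulk) or two (twobulk).
#' @param nVariants number of markers (default 2000). A marker is always
#'   placed at the causal position itself.
#' @param placement "random" (uniform over the genome) or "grid".
#' @param cmPerMb recombination rate, cM per Mb (default 4).
#' @param meanDepth mean per-sample depth (default 100).
#' @param depthOverdispersion 0 for fixed depth, otherwise negative
#'   binomial with size `meanDepth / depthOverdispersion`.
#' @param errorRate per-read miscall probability in \[0, 0.1\] (default 0).
#' @param seed RNG seed (default 1).
#' @return a [BsaScenario-class].
#' @export
bsaScenario <- function(genome = genomeMap(c(chr1 = 10e6, chr2 = 10e6)),
                        causalChrom = "chr1", causalPos = 5e6,
                        mode = c("onebulk", "twobulk"),
                        designs = NULL, nVariants = 2000L,
                        placement = c("random", "grid"),
                        cmPerMb = 4, meanDepth = 100,
                        depthOverdispersion = 0, errorRate = 0,
                        seed = 1L) {
    mode <- match.arg(mode)
    if (is.null(designs))
        designs <- if (mode == "onebulk") list(bulkDesign(20L))
                   else list(bulkDesign(20L), bulkDesign(20L))
    if (is(designs, "BulkDesign")) designs <- list(designs)
    new("BsaScenario", genome = genome, cmPerMb = cmPerMb,
        causalChrom = causalChrom, causalPos = as.numeric(causalPos),
        mode = mode, designs = designs, nVariants = as.integer(nVariants),
        placement = match.arg(placement), meanDepth = meanDepth,
        depthOverdispersion = depthOverdispersion, errorRate = errorRate,
        seed = as.integer(seed))
}

#' Haldane map function
#'
#' Recombination fraction for a map distance d in centimorgans under no
#' interference: `r = 0.5 * (1 - exp(-2 d / 100))`. r = 0 at d = 0 and
#' r -> 0.5 as d -> Inf (and for unlinked loci, d = Inf).
#'
#' @param dCM map distance in centimorgans (Inf for unlinked).
#' @return recombination fraction in \[0, 0.5\].
#' @examples
#' haldaneR(10)   # ~0.0906
#' @export
haldaneR <- function(dCM) {
    stopifnot(all(dCM >= 0))
    0.5 * (1 - exp(-2 * dCM / 100))
}

#' Expected non-parental allele frequency of a bulk at a marker
#'
#' Distance to the causal locus in cM is `cmPerMb` times the physical
#' distance (infinite across chromosomes); the recombination fraction r
#' comes from [haldaneR()]. A bulk fixed homozygous non-parental at the
#' causal locus carries the non-parental marker allele with frequency
#' 1 - r; in two-bulk mode the low bulk (fixed parental) carries it with
#' frequency r. Unlinked markers sit at 0.5 in every bulk.
#'
#' @param chrom,pos marker location(s), vectorised.
#' @param scenario a [BsaScenario-class].
#' @return matrix with one row per marker and one column per bulk.
#' @export
expectedBulkFreq <- function(chrom, pos, scenario) {
    r <- unname(.markerR(chrom, pos, scenario))
    f <- if (scenario@mode == "onebulk") cbind(1 - r) else cbind(1 - r, r)
    dimnames(f) <- NULL
    f
}

.markerR <- function(chrom, pos, scenario) {
    dCM <- ifelse(chrom == scenario@causalChrom,
                  scenario@cmPerMb * abs(pos - scenario@causalPos) / 1e6,
                  Inf)
    haldaneR(dCM)
}

#' Generate a synthetic parent + bulk VCF with truth table
#'
#' Simulates the experiment the scenario describes and writes (i) a VCF
#' 4.2 file with the parent and bulk samples (GT and AD FORMAT fields,
#' INFO MQ, the seed recorded as a `##bsaScanSeed` header comment) and
#' (ii) a tab-separated truth table (CHROM, POS, DIST_CM, TRUE_FREQ per
#' bulk).
#'
#' Sampling model: each bulked individual is fixed at the causal locus
#' (homozygous non-parental in the selected / high bulk, homozygous
#' parental in the low bulk); on the causal chromosome its two marker
#' alleles are drawn as independent gametes, each non-parental with
#' probability 1 - r (high) or r (low); on other chromosomes genotypes
#' follow the F_k segregation of [segregationProbs()]. The realised bulk
#' frequency f is the pooled allele frequency of the n simulated
#' individuals (a finite-bulk draw, not the expectation). Reads are then
#' Binomial(depth, f(1-e) + (1-f)e) for the non-parental allele with
#' per-read miscall rate e; the parent is always emitted homozygous
#' reference with ref-only depth.
#'
#' @param scenario a [BsaScenario-class].
#' @param vcfFile,truthFile output paths.
#' @return invisibly, a list with the two paths and the truth data.frame.
#' @examples
#' sc <- bsaScenario(nVariants = 50L, seed = 7L)
#' out <- writeScenarioVcf(sc, tempfile(fileext = ".vcf"), tempfile())
#' @export
writeScenarioVcf <- function(scenario, vcfFile, truthFile) {
    stopifnot(is(scenario, "BsaScenario"))
    g <- scenario@genome
    res <- .withSeed(scenario@seed, {
        mk <- .placeMarkers(scenario)
        r <- .markerR(mk$chrom, mk$pos, scenario)
        m <- nrow(mk)
        nb <- length(scenario@designs)
        freq <- matrix(NA_real_, m, nb)
        for (b in seq_len(nb)) {
            design <- scenario@designs[[b]]
            pNP <- if (scenario@mode == "twobulk" && b == 2L) r else 1 - r
            linked <- mk$chrom == scenario@causalChrom
            dosage <- numeric(m)
            # causal chromosome: two gametes per individual, each
            # non-parental with prob pNP
            dosage[linked] <- stats::rbinom(sum(linked), 2L * design@n,
                                            pNP[linked])
            # unlinked chromosomes: exact F_k genotype classes
            if (any(!linked)) {
                pr <- segregationProbs(design@generation)
                cls <- stats::rmultinom(sum(!linked), design@n, pr)
                dosage[!linked] <- 2 * cls[3L, ] + cls[2L, ]
            }
            freq[, b] <- dosage / (2 * design@n)
        }
        # per-sample per-site depths (parent first)
        depth <- matrix(.drawDepth(scenario, m * (nb + 1L)), m, nb + 1L)
        e <- scenario@errorRate
        altReads <- matrix(0L, m, nb)
        for (b in seq_len(nb))
            altReads[, b] <- stats::rbinom(m, depth[, b + 1L],
                                           freq[, b] * (1 - e) + (1 - freq[, b]) * e)
        alleles <- .drawAlleles(m)
        list(mk = mk, r = r, freq = freq, depth = depth,
             altReads = altReads, alleles = alleles)
    })

    nb <- length(scenario@designs)
    bulkNames <- paste0("BULK", seq_len(nb))
    samples <- c("PARENT", bulkNames)
    gtOf <- function(idx) ifelse(idx < 0.1, "0/0",
                          ifelse(idx > 0.9, "1/1", "0/1"))
    parentField <- paste0("0/0:", res$depth[, 1L], ",0")
    body <- cbind(res$mk$chrom, format(res$mk$pos, scientific = FALSE,
                                       trim = TRUE),
                  ".", res$alleles$ref, res$alleles$alt, "60", ".",
                  "MQ=60", "GT:AD", parentField)
    for (b in seq_len(nb)) {
        d <- res$depth[, b + 1L]
        a <- res$altReads[, b]
        body <- cbind(body, paste0(gtOf(a / d), ":", d - a, ",", a))
    }
    hdr <- c("##fileformat=VCFv4.2",
             "##source=BSAscan synthetic cross generator",
             paste0("##bsaScanSeed=", scenario@seed),
             sprintf("##contig=<ID=%s,length=%d>", g@chrom,
                     as.integer(g@length)),
             "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"RMS mapping quality\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, apply(body, 1L, paste, collapse = "\t")), vcfFile)

    truth <- data.frame(CHROM = res$mk$chrom, POS = res$mk$pos,
                        DIST_CM = ifelse(res$mk$chrom == scenario@causalChrom,
                            scenario@cmPerMb *
                                abs(res$mk$pos - scenario@causalPos) / 1e6,
                            Inf),
                        stringsAsFactors = FALSE)
    for (b in seq_len(nb))
        truth[[paste0("TRUE_FREQ", b)]] <- res$freq[, b]
    utils::write.table(truth, truthFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(vcf = vcfFile, truth = truthFile, truthTable = truth))
}

# marker positions: always includes the causal position itself
.placeMarkers <- function(scenario) {
    g <- scenario@genome
    m <- scenario@nVariants
    if (scenario@placement == "grid") {
        per <- pmax(1L, round(m * g@length / sum(g@length)))
        chrom <- rep(g@chrom, per)
        pos <- unlist(lapply(seq_along(g@chrom), function(i)
            unique(round(seq(1, g@length[i], length.out = per[i])))))
    } else {
        chrom <- sample(g@chrom, m, replace = TRUE,
                        prob = g@length / sum(g@length))
        pos <- floor(stats::runif(m, 1, chromLengths(g)[chrom] + 1))
    }
    df <- data.frame(chrom = chrom, pos = as.numeric(pos),
                     stringsAsFactors = FALSE)
    hit <- df$chrom == scenario@causalChrom & df$pos == scenario@causalPos
    if (!any(hit)) {
        onC <- which(df$chrom == scenario@causalChrom)
        repl <- if (length(onC)) onC[1L] else 1L
        df$chrom[repl] <- scenario@causalChrom
        df$pos[repl] <- scenario@causalPos
    }
    df <- unique(df[order(match(df$chrom, g@chrom), df$pos), ])
    rownames(df) <- NULL
    df
}

.drawDepth <- function(scenario, n) {
    if (scenario@depthOverdispersion <= 0)
        rep(as.integer(round(scenario@meanDepth)), n)
    else
        pmax(1L, stats::rnbinom(n, mu = scenario@meanDepth,
            size = scenario@meanDepth / scenario@depthOverdispersion))
}

.drawAlleles <- function(m) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    list(ref = ref, alt = unname(alt))
}
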