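# Independent oracles and tiny fixture builders used across the tests.
# These deliberately avoid the package's own code paths: the null
# distribution is enumerated exactly, Fisher p-values come from direct
# hypergeometric enumeration, and VCFs are assembled as literal text.

# exact one-bulk null distribution: probabilities over statistic values
# j/depth for a bulk of n F_k individuals sequenced at `depth`.
# Per-individual non-parental dosage is 0/1/2 with the F_k class
# probabilities; the bulk dosage is their n-fold convolution; reads are
# Binomial(depth, dosage/(2n)).
exactNullDist <- function(n, depth, generation = 2L) {
    het <- 0.5^(generation - 1L)
    perInd <- c(`0` = (1 - het) / 2, `1` = het, `2` = (1 - het) / 2)
    dos <- perInd
    if (n > 1L) for (i in seq_len(n - 1L)) {
        m <- outer(dos, perInd)
        idx <- outer(as.integer(names(dos)), 0:2, `+`)
        dos <- tapply(as.vector(m), as.vector(idx), sum)
    }
    pReads <- vapply(0:depth, function(j)
        sum(dos * stats::dbinom(j, depth, as.integer(names(dos)) / (2 * n))),
        numeric(1))
    data.frame(value = (0:depth) / depth, prob = pReads)
}

# two-sided Fisher exact p-value by full hypergeometric enumeration on
# the 2x2 table [[a, b], [c, d]] (sum of all tables with the fixed
# margins whose probability does not exceed the observed one)
fisherEnumP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    ks <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(ks, m, n, k)
    obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
}

# minimal VCF text builder: `rows` is a character vector of body lines
# (tab-separated, matching `samples`), written with a valid 4.2 header
writeTestVcf <- function(rows, samples = c("PARENT", "BULK1"),
                         contigs = c(chr1 = 10000000),
                         file = tempfile(fileext = ".vcf")) {
    hdr <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                as.integer(contigs)),
        "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"RMS mapping quality\">",
        "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward depths\">",
        "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse depths\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, rows), file)
    file
}

toyVcfPath <- function() {
    system.file("extdata", "toy_mutmap.vcf", package = "BSAscan")
}
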