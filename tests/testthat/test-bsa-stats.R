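test_that("SNP-index and delta are the documented depth fractions", {
    expect_equal(snpIndex(0, 18), 1)
    expect_equal(snpIndex(10, 10), 0.5)
    expect_equal(snpIndex(7, 3), 0.3)
    expect_equal(snpIndex(c(0, 5), c(10, 5)), c(1, 0.5))
    expect_error(snpIndex(0, 0), "depth 0")

    expect_equal(deltaSnpIndex(1, 0), 1)
    expect_equal(deltaSnpIndex(0.5, 0.5), 0)
    expect_equal(deltaSnpIndex(0.3, 0.8), -0.5)
    expect_error(deltaSnpIndex(1.2, 0))
})

test_that("indices are polarized against a homozygous-ALT parent", {
    # parent fixed for the alternate allele: the tracked (non-parental)
    # allele is REF, so a bulk fixed REF must score index 1
    f <- writeTestVcf(c(
        "chr1\t100\t.\tA\tG\t60\t.\tMQ=60\tGT:AD\t1/1:0,20\t0/0:18,0",
        "chr1\t200\t.\tC\tT\t60\t.\tMQ=60\tGT:AD\t0/0:20,0\t1/1:0,18"))
    x <- readBsaVcf(f, parent = "PARENT", bulks = "BULK1")
    tab <- snpIndexTable(x)
    expect_equal(tab$SNP_INDEX1, c(1, 1))
    expect_equal(tab$DEPTH1, c(18L, 18L))
})

test_that("window membership follows the hand-enumerated sliding scheme", {
    g <- genomeMap(c(chr1 = 6e6))
    tab <- data.frame(CHROM = "chr1", POS = c(100, 200, 5e6),
                      REF = "A", ALT = "G", ANN = NA_character_,
                      DEPTH1 = c(10L, 20L, 30L),
                      SNP_INDEX1 = c(0.2, 0.4, 1.0))
    w <- windowScan(tab, g, windowBp = 2e6, stepBp = 1e6, minVariants = 1L)
    # anchored at 1, stepping 1 Mb, trailing windows truncated at 6 Mb
    expect_equal(w$START, c(1, 1e6 + 1, 2e6 + 1, 3e6 + 1, 4e6 + 1, 5e6 + 1))
    expect_equal(w$END, c(2e6, 3e6, 4e6, 5e6, 6e6, 6e6))
    # first window [1, 2e6]: the two near variants only
    expect_equal(w$N_VARIANTS[1L], 2L)
    expect_equal(w$MEAN_INDEX1[1L], mean(c(0.2, 0.4)))
    expect_equal(w$MEAN_DEPTH1[1L], 15)
    # single-variant windows covering pos 5e6: mean equals that index
    hit <- w$START <= 5e6 & w$END >= 5e6 & w$N_VARIANTS == 1L
    expect_true(any(hit))
    expect_true(all(w$MEAN_INDEX1[hit] == 1.0))
})

test_that("interior variants fall in exactly ceil(window/step) windows", {
    g <- genomeMap(c(chr1 = 10e6))
    for (pos in c(3.5e6, 5e6, 7.123e6)) {
        tab <- data.frame(CHROM = "chr1", POS = pos, REF = "A", ALT = "G",
                          ANN = NA_character_, DEPTH1 = 10L, SNP_INDEX1 = 0.5)
        for (cfg in list(c(2e6, 1e6), c(2e6, 5e5), c(1e6, 1e6))) {
            w <- windowScan(tab, g, windowBp = cfg[1L], stepBp = cfg[2L],
                            minVariants = 1L)
            # brute-force membership over all emitted windows
            member <- sum(w$START <= pos & w$END >= pos & w$N_VARIANTS > 0)
            expect_equal(member, ceiling(cfg[1L] / cfg[2L]))
        }
    }
})

test_that("sparse windows are masked and empty chromosomes fully masked", {
    g <- genomeMap(c(chr1 = 4e6, chr2 = 4e6))
    tab <- data.frame(CHROM = "chr1", POS = c(1.1e6, 1.15e6, 1.2e6, 3.9e6),
                      REF = "A", ALT = "G", ANN = NA_character_,
                      DEPTH1 = 10L, SNP_INDEX1 = c(0.5, 0.6, 0.7, 1.0))
    w <- windowScan(tab, g, windowBp = 1e6, stepBp = 1e6, minVariants = 3L)
    chr2 <- w[w$CHROM == "chr2", ]
    expect_true(all(chr2$MASKED))
    expect_true(all(is.na(chr2$MEAN_INDEX1)))
    # the 3-variant window is unmasked; the singleton window is masked
    expect_false(w$MASKED[w$CHROM == "chr1" & w$START == 1e6 + 1])
    expect_true(w$MASKED[w$CHROM == "chr1" & w$START == 3e6 + 1])
    expect_error(windowScan(tab[c(2, 1, 3, 4), ], g), "sorted")
})

test_that("window means are order-invariant within a window", {
    g <- genomeMap(c(chr1 = 2e6))
    tab <- data.frame(CHROM = "chr1", POS = c(100, 200, 300),
                      REF = "A", ALT = "G", ANN = NA_character_,
                      DEPTH1 = c(10L, 20L, 30L),
                      SNP_INDEX1 = c(0.1, 0.5, 0.9))
    w1 <- windowScan(tab, g, windowBp = 1e6, stepBp = 1e6, minVariants = 1L)
    # same positions, the index values attached in a different order
    tab2 <- tab
    tab2$SNP_INDEX1 <- c(0.9, 0.1, 0.5)
    tab2$DEPTH1 <- c(30L, 10L, 20L)
    w2 <- windowScan(tab2, g, windowBp = 1e6, stepBp = 1e6, minVariants = 1L)
    expect_equal(w1$MEAN_INDEX1, w2$MEAN_INDEX1)
    expect_equal(w1$MEAN_DEPTH1, w2$MEAN_DEPTH1)
})
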