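test_that("toy fixture yields the documented per-record verdicts", {
    x <- readBsaVcf(toyVcfPath(), parent = "PARENT", bulks = "BULK1")
    v <- applyFilters(x)
    exp <- read.table(system.file("extdata", "toy_mutmap_expected.tsv",
                                  package = "BSAscan"),
                      header = TRUE, sep = "\t", comment.char = "#")
    expect_equal(v$keep, exp$KEEP)
    got <- vapply(as.list(v$reasons), function(r)
        if (length(r)) paste(r, collapse = ",") else ".", character(1))
    expect_equal(got, exp$REASONS)
    expect_equal(sum(v$keep), 2L)
    # keep is true iff the reason list is empty
    expect_equal(v$keep, lengths(v$reasons) == 0L)
})

test_that("all violated rules are reported, not just the first", {
    f <- writeTestVcf(
        "chr1\t100\t.\tA\tG\t60\t.\tMQ=20\tGT:AD\t0/0:20,0\t0/1:2,2")
    v <- applyFilters(readBsaVcf(f, parent = "PARENT", bulks = "BULK1"))
    expect_setequal(as.character(v$reasons[[1L]]), c("LOW_MQ", "LOW_DEPTH"))
})

test_that("two-bulk spurious-SNP rule fires only when every bulk index is low", {
    mk <- function(ad1, ad2) {
        f <- writeTestVcf(
            sprintf("chr1\t100\t.\tA\tG\t60\t.\tMQ=60\tGT:AD\t0/0:20,0\t0/1:%s\t0/1:%s",
                    ad1, ad2),
            samples = c("P", "B1", "B2"))
        applyFilters(readBsaVcf(f, parent = "P", bulks = c("B1", "B2")))
    }
    v <- mk("18,2", "16,4")        # indices 0.1 and 0.2: both < 0.3
    expect_true("LOW_INDEX_BOTH_BULKS" %in% v$reasons[[1L]])
    v <- mk("18,2", "10,10")       # 0.1 and 0.5: one bulk clears the bar
    expect_false("LOW_INDEX_BOTH_BULKS" %in% v$reasons[[1L]])
    # one-bulk mode: the rule never applies
    f <- writeTestVcf("chr1\t100\t.\tA\tG\t60\t.\tMQ=60\tGT:AD\t0/0:20,0\t0/1:18,2")
    v <- applyFilters(readBsaVcf(f, parent = "PARENT", bulks = "BULK1"))
    expect_false("LOW_INDEX_BOTH_BULKS" %in% v$reasons[[1L]])
})

test_that("kept set is threshold-driven, additive and order-independent", {
    x <- readBsaVcf(toyVcfPath(), parent = "PARENT", bulks = "BULK1")
    v <- applyFilters(x)
    s <- filterSummary(v)
    # each rejected fixture record violates exactly one rule, so the
    # per-reason counts add up to the rejected total
    expect_equal(sum(s[!names(s) %in% c("TOTAL", "KEPT")]),
                 s[["TOTAL"]] - s[["KEPT"]])
    # permuting the records permutes the verdicts identically
    perm <- c(7L, 3L, 10L, 1L, 5L, 9L, 2L, 8L, 4L, 6L)
    v2 <- applyFilters(x[perm])
    expect_equal(v2$keep, v$keep[perm])
    expect_equal(as.list(v2$reasons), as.list(v$reasons)[perm])
})

test_that("strand-bias statistic matches hypergeometric enumeration", {
    # balanced strands: essentially no signal
    expect_lt(strandBiasPhred(10, 10, 9, 11), 5)
    # complete strand segregation: far beyond the default cutoff
    expect_gt(strandBiasPhred(20, 0, 0, 20), 40)
    # any empty margin: statistic defined as 0
    expect_identical(strandBiasPhred(0, 0, 5, 5), 0)
    expect_identical(strandBiasPhred(5, 0, 5, 0), 0)

    set.seed(7)
    for (i in 1:25) {
        v <- rpois(4, 6)
        if (sum(v[1:2]) == 0 || sum(v[3:4]) == 0 ||
            v[1] + v[3] == 0 || v[2] + v[4] == 0) next
        expect_equal(strandBiasPhred(v[1], v[2], v[3], v[4]),
                     -10 * log10(fisherEnumP(v[1], v[2], v[3], v[4])),
                     tolerance = 1e-6)
    }
})

test_that("strand-bias statistic is symmetric in rows and columns", {
    set.seed(11)
    for (i in 1:20) {
        v <- rpois(4, 8) + 1
        base <- strandBiasPhred(v[1], v[2], v[3], v[4])
        expect_equal(strandBiasPhred(v[3], v[4], v[1], v[2]), base) # ref<->alt
        expect_equal(strandBiasPhred(v[2], v[1], v[4], v[3]), base) # fwd<->rev
    }
    expect_error(strandBiasPhred(-1, 2, 3, 4), "non-negative")
})

test_that("filter thresholds are configurable", {
    x <- readBsaVcf(toyVcfPath(), parent = "PARENT", bulks = "BULK1")
    lax <- filterParam(minMQ = 10, minDepth = 1, maxDepth = 1000,
                       strandBiasPhredMax = 1000, parentHomRequired = FALSE,
                       excludeIndels = FALSE)
    v <- applyFilters(x, lax)
    # only the structurally unusable records remain excluded
    expect_setequal(unique(unlist(v$reasons)),
                    c("MISSING_PARENT", "MULTIALLELIC"))
    expect_error(filterParam(minDepth = 10, maxDepth = 5), "minDepth")
})
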