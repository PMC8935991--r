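test_that("segregation probabilities follow the selfing recurrence", {
    expect_equal(segregationProbs(2),
                 c(pHomParent = 0.25, pHet = 0.5, pHomNonparent = 0.25))
    expect_equal(segregationProbs(6)[["pHet"]], 0.03125)
    # recurrence h_{k+1} = h_k / 2 from h_2 = 0.5
    h <- 0.5
    for (k in 3:10) {
        h <- h / 2
        expect_equal(segregationProbs(k)[["pHet"]], h)
    }
    # fully inbred limit
    pInf <- segregationProbs(40)
    expect_equal(unname(pInf), c(0.5, 0, 0.5), tolerance = 1e-10)
    expect_equal(sum(segregationProbs(5)), 1)
    expect_error(segregationProbs(1), ">= 2")
})

test_that("simulated bulk frequencies have the exact mean and variance", {
    set.seed(101)
    f <- sampleBulkFreq(bulkDesign(20, 2), reps = 50000)
    expect_true(all(f >= 0 & f <= 1))
    expect_lt(abs(mean(f) - 0.5), 3 * sd(f) / sqrt(length(f)))
    # per-individual allele fraction in {0, 0.5, 1} w.p. (1/4, 1/2, 1/4):
    # Var(one individual) = 0.125, bulk of n averages n of them
    expect_equal(var(f), 0.125 / 20, tolerance = 0.05)
    # a single fully inbred line is homozygous: frequency 0 or 1 only
    f1 <- sampleBulkFreq(bulkDesign(1, 30), reps = 2000)
    expect_true(all(f1 %in% c(0, 1)))
    expect_equal(mean(f1), 0.5, tolerance = 0.05)
})

test_that("null statistic matches exact enumeration at desk scale", {
    # depth 1, n = 1, F2: P(read is non-parental) = E[p] = 0.5 exactly
    set.seed(5)
    s <- simulateNullStatistic(1, bulkDesign(1, 2), reps = 40000)
    expect_true(all(s %in% c(0, 1)))
    expect_lt(abs(mean(s == 1) - 0.5), 3 * sqrt(0.25 / length(s)))

    # small designs vs full genotype x binomial enumeration
    set.seed(6)
    for (cfg in list(c(1, 2), c(2, 2), c(2, 3))) {
        n <- cfg[1L]; depth <- cfg[2L]
        s <- simulateNullStatistic(depth, bulkDesign(n, 2), reps = 1e5)
        exact <- exactNullDist(n, depth, 2L)
        emp <- as.numeric(table(factor(round(s * depth), levels = 0:depth))) /
            length(s)
        tv <- 0.5 * sum(abs(emp - exact$prob))
        expect_lt(tv, 0.01)
    }
})

test_that("two-bulk null statistic is symmetric and centred at zero", {
    set.seed(9)
    designs <- list(bulkDesign(20, 6), bulkDesign(20, 6))
    s <- simulateNullStatistic(c(80, 120), designs, reps = 50000)
    expect_true(all(s >= -1 & s <= 1))
    expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(length(s)))
    # distributional symmetry about 0
    qs <- quantile(s, c(0.05, 0.25, 0.75, 0.95))
    expect_equal(unname(qs[1] + qs[4]), 0, tolerance = 0.02)
    expect_equal(unname(qs[2] + qs[3]), 0, tolerance = 0.02)
})

test_that("CI tables nest, stay in range, narrow with depth, reproduce", {
    d <- c(10L, 50L, 200L)
    ci <- buildCITable(d, bulkDesign(20, 2), levels = c(0.95, 0.99),
                       reps = 5000, seed = 3L)
    b <- ciBoundsAt(ci, d)
    expect_true(all(b$lower >= 0 & b$upper <= 1))
    # 99% bounds enclose 95% bounds at every depth
    expect_true(all(b$lower[, "0.99"] <= b$lower[, "0.95"]))
    expect_true(all(b$upper[, "0.99"] >= b$upper[, "0.95"]))
    # read-sampling variance shrinks ~1/depth: intervals narrow
    width95 <- b$upper[, "0.95"] - b$lower[, "0.95"]
    expect_true(all(diff(width95) < 0))

    ci2 <- buildCITable(d, bulkDesign(20, 2), levels = c(0.95, 0.99),
                        reps = 5000, seed = 3L)
    expect_identical(ci@lower, ci2@lower)
    expect_identical(ci@upper, ci2@upper)

    expect_error(buildCITable(10, bulkDesign(20), levels = 0.999,
                              reps = 100), "reps too small")
    expect_error(buildCITable(cbind(10, 10), bulkDesign(20)), "match")
})

test_that("depth lookup caps at the table maximum and honours exactness", {
    ci <- buildCITable(c(20L, 100L), bulkDesign(20, 2), reps = 2000,
                       seed = 1L)
    b <- ciBoundsAt(ci, c(100, 500))      # 500 capped to the deepest entry
    expect_equal(b$lower[1L, ], b$lower[2L, ])
    expect_error(ciBoundsAt(ci, 60), "not covered")
    bN <- ciBoundsAt(ci, 60, nearest = TRUE)
    expect_true(all(!is.na(bN$lower)))
    expect_true(all(is.na(ciBoundsAt(ci, NA_real_, nearest = TRUE)$lower)))
})

test_that("classification flags strictly-outside statistics only", {
    ci <- buildCITable(20L, bulkDesign(20, 2), levels = 0.95,
                       reps = 5000, seed = 8L)
    b <- ciBoundsAt(ci, 20)
    tab <- data.frame(CHROM = "chr1", POS = c(1, 2, 3, 4),
                      DEPTH1 = 20L,
                      SNP_INDEX1 = c(1.0, 0.5, b$upper[1L], b$lower[1L]))
    out <- classifyVariants(tab, ci)
    expect_true(out$FLAGGED_95[1L])         # far outside
    expect_false(out$FLAGGED_95[2L])        # the centre of the null
    expect_false(out$FLAGGED_95[3L])        # exactly on a bound
    expect_false(out$FLAGGED_95[4L])
    # 0.5 is never flagged whatever the depth or design
    for (d in c(10L, 100L)) {
        cid <- buildCITable(d, bulkDesign(5, 4), levels = 0.95,
                            reps = 3000, seed = 2L)
        mid <- classifyVariants(
            data.frame(CHROM = "c", POS = 1, DEPTH1 = d, SNP_INDEX1 = 0.5),
            cid)
        expect_false(mid$FLAGGED_95)
    }
})

test_that("Sidak correction is exact, monotone and demands its inputs", {
    expect_equal(unname(correctedLevels(c(0.95, 0.99), 1, 1e6, 40)),
                 c(0.95, 0.99))
    # alpha' = 1 - 0.95^(1/2) for m = 2
    lv <- correctedLevels(0.95, nChromosomes = 2, genomeSizeBp = 1e8,
                          totalCM = 100)
    expect_equal(unname(1 - lv), 1 - 0.95^(1 / 2), tolerance = 1e-12)
    # alpha' strictly decreasing in m (driven by totalCM here)
    alphas <- vapply(c(100, 200, 400, 800), function(cm)
        1 - unname(correctedLevels(0.95, 1, 1e8, cm)), numeric(1))
    expect_true(all(diff(alphas) < 0))
    # m rule: never below the chromosome count
    expect_equal(effectiveTests(12, 4e8, 100), 12L)
    expect_equal(effectiveTests(2, 4e8, 1500), 30L)
    expect_error(correctedLevels(0.95, NULL, 1e8, 100), "unavailable")
    expect_error(correctedLevels(0.95, 12, NA, 1500), "unavailable")
})

test_that("CI tables survive the TSV cache round trip", {
    ci <- buildCITable(c(15L, 60L), bulkDesign(10, 2),
                       levels = c(0.95, 0.99), reps = 2000, seed = 21L)
    f <- tempfile(fileext = ".tsv")
    writeCITable(ci, f)
    ci2 <- readCITable(f)
    expect_equal(ci2@lower, ci@lower)
    expect_equal(ci2@upper, ci@upper)
    expect_identical(ci2@depths, ci@depths)
    expect_equal(ci2@levels, ci@levels)
    expect_identical(ci2@seed, ci@seed)
    expect_identical(vapply(ci2@designs, function(d) d@n, integer(1)),
                     vapply(ci@designs, function(d) d@n, integer(1)))
})
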