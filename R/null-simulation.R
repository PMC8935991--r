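#' Genotype probabilities for one F_k individual at an unlinked locus
#'
#' Under selfing from an F1, per-individual heterozygosity halves each
#' generation: `pHet = 0.5^(k-1)`; the two homozygote classes are equal by
#' symmetry. F2 gives the Mendelian (0.25, 0.5, 0.25); k -> Inf gives fully
#' inbred lines (0.5, 0, 0.5).
#'
#' @param generation selfed generation k >= 2 (2 = F2).
#' @return named numeric: `pHomParent`, `pHet`, `pHomNonparent`.
#' @examples
#' segregationProbs(2)  # 0.25 / 0.5 / 0.25
#' segregationProbs(6)  # het = 0.03125 (F6 RILs)
#' @export
segregationProbs <- function(generation) {
    generation <- as.integer(generation)
    if (length(generation) != 1L || is.na(generation) || generation < 2L)
        stop("'generation' must be a single integer >= 2")
    pHet <- 0.5^(generation - 1L)
    c(pHomParent = (1 - pHet) / 2, pHet = pHet,
      pHomNonparent = (1 - pHet) / 2)
}

#' Simulate the non-parental allele frequency of a null bulk
#'
#' Draws the genotypes of `n` pooled individuals at an unlinked locus from
#' [segregationProbs()] and returns the non-parental allele frequency in
#' the pooled 2n chromosomes. Phenotypic selection plays no role here: at
#' a locus unlinked to the causal one, selection does not distort
#' segregation, which is exactly the null being simulated.
#'
#' @param design a [BulkDesign-class].
#' @param reps number of independent bulk draws.
#' @return numeric vector of length `reps`, values in \[0, 1\].
#' @export
sampleBulkFreq <- function(design, reps = 1L) {
    stopifnot(is(design, "BulkDesign"))
    pr <- segregationProbs(design@generation)
    counts <- stats::rmultinom(reps, design@n, pr)
    (2 * counts[3L, ] + counts[2L, ]) / (2 * design@n)
}

#' Simulate the null distribution of the (delta) SNP-index
#'
#' One replicate draws a fresh bulk allele frequency p with
#' [sampleBulkFreq()] and then the sequenced reads as Binomial(depth, p);
#' the statistic is the read fraction (SNP-index). In two-bulk mode both
#' bulks are drawn independently at their own depths and the statistic is
#' the difference (delta SNP-index). This is the simulation behind the
#' depth-dependent confidence intervals: no distributional assumption is
#' placed on the SNP-index itself.
#'
#' @param depth per-bulk read depth: a single value (one-bulk mode) or a
#'   length-2 vector (two-bulk mode).
#' @param designs a [BulkDesign-class] (one-bulk) or list of two (two-bulk,
#'   matching `depth`).
#' @param reps number of replicates.
#' @return numeric vector of `reps` statistic values: in \[0, 1\]
#'   (one-bulk) or \[-1, 1\] (two-bulk).
#' @examples
#' x <- simulateNullStatistic(100, bulkDesign(20), reps = 1000)
#' mean(x)   # ~0.5: the null is centred
#' @export
simulateNullStatistic <- function(depth, designs, reps) {
    if (is(designs, "BulkDesign")) designs <- list(designs)
    stopifnot(length(depth) == length(designs), length(designs) %in% 1:2,
              all(depth >= 1), reps >= 1)
    one <- function(d, design) {
        p <- sampleBulkFreq(design, reps)
        stats::rbinom(reps, d, p) / d
    }
    if (length(designs) == 1L)
        one(depth[1L], designs[[1L]])
    else
        one(depth[1L], designs[[1L]]) - one(depth[2L], designs[[2L]])
}

#' Build a depth-indexed confidence-interval table
#'
#' For every requested depth (one-bulk) or per-bulk depth pair (two-bulk),
#' simulates the null statistic and stores the `(1-L)/2` and `1-(1-L)/2`
#' empirical quantiles for each confidence level L. The table is
#' deterministic given `seed` (built in sorted-depth order) and can be
#' cached via [writeCITable()] / [readCITable()]. Variants deeper than the
#' deepest table entry are classified against that entry, which is
#' conservative.
#'
#' @param depths integer vector of depths (one-bulk) or a 2-column matrix
#'   of per-bulk depth pairs (two-bulk); duplicates are collapsed.
#' @param designs a [BulkDesign-class] or list of two.
#' @param levels confidence levels in (0, 1); default `c(0.95, 0.99)`.
#' @param reps simulation replicates per depth (default 10000); must
#'   satisfy `reps * (1 - max(levels)) / 2 >= 1` so the extreme quantiles
#'   are estimable.
#' @param seed RNG seed recorded in the table.
#' @return a [CITable-class].
#' @examples
#' ci <- buildCITable(c(50, 100), bulkDesign(20), reps = 2000, seed = 1)
#' ciBoundsAt(ci, 100)
#' @export
buildCITable <- function(depths, designs, levels = c(0.95, 0.99),
                         reps = 10000L, seed = 42L) {
    if (is(designs, "BulkDesign")) designs <- list(designs)
    stopifnot(length(designs) %in% 1:2,
              all(levels > 0 & levels < 1), length(levels) >= 1)
    reps <- as.integer(reps)
    if (any(reps * (1 - levels) / 2 < 1))
        stop("reps too small to estimate the ", max(levels),
             " quantiles; increase reps")
    d <- if (is.matrix(depths)) depths else matrix(as.numeric(depths), ncol = 1L)
    if (ncol(d) != length(designs))
        stop("depth columns must match the number of bulk designs ",
             "(one-bulk: vector; two-bulk: 2-column matrix)")
    if (any(d < 1)) stop("depths must be >= 1")
    d <- unique(d[order(d[, 1L], d[, ncol(d)]), , drop = FALSE])
    storage.mode(d) <- "integer"

    levels <- sort(levels)
    probs <- c((1 - levels) / 2, rev(1 - (1 - levels) / 2))
    lower <- matrix(NA_real_, nrow(d), length(levels))
    upper <- matrix(NA_real_, nrow(d), length(levels))
    .withSeed(seed, {
        for (i in seq_len(nrow(d))) {
            s <- simulateNullStatistic(d[i, ], designs, reps)
            q <- stats::quantile(s, probs = probs, names = FALSE)
            lower[i, ] <- q[seq_along(levels)]
            upper[i, ] <- rev(q[length(levels) + seq_along(levels)])
        }
    })
    # enforce nesting exactly (empirical quantiles can cross by MC noise)
    if (length(levels) > 1L)
        for (j in seq_len(length(levels) - 1L)) {
            lower[, j + 1L] <- pmin(lower[, j + 1L], lower[, j])
            upper[, j + 1L] <- pmax(upper[, j + 1L], upper[, j])
        }
    new("CITable", depths = d, levels = levels, lower = lower, upper = upper,
        designs = designs, reps = reps, seed = as.integer(seed))
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Look up confidence bounds by depth
#'
#' Finds table rows for the given depths. Depths above the table maximum
#' are capped to the deepest entry; otherwise an exact match is required
#' unless `nearest = TRUE`, in which case the closest tabulated depth is
#' used (as for window mean depths). NA depths yield NA bounds.
#'
#' @param ciTable a [CITable-class].
#' @param depths vector (one-bulk) or 2-column matrix (two-bulk) of depths.
#' @param nearest use the nearest tabulated depth instead of requiring an
#'   exact match.
#' @return list with `lower` and `upper` matrices (rows = depths, columns
#'   named by level).
#' @export
ciBoundsAt <- function(ciTable, depths, nearest = FALSE) {
    stopifnot(is(ciTable, "CITable"))
    d <- if (is.matrix(depths)) depths else matrix(as.numeric(depths), ncol = 1L)
    if (ncol(d) != ncol(ciTable@depths))
        stop("depth columns do not match the table's mode")
    tabd <- ciTable@depths
    maxd <- apply(tabd, 2L, max)
    d <- pmin(d, matrix(maxd, nrow(d), ncol(d), byrow = TRUE))
    key <- function(m) do.call(paste, c(as.data.frame(m), sep = ":"))
    idx <- match(key(d), key(tabd))
    bad <- which(is.na(idx) & !apply(is.na(d), 1L, any))
    if (length(bad)) {
        if (!nearest)
            stop("depth(s) not covered by the CI table: ",
                 paste(utils::head(key(d)[bad], 5L), collapse = ", "))
        for (i in bad)
            idx[i] <- which.min(rowSums(abs(
                tabd - matrix(d[i, ], nrow(tabd), ncol(tabd), byrow = TRUE))))
    }
    lv <- as.character(ciTable@levels)
    lower <- ciTable@lower[idx, , drop = FALSE]
    upper <- ciTable@upper[idx, , drop = FALSE]
    dimnames(lower) <- dimnames(upper) <- list(NULL, lv)
    list(lower = lower, upper = upper)
}

#' Flag variants outside the null confidence bounds
#'
#' For each confidence level in the table, a variant is flagged iff its
#' observed statistic (SNP-index in one-bulk mode, delta SNP-index in
#' two-bulk mode) lies strictly outside the `[lower, upper]` bounds at its
#' read depth; a value exactly on a bound is not flagged.
#'
#' @param tab per-variant table from [snpIndexTable()].
#' @param ciTable a [CITable-class] covering the observed (capped) depths.
#' @return `tab` with added `CI_LOWER_*` / `CI_UPPER_*` and logical
#'   `FLAGGED_*` columns per level.
#' @export
classifyVariants <- function(tab, ciTable) {
    twoBulk <- ncol(ciTable@depths) == 2L
    if (twoBulk && !"DELTA_SNP_INDEX" %in% names(tab))
        stop("two-bulk CI table but no DELTA_SNP_INDEX column")
    stat <- if (twoBulk) tab$DELTA_SNP_INDEX else tab$SNP_INDEX1
    d <- if (twoBulk) cbind(tab$DEPTH1, tab$DEPTH2) else tab$DEPTH1
    bounds <- ciBoundsAt(ciTable, d)
    for (lv in ciLevels(ciTable)) {
        tag <- .levelTag(lv)
        lo <- bounds$lower[, as.character(lv)]
        up <- bounds$upper[, as.character(lv)]
        tab[[paste0("CI_LOWER_", tag)]] <- lo
        tab[[paste0("CI_UPPER_", tag)]] <- up
        tab[[paste0("FLAGGED_", tag)]] <- stat < lo | stat > up
    }
    tab
}

#' Effective number of independent tests for a genome scan
#'
#' Loci separated by roughly 50 cM or more segregate near-independently,
#' so the genetic map supports about `totalCM / 50` independent tests, and
#' never fewer than one per chromosome:
#' `m = max(nChromosomes, round(totalCM / 50))`. Isolated here so an
#' alternative rule can be swapped in.
#'
#' @param nChromosomes,genomeSizeBp,totalCM genome facts; all three are
#'   required (the correction is unavailable without them).
#' @return integer m >= 1.
#' @export
effectiveTests <- function(nChromosomes, genomeSizeBp, totalCM) {
    if (is.null(nChromosomes) || is.null(genomeSizeBp) || is.null(totalCM) ||
        any(is.na(c(nChromosomes, genomeSizeBp, totalCM))))
        stop("multiple-testing correction needs the number of chromosomes, ",
             "the genome size and the total centimorgans; it is unavailable ",
             "when any of these is unknown")
    if (any(c(nChromosomes, genomeSizeBp, totalCM) <= 0))
        stop("correction inputs must be positive")
    m <- max(as.numeric(nChromosomes), round(totalCM / 50))
    if (m < 1) stop("effective number of tests must be >= 1")
    as.integer(m)
}

#' Sidak-adjusted confidence levels for multiple testing
#'
#' Converts genome-wide confidence levels to per-test levels: with
#' per-test tail mass `alpha' = 1 - (1 - alpha)^(1/m)` (Sidak), the
#' adjusted level is `1 - alpha'`. With m = 1 the levels are unchanged;
#' alpha' strictly decreases in m.
#'
#' @param levels base confidence levels in (0, 1).
#' @param nChromosomes,genomeSizeBp,totalCM genome facts passed to
#'   [effectiveTests()].
#' @return adjusted levels, named by the base levels.
#' @examples
#' correctedLevels(0.95, nChromosomes = 2, genomeSizeBp = 4e8, totalCM = 100)
#' @export
correctedLevels <- function(levels, nChromosomes, genomeSizeBp, totalCM) {
    stopifnot(all(levels > 0 & levels < 1))
    m <- effectiveTests(nChromosomes, genomeSizeBp, totalCM)
    alpha <- 1 - levels
    alphaPrime <- 1 - (1 - alpha)^(1 / m)
    stats::setNames(1 - alphaPrime, format(levels))
}

#' Export / import a CI table as TSV
#'
#' Cached tables carry DEPTH (or DEPTH1/DEPTH2), LEVEL, LOWER, UPPER, one
#' row per depth x level, plus header comment lines recording the designs,
#' reps and seed so a cached table is self-describing.
#'
#' @param ciTable a [CITable-class].
#' @param file path.
#' @return `writeCITable`: the path, invisibly. `readCITable`: a
#'   [CITable-class].
#' @export
writeCITable <- function(ciTable, file) {
    con <- file(file, "w")
    on.exit(close(con))
    meta <- vapply(ciTable@designs, function(d)
        sprintf("n=%d,F=%d", d@n, d@generation), character(1))
    writeLines(c(
        paste0("# designs: ", paste(meta, collapse = "; ")),
        paste0("# reps: ", ciTable@reps),
        paste0("# seed: ", ciTable@seed)), con)
    nd <- ncol(ciTable@depths)
    rows <- do.call(rbind, lapply(seq_along(ciTable@levels), function(j) {
        df <- as.data.frame(ciTable@depths)
        names(df) <- if (nd == 1L) "DEPTH" else c("DEPTH1", "DEPTH2")
        df$LEVEL <- ciTable@levels[j]
        df$LOWER <- ciTable@lower[, j]
        df$UPPER <- ciTable@upper[, j]
        df
    }))
    rows <- rows[order(rows[[1L]], rows$LEVEL), ]
    utils::write.table(format(rows, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @param designs,reps,seed metadata to attach when the file's comment
#'   header is absent (files written by [writeCITable()] carry them).
#' @rdname writeCITable
#' @export
readCITable <- function(file, designs = NULL, reps = NULL, seed = NULL) {
    hdr <- readLines(file, n = 10L)
    hdr <- hdr[startsWith(hdr, "#")]
    getMeta <- function(key) {
        ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
        if (length(ln)) sub(paste0("^# ", key, ": *"), "", ln[1L]) else NULL
    }
    if (is.null(designs) && !is.null(dd <- getMeta("designs"))) {
        designs <- lapply(strsplit(dd, "; ")[[1L]], function(s) {
            v <- as.integer(sub(".*n=(\\d+),F=(\\d+).*", "\\1 \\2",
                                s) |> strsplit(" ") |> unlist())
            bulkDesign(v[1L], v[2L])
        })
    }
    if (is.null(reps)) reps <- as.integer(getMeta("reps") %||% 0L)
    if (is.null(seed)) seed <- as.integer(getMeta("seed") %||% 0L)
    tab <- utils::read.table(file, header = TRUE, sep = "\t",
                             comment.char = "#")
    dcols <- grep("^DEPTH", names(tab), value = TRUE)
    levels <- sort(unique(tab$LEVEL))
    dmat <- unique(as.matrix(tab[tab$LEVEL == levels[1L], dcols, drop = FALSE]))
    dimnames(dmat) <- NULL
    storage.mode(dmat) <- "integer"
    key <- do.call(paste, c(as.data.frame(dmat), sep = ":"))
    lower <- upper <- matrix(NA_real_, nrow(dmat), length(levels))
    for (j in seq_along(levels)) {
        sub <- tab[tab$LEVEL == levels[j], , drop = FALSE]
        idx <- match(key, do.call(paste,
            c(as.data.frame(as.matrix(sub[, dcols, drop = FALSE])), sep = ":")))
        lower[, j] <- sub$LOWER[idx]
        upper[, j] <- sub$UPPER[idx]
    }
    if (is.null(designs))
        stop("designs metadata absent from file; supply 'designs'")
    new("CITable", depths = dmat, levels = as.numeric(levels),
        lower = lower, upper = upper, designs = designs,
        reps = as.integer(reps), seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
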