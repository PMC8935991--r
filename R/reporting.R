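#' @importFrom ggplot2 .data
NULL

#' Parse SnpEff ANN annotation strings
#'
#' SnpEff writes its functional annotations into the ANN INFO field as
#' comma-separated entries of pipe-delimited sub-fields; only the first
#' four (allele, effect, impact, gene) are retained here. SnpEff itself is
#' never executed by this package — run it upstream if annotations are
#' wanted; its output is simply consumed when present.
#'
#' @param ann character vector of raw ANN strings (NA for absent).
#' @return a list (one element per input) of data.frames with columns
#'   allele, effect, impact, gene; zero-row for absent ANN. Malformed
#'   entries (fewer than 4 sub-fields) are skipped with a warning.
#' @examples
#' parseAnn("G|missense_variant|MODERATE|OsABC1|x|y")
#' @export
parseAnn <- function(ann) {
    empty <- data.frame(allele = character(), effect = character(),
                        impact = character(), gene = character(),
                        stringsAsFactors = FALSE)
    lapply(ann, function(a) {
        if (is.na(a) || !nzchar(a)) return(empty)
        entries <- strsplit(a, ",", fixed = TRUE)[[1L]]
        rows <- lapply(entries, function(e) {
            f <- strsplit(e, "|", fixed = TRUE)[[1L]]
            if (length(f) < 4L) {
                warning("skipping malformed ANN entry: ", e, call. = FALSE)
                return(NULL)
            }
            data.frame(allele = f[1L], effect = f[2L], impact = f[3L],
                       gene = f[4L], stringsAsFactors = FALSE)
        })
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows)) do.call(rbind, rows) else empty
    })
}

#' Candidate-locus table
#'
#' Variants flagged at the requested confidence level, sorted by
#' (CHROM, POS), with GENE / EFFECT / IMPACT columns filled from the ANN
#' field when present (first annotation entry per variant). Written as TSV
#' when `file` is given; with no flagged variants the file is header-only.
#'
#' @param tab classified table from [classifyVariants()].
#' @param level confidence level to report (must be one of the classified
#'   levels).
#' @param file optional output path.
#' @return the candidate data.frame (invisibly when `file` is given).
#' @export
candidateTable <- function(tab, level = 0.95, file = NULL) {
    col <- paste0("FLAGGED_", .levelTag(level))
    if (!col %in% names(tab))
        stop("table is not classified at level ", level)
    out <- tab[tab[[col]] %in% TRUE, , drop = FALSE]
    out <- out[order(out$CHROM, out$POS), , drop = FALSE]
    if ("ANN" %in% names(out)) {
        annRows <- parseAnn(out$ANN)
        first <- function(field) vapply(annRows, function(d)
            if (nrow(d)) d[[field]][1L] else NA_character_, character(1))
        out$GENE <- first("gene")
        out$EFFECT <- first("effect")
        out$IMPACT <- first("impact")
    }
    rownames(out) <- NULL
    if (!is.null(file)) {
        .writeTsv(out, file)
        return(invisible(out))
    }
    out
}

#' Genome-scan plot
#'
#' The classic bulked-segregant presentation: one panel per chromosome
#' with per-variant statistics as points, the sliding-window mean as a
#' line (masked windows leave gaps, never interpolation), and shaded
#' confidence bands per level. x is position in Mb; y is the SNP-index
#' (one-bulk, \[0, 1\]) or the delta SNP-index (two-bulk, \[-1, 1\] with a
#' zero reference line). Output format follows the file extension
#' (`.png`, `.svg`, `.pdf`).
#'
#' @param tab per-variant table ([snpIndexTable()]).
#' @param windows window table ([windowScan()]), ideally built with a CI
#'   table so the bands can be drawn.
#' @param file optional output path; when NULL the ggplot object is
#'   returned for interactive use.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
plotScan <- function(tab, windows, file = NULL, width = 9, height = 5) {
    if (nrow(tab) == 0L)
        stop("no variants to plot")
    twoBulk <- "DELTA_SNP_INDEX" %in% names(tab)
    stat <- if (twoBulk) "DELTA_SNP_INDEX" else "SNP_INDEX1"
    wstat <- if (twoBulk) "MEAN_DELTA" else "MEAN_INDEX1"
    ylab <- if (twoBulk) "ΔSNP-index" else "SNP-index"

    pts <- data.frame(CHROM = tab$CHROM, MB = tab$POS / 1e6,
                      Y = tab[[stat]])
    # masked windows must appear as gaps: group runs of unmasked windows
    # so lines/ribbons never interpolate across them
    grp <- interaction(windows$CHROM, cumsum(is.na(windows[[wstat]])))
    wdf <- data.frame(CHROM = windows$CHROM, MB = windows$CENTER / 1e6,
                      Y = windows[[wstat]], GRP = grp)
    wdf <- wdf[!is.na(wdf$Y), , drop = FALSE]
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$MB, y = .data$Y)) +
        ggplot2::geom_point(colour = "grey55", size = 0.6, alpha = 0.7)
    loCols <- grep("^CI_LOWER_", names(windows), value = TRUE)
    for (lc in loCols) {
        uc <- sub("LOWER", "UPPER", lc)
        band <- data.frame(CHROM = windows$CHROM,
                           MB = windows$CENTER / 1e6,
                           LO = windows[[lc]], UP = windows[[uc]],
                           GRP = grp)
        band <- band[!is.na(band$LO), , drop = FALSE]
        p <- p + ggplot2::geom_ribbon(
            data = band,
            ggplot2::aes(x = .data$MB, ymin = .data$LO, ymax = .data$UP,
                         group = .data$GRP),
            inherit.aes = FALSE, fill = "tan2", alpha = 0.25)
    }
    if (twoBulk)
        p <- p + ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                                     colour = "grey30")
    p <- p +
        ggplot2::geom_line(data = wdf,
                           ggplot2::aes(group = .data$GRP),
                           colour = "red3", linewidth = 0.7) +
        ggplot2::facet_wrap(~CHROM, nrow = 1, scales = "free_x") +
        ggplot2::coord_cartesian(
            ylim = if (twoBulk) c(-1, 1) else c(0, 1)) +
        ggplot2::labs(x = "Position (Mb)", y = ylab) +
        ggplot2::theme_bw()
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
        return(invisible(p))
    }
    p
}
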