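#' @rdname BsaVariants-class
#' @param x a BsaVariants (or, for genome accessors, a GenomeMap).
#' @export
setGeneric("bsaMode", function(x) standardGeneric("bsaMode"))

#' @rdname BsaVariants-class
#' @export
setGeneric("nBulks", function(x) standardGeneric("nBulks"))

#' @rdname BsaVariants-class
#' @export
setGeneric("parentCall", function(x) standardGeneric("parentCall"))

#' @rdname BsaVariants-class
#' @param i bulk number (1 or 2).
#' @export
setGeneric("bulkCall", function(x, i = 1L) standardGeneric("bulkCall"))

#' @rdname BsaVariants-class
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname GenomeMap-class
#' @param x a GenomeMap.
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))

#' @rdname GenomeMap-class
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @rdname GenomeMap-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeMap-class
#' @export
setGeneric("totalCM", function(x) standardGeneric("totalCM"))

#' @rdname CITable-class
#' @param x a CITable.
#' @export
setGeneric("ciLevels", function(x) standardGeneric("ciLevels"))

#' @rdname CITable-class
#' @export
setGeneric("ciDepths", function(x) standardGeneric("ciDepths"))

setMethod("bsaMode", "BsaVariants", function(x)
    if (length(x@bulks) == 1L) "onebulk" else "twobulk")
setMethod("nBulks", "BsaVariants", function(x) length(x@bulks))
setMethod("parentCall", "BsaVariants", function(x) x@parent)
setMethod("bulkCall", "BsaVariants", function(x, i = 1L) x@bulks[[i]])
setMethod("variantRanges", "BsaVariants", function(x) x@gr)

setMethod("nChromosomes", "GenomeMap", function(x) length(x@chrom))
setMethod("genomeSize", "GenomeMap", function(x) sum(x@length))
setMethod("chromLengths", "GenomeMap", function(x)
    stats::setNames(x@length, x@chrom))
setMethod("totalCM", "GenomeMap", function(x) x@totalCM)

setMethod("ciLevels", "CITable", function(x) x@levels)
setMethod("ciDepths", "CITable", function(x) x@depths)
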