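#' VariantPanel: per-sample ref/alt read counts at SNV sites
#'
#' A `VariantPanel` holds one biallelic SNV per row and one sequenced sample
#' per column, with two integer assays, `ref` and `alt`, giving the number of
#' reads supporting the reference and alternate allele. Row metadata carries
#' the `ref` and `alt` alleles as single bases; column metadata (`colData`)
#' carries at least a `sample` name and optionally a `declared_sex` label.
#' The class extends [SummarizedExperiment::RangedSummarizedExperiment] so
#' all the usual subsetting, `rowRanges()` and `colData()` machinery applies.
#'
#' @slot .. inherited from `RangedSummarizedExperiment`.
#' @seealso [alleleFrequency()], [maleSpecificSites()], [simulatePanel()]
#' @export
setClass("VariantPanel", contains = "RangedSummarizedExperiment")

setValidity("VariantPanel", function(object) {
    msg <- NULL
    if (!all(c("ref", "alt") %in% assayNames(object)))
        msg <- c(msg, "assays 'ref' and 'alt' are required")
    else {
        r <- assay(object, "ref"); a <- assay(object, "alt")
        if (any(r < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
            msg <- c(msg, "read counts must be non-negative")
    }
    if (nrow(object) > 0) {
        rr <- mcols(rowRanges(object))
        if (!all(c("ref_allele", "alt_allele") %in% colnames(rr)))
            msg <- c(msg, "rowRanges must carry 'ref_allele' and 'alt_allele'")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a VariantPanel
#'
#' @param chrom,pos character / integer vectors of site coordinates
#'   (1-based, VCF convention).
#' @param ref_allele,alt_allele single-base reference and alternate alleles.
#' @param ref,alt integer matrices (sites x samples) of reference- and
#'   alternate-supporting read counts.
#' @param samples sample names (defaults to `colnames(ref)`).
#' @param declared_sex optional per-sample labels (e.g. `"male"`/`"female"`)
#'   as recorded at submission; the inferred class used by the analysis comes
#'   from [inferSex()].
#' @return A [VariantPanel] object.
#' @examples
#' vp <- VariantPanel(chrom = "chr2", pos = c(100L, 200L),
#'                    ref_allele = c("A", "C"), alt_allele = c("G", "T"),
#'                    ref = matrix(c(20L, 10L, 18L, 12L), 2),
#'                    alt = matrix(c(10L, 0L, 9L, 0L), 2),
#'                    samples = c("SS", "BN"))
#' alleleFrequency(vp)
#' @export
VariantPanel <- function(chrom, pos, ref_allele, alt_allele, ref, alt,
                         samples = colnames(ref), declared_sex = NULL) {
    ref <- as.matrix(ref); alt <- as.matrix(alt)
    storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
    if (is.null(samples))
        samples <- paste0("S", seq_len(ncol(ref)))
    if (any(pos < 1))
        stop("positions must be 1-based (>= 1)")
    rr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    mcols(rr)$ref_allele <- as.character(ref_allele)
    mcols(rr)$alt_allele <- as.character(alt_allele)
    cd <- DataFrame(sample = as.character(samples))
    if (!is.null(declared_sex)) cd$declared_sex <- as.character(declared_sex)
    rownames(cd) <- samples
    colnames(ref) <- colnames(alt) <- samples
    se <- SummarizedExperiment(assays = list(ref = ref, alt = alt),
                               rowRanges = rr, colData = cd)
    new("VariantPanel", se)
}

#' @describeIn VariantPanel reference-supporting read counts (sites x samples).
#' @param x A `VariantPanel`.
#' @export
refCounts <- function(x) assay(x, "ref")

#' @describeIn VariantPanel alternate-supporting read counts.
#' @export
altCounts <- function(x) assay(x, "alt")

#' @describeIn VariantPanel total read depth per site and sample.
#' @export
readDepth <- function(x) refCounts(x) + altCounts(x)

#' Per-sample allele frequency
#'
#' The per-sample alternate allele frequency at a site is the ratio of
#' alternate-supporting to total reads, `alt / (ref + alt)`. Zero-depth
#' entries are `NA` (no evidence, not reference-homozygous).
#'
#' @param ref,alt non-negative read counts; vectors, matrices, or a
#'   `VariantPanel` as the single first argument.
#' @return Numeric of the same shape, in `[0, 1]` or `NA` at zero depth.
#' @examples
#' alleleFrequency(10, 5)   # 1/3
#' alleleFrequency(0, 0)    # NA: zero depth
#' @export
setGeneric("alleleFrequency", function(ref, alt) standardGeneric("alleleFrequency"))

#' @rdname alleleFrequency
#' @export
setMethod("alleleFrequency", signature("numeric", "numeric"), function(ref, alt) {
    if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
        stop("read counts must be non-negative")
    depth <- ref + alt
    ifelse(depth > 0, alt / depth, NA_real_)
})

#' @rdname alleleFrequency
#' @export
setMethod("alleleFrequency", signature("matrix", "matrix"), function(ref, alt) {
    out <- alleleFrequency(as.numeric(ref), as.numeric(alt))
    matrix(out, nrow(ref), ncol(ref), dimnames = dimnames(ref))
})

#' @rdname alleleFrequency
#' @export
setMethod("alleleFrequency", signature("VariantPanel", "missing"), function(ref, alt) {
    alleleFrequency(refCounts(ref), altCounts(ref))
})

setMethod("show", "VariantPanel", function(object) {
    cat("VariantPanel with", nrow(object), "sites x", ncol(object), "samples\n")
    if (nrow(object) > 0) {
        chr <- unique(as.character(seqnames(rowRanges(object))))
        cat("  chromosomes:", paste(head(chr, 8), collapse = ", "),
            if (length(chr) > 8) "..." else "", "\n")
    }
    cat("  samples:", paste(head(colnames(object), 8), collapse = ", "),
        if (ncol(object) > 8) "..." else "", "\n")
    invisible(object)
})
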