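#' Infer sample sex from Y-marker reads
#'
#' Classifies each sample as `female` or `male_class` by searching its reads
#' for Y-marker (Sry coding) probe sequence. A read counts as a Y-marker
#' read when it contains any probe, or its reverse complement, as an exact
#' substring. Any Y evidence (>= 1 marker read) makes the sample
#' `male_class`: a declared-female sample with trace Y reads is treated as a
#' male downstream, because its variant calls may carry Y-derived alleles
#' with the same per-read probability as its Sry reads.
#'
#' @param reads named list of [Biostrings::DNAStringSet] read sets (one per
#'   sample), or a single `DNAStringSet` for one sample.
#' @param probes [Biostrings::DNAStringSet] of Y-marker probe sequences
#'   (>= 24 nt each); must be non-empty.
#' @param declared_sex optional named character vector of submission labels.
#' @return data.frame with columns `sample`, `declared_sex`,
#'   `y_marker_reads`, `inferred_class` (`"female"` iff zero marker reads).
#' @examples
#' probes <- Biostrings::DNAStringSet(c(Sry1 = paste(rep("ACGT", 8), collapse = "")))
#' reads <- Biostrings::DNAStringSet("TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTT")
#' inferSex(list(F01 = reads), probes)
#' @export
inferSex <- function(reads, probes, declared_sex = NULL) {
    if (length(probes) == 0) stop("probe set must be non-empty")
    if (is(reads, "DNAStringSet")) reads <- list(sample = reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("S", seq_along(reads))
    hits <- vapply(reads, function(rs) .yMarkerReads(rs, probes), integer(1))
    data.frame(
        sample = names(reads),
        declared_sex = if (is.null(declared_sex)) NA_character_
                       else as.character(declared_sex[names(reads)]),
        y_marker_reads = hits,
        inferred_class = ifelse(hits > 0, "male_class", "female"),
        stringsAsFactors = FALSE)
}

## number of reads containing any probe (either strand) at least once
.yMarkerReads <- function(reads, probes) {
    if (length(reads) == 0) return(0L)
    hit <- rep(FALSE, length(reads))
    for (i in seq_along(probes)) {
        p <- probes[[i]]
        ok <- width(reads) >= length(p)
        if (!any(ok)) next
        hit[ok] <- hit[ok] |
            vcountPattern(p, reads[ok]) > 0 |
            vcountPattern(reverseComplement(p), reads[ok]) > 0
    }
    sum(hit)
}
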