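#' Construct a marker probe panel
#'
#' A probe panel is a named [Biostrings::DNAStringSet], one probe per gene
#' copy, with per-probe metadata: `copy` name and the 1-based offsets of the
#' copy-identifying SNVs within the probe. Probes shorter than 24 nt are
#' rejected (an exact match of a >= 24-mer carrying embedded SNVs is, for
#' practical purposes, the same evidence as a 100%-identity alignment hit).
#'
#' @param sequences character vector or `DNAStringSet` of probe sequences.
#' @param copy copy names (default `names(sequences)`).
#' @param snv_offsets list of integer vectors of SNV offsets per probe.
#' @return A `DNAStringSet` with metadata columns `copy`, `snv_offsets`.
#' @export
markerProbes <- function(sequences, copy = names(sequences),
                         snv_offsets = NULL) {
    probes <- DNAStringSet(sequences)
    if (is.null(copy)) stop("probe copies must be named")
    names(probes) <- copy
    if (is.null(snv_offsets)) snv_offsets <- rep(list(integer(0)), length(probes))
    mcols(probes) <- DataFrame(copy = copy,
                               snv_offsets = IntegerList(snv_offsets))
    .validateProbes(probes)
    probes
}

#' Count marker-positive reads
#'
#' Number of reads containing the probe, or its reverse complement, as an
#' exact substring. A read containing the probe more than once counts once:
#' the unit is the positive read, not the match. Because the probe carries
#' its identifying SNVs internally, every counted read necessarily covers
#' all of them; a read carrying the reference alleles does not match.
#'
#' @param reads A [Biostrings::DNAStringSet] read set (may be empty).
#' @param probe length-1 `DNAStringSet`, `DNAString` or character.
#' @return Integer count of marker-positive reads.
#' @export
countMarkerHits <- function(reads, probe) {
    p <- if (is(probe, "DNAStringSet")) probe[[1]] else DNAString(as.character(probe))
    if (length(reads) == 0) return(0L)
    if (length(p) > max(width(reads)))
        stop("probe (", length(p), " nt) is longer than every read; ",
             "it cannot be contained in any read")
    ok <- width(reads) >= length(p)
    sum(vcountPattern(p, reads[ok]) > 0 |
        vcountPattern(reverseComplement(p), reads[ok]) > 0)
}

#' Reads-per-million normalization
#'
#' @param hits marker-positive read count(s).
#' @param total_reads total reads in the dataset (> 0).
#' @return `hits / total_reads * 1e6`.
#' @examples
#' rpm(5, 2.5e6)  # 2
#' @export
rpm <- function(hits, total_reads) {
    if (any(total_reads <= 0)) stop("total_reads must be > 0")
    hits / total_reads * 1e6
}

#' Y-copy transcript fraction
#'
#' Fraction of homolog-pair reads attributable to the Y-borne copy:
#' `y / (y + homolog)`. 0.5 means a 50/50 transcript ratio between the
#' X-or-autosome homolog and the MSY copy; 0 means homolog-only expression.
#' `NA` when both counts are zero.
#'
#' @param y_hits,homolog_hits non-negative read counts (vectorized).
#' @return Fraction(s) in `[0, 1]` or `NA`.
#' @export
yFraction <- function(y_hits, homolog_hits) {
    if (any(y_hits < 0) || any(homolog_hits < 0)) stop("counts must be >= 0")
    tot <- y_hits + homolog_hits
    ifelse(tot > 0, y_hits / tot, NA_real_)
}

#' Per-dataset per-copy expression profile
#'
#' Counts marker hits for every probe in every dataset, normalizes to RPM,
#' and classifies each dataset by whether any copy other than the focal one
#' (default `Sry2`) is expressed: `non_focal_expressing` iff any non-focal
#' probe has RPM > 0, `focal_only` iff only the focal probe is positive.
#'
#' @param datasets named list; each element either a
#'   [Biostrings::DNAStringSet] read set or a list with elements `reads`
#'   and `total_reads` (when the read set is a marker-enriched subset of a
#'   larger run).
#' @param panel probe panel from [markerProbes()].
#' @param focal focal copy name (must be in the panel).
#' @return list with `rpm` (datasets x copies matrix), `hits` (counts),
#'   and `classification` data.frame (`dataset`, `focal_only`,
#'   `non_focal_expressing`).
#' @export
copyProfile <- function(datasets, panel, focal = "Sry2") {
    copies <- mcols(panel)$copy
    if (!(focal %in% copies))
        stop("focal copy '", focal, "' is not in the probe panel")
    getReads <- function(d) if (is.list(d)) d$reads else d
    getTotal <- function(d) if (is.list(d)) d$total_reads else length(d)
    hits <- t(vapply(datasets, function(d) {
        vapply(seq_along(panel),
               function(i) countMarkerHits(getReads(d), panel[i]), integer(1))
    }, integer(length(panel))))
    colnames(hits) <- copies
    totals <- vapply(datasets, getTotal, numeric(1))
    rpm_mat <- rpm(hits, totals)
    nonfocal <- rpm_mat[, setdiff(copies, focal), drop = FALSE]
    non_focal_expressing <- apply(nonfocal, 1, function(v) any(v > 0))
    focal_pos <- rpm_mat[, focal] > 0
    list(rpm = rpm_mat, hits = hits,
         classification = data.frame(
             dataset = names(datasets),
             focal_only = focal_pos & !non_focal_expressing,
             non_focal_expressing = non_focal_expressing,
             stringsAsFactors = FALSE))
}

#' Copy distinguishability under a read length
#'
#' A gene copy is distinguishable (`determinable`) when some window of at
#' most `read_length` bases on the common coordinate frame contains a
#' combination of alleles unique to that copy; otherwise it is `nd` (not
#' determined) -- short reads cannot tell it apart from another copy, as
#' with paralogs whose private variants lie too far apart.
#'
#' @param variants data.frame with columns `copy`, `position`, `allele`:
#'   the allele carried by each copy at each variant position of the shared
#'   coordinate frame. Every copy must be listed at every position.
#' @param read_length window size in bases (`Inf` for whole-gene).
#' @return data.frame with columns `copy`, `status`
#'   (`"determinable"`/`"nd"`).
#' @export
distinguishability <- function(variants, read_length) {
    if (nrow(variants) == 0) stop("variant panel must be non-empty")
    copies <- unique(variants$copy)
    pos <- sort(unique(variants$position))
    al <- matrix(NA_character_, length(copies), length(pos),
                 dimnames = list(copies, as.character(pos)))
    for (i in seq_len(nrow(variants)))
        al[variants$copy[i], as.character(variants$position[i])] <- variants$allele[i]
    if (anyNA(al))
        stop("every copy must have an allele at every variant position")
    uniqueIn <- function(k, idx) {
        sig <- al[k, idx, drop = FALSE]
        !any(vapply(setdiff(copies, k),
                    function(j) all(al[j, idx] == sig), logical(1)))
    }
    status <- vapply(copies, function(k) {
        for (s in seq_along(pos)) {
            idx <- which(pos >= pos[s] & pos <= pos[s] + read_length - 1)
            if (length(idx) && uniqueIn(k, idx)) return("determinable")
        }
        "nd"
    }, character(1))
    data.frame(copy = copies, status = unname(status), stringsAsFactors = FALSE)
}
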