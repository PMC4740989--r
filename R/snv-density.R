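#' Per-chromosome SNV density
#'
#' Normalizes per-strain per-chromosome SNV counts to chromosome size in
#' megabases.
#'
#' @param counts data.frame with columns `strain`, `chromosome`,
#'   `snv_count`; or a named list of per-strain [VariantPanel]s /
#'   [GenomicRanges::GRanges], in which case sites are tallied per
#'   chromosome.
#' @param lengths_mb named numeric vector of chromosome lengths in Mb;
#'   every counted chromosome must be present.
#' @return data.frame with columns `strain`, `chromosome`, `snv_count`,
#'   `length_mb`, `density` (SNVs per Mb).
#' @export
densityTable <- function(counts, lengths_mb) {
    if (!is.data.frame(counts)) {
        counts <- do.call(rbind, lapply(names(counts), function(s) {
            x <- counts[[s]]
            gr <- if (is(x, "VariantPanel")) rowRanges(x) else x
            tab <- table(as.character(seqnames(gr)))
            data.frame(strain = s, chromosome = names(tab),
                       snv_count = as.integer(tab), stringsAsFactors = FALSE)
        }))
    }
    missing <- setdiff(unique(counts$chromosome), names(lengths_mb))
    if (length(missing) > 0)
        stop("no length for chromosome(s): ", paste(missing, collapse = ", "))
    if (any(lengths_mb <= 0)) stop("chromosome lengths must be > 0")
    counts$length_mb <- unname(lengths_mb[counts$chromosome])
    counts$density <- counts$snv_count / counts$length_mb
    rownames(counts) <- NULL
    counts
}

#' MSY SNV density fold-elevation
#'
#' Per strain, the fold is the MSY density divided by the mean density of
#' all non-MSY chromosomes (unweighted across chromosomes, matching a
#' per-chromosome box-plot framing; set `weighted = TRUE` for the
#' genome-wide length-weighted alternative). Reported as mean +/- SEM over
#' strains (`SEM = NA` for a single strain).
#'
#' @param density a [densityTable()] result.
#' @param msy_name chromosome name of the MSY (default `"chrY"`).
#' @param weighted use the length-weighted genome-wide non-MSY density
#'   instead of the unweighted per-chromosome mean.
#' @return list with `per_strain` (named fold vector), `mean_fold`,
#'   `sem_fold`.
#' @export
msyFold <- function(density, msy_name = "chrY", weighted = FALSE) {
    if (!msy_name %in% density$chromosome)
        stop("MSY chromosome '", msy_name, "' not present in the density table")
    folds <- vapply(split(density, density$strain), function(d) {
        msy <- d$density[d$chromosome == msy_name]
        oth <- d[d$chromosome != msy_name, , drop = FALSE]
        base <- if (weighted) sum(oth$snv_count) / sum(oth$length_mb)
                else mean(oth$density)
        if (length(msy) != 1 || nrow(oth) == 0)
            stop("each strain needs the MSY and >= 1 other chromosome")
        if (base <= 0) stop("zero non-MSY density for a strain")
        msy / base
    }, numeric(1))
    list(per_strain = folds,
         mean_fold = mean(folds),
         sem_fold = if (length(folds) > 1) sd(folds) / sqrt(length(folds))
                    else NA_real_)
}
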