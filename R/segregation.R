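#' Segregation filter configuration
#'
#' Thresholds for the male/female allele-frequency segregation filter.
#' Female genomes must sit at an allele frequency of 0% (at most
#' `female_max_af`), while male-class genomes may sit anywhere strictly
#' inside the heterozygous-like window 0.1--99.9% (fractions
#' `male_af_lower`--`male_af_upper`, inclusive). `min_depth` is the minimum
#' read depth for a per-sample allele frequency to count as observed;
#' shallower entries are treated as missing and exclude the site from
#' candidacy (absence of evidence is not reference homozygosity).
#'
#' @param female_max_af maximum female allele frequency (default 0).
#' @param male_af_lower,male_af_upper inclusive male AF window as fractions
#'   (defaults 0.001 and 0.999, i.e. 0.1% and 99.9%).
#' @param min_depth minimum per-sample depth (default 1).
#' @return A validated list of class `SegregationConfig`.
#' @export
segregationConfig <- function(female_max_af = 0, male_af_lower = 0.001,
                              male_af_upper = 0.999, min_depth = 1L) {
    if (!(female_max_af >= 0 && female_max_af < male_af_lower &&
          male_af_lower < male_af_upper && male_af_upper <= 1))
        stop("require 0 <= female_max_af < male_af_lower < male_af_upper <= 1")
    if (min_depth < 1) stop("min_depth must be >= 1")
    structure(list(female_max_af = female_max_af,
                   male_af_lower = male_af_lower,
                   male_af_upper = male_af_upper,
                   min_depth = as.integer(min_depth)),
              class = "SegregationConfig")
}

## AF matrix with sub-threshold depth masked to NA
.maskedAF <- function(panel, config) {
    af <- alleleFrequency(panel)
    af[readDepth(panel) < config$min_depth] <- NA_real_
    af
}

.splitSexes <- function(panel, sex_calls) {
    samples <- colnames(panel)
    missing <- setdiff(samples, sex_calls$sample)
    if (length(missing) > 0)
        stop("no sex call for sample(s): ", paste(missing, collapse = ", "))
    cls <- setNames(sex_calls$inferred_class, sex_calls$sample)[samples]
    list(male = samples[cls == "male_class"], female = samples[cls == "female"])
}

#' Male-specific candidate sites
#'
#' Applies the segregation filter: a site is male-specific when every female
#' sample has allele frequency at most `female_max_af` (0% by default) and
#' every male-class sample has allele frequency inside the
#' `male_af_lower`--`male_af_upper` window (0.1--99.9%). A site with a
#' missing allele frequency (depth below `min_depth`) in any sample is
#' excluded.
#'
#' @param panel A [VariantPanel].
#' @param sex_calls data.frame from [inferSex()] (columns `sample`,
#'   `inferred_class`) covering every panel sample.
#' @param config A [segregationConfig()].
#' @return The subset `VariantPanel` of passing sites.
#' @export
maleSpecificSites <- function(panel, sex_calls, config = segregationConfig()) {
    sx <- .splitSexes(panel, sex_calls)
    af <- .maskedAF(panel, config)
    keep <- rep(TRUE, nrow(panel))
    if (length(sx$female) > 0) {
        f <- af[, sx$female, drop = FALSE]
        keep <- keep & apply(f, 1, function(v) !anyNA(v) && all(v <= config$female_max_af))
    }
    m <- af[, sx$male, drop = FALSE]
    keep <- keep & apply(m, 1, function(v)
        !anyNA(v) && all(v >= config$male_af_lower & v <= config$male_af_upper))
    panel[keep, ]
}

#' Strain-specific SNV absences (leave-one-out)
#'
#' Re-runs the segregation filter once per male strain `s` with `s` forced to
#' the female side: females at 0%, strain `s` at most `female_max_af`, and
#' all remaining males inside the 0.1--99.9% window. A site passing for `s`
#' is evidence that the duplicated copy carrying it is absent from the MSY of
#' strain `s`. A site absent from two strains at once appears under neither
#' (the definition is one-at-a-time).
#'
#' @inheritParams maleSpecificSites
#' @return A named list, one element per male strain with at least one
#'   qualifying site, each a `VariantPanel` subset. Strains with no
#'   qualifying sites are dropped.
#' @export
strainSpecificSites <- function(panel, sex_calls, config = segregationConfig()) {
    sx <- .splitSexes(panel, sex_calls)
    if (length(sx$male) < 2)
        stop("leave-one-out strain-specific filtering needs >= 2 male-class samples")
    af <- .maskedAF(panel, config)
    out <- list()
    for (s in sx$male) {
        others <- setdiff(sx$male, s)
        keep <- rep(TRUE, nrow(panel))
        if (length(sx$female) > 0) {
            f <- af[, sx$female, drop = FALSE]
            keep <- keep & apply(f, 1, function(v) !anyNA(v) && all(v <= config$female_max_af))
        }
        vs <- af[, s]
        keep <- keep & !is.na(vs) & vs <= config$female_max_af
        m <- af[, others, drop = FALSE]
        keep <- keep & apply(m, 1, function(v)
            !anyNA(v) && all(v >= config$male_af_lower & v <= config$male_af_upper))
        if (any(keep)) out[[s]] <- panel[keep, ]
    }
    out
}

#' Expected duplication allele frequency
#'
#' Analytic expectation for the alternate-read fraction in a male sample at
#' a marker SNV of a gene with `c` copies on the MSY: the Y-borne copies
#' contribute `c` allele doses against the 2 source doses of an autosomal
#' gene (`c/(c+2)`), or against the single X dose of an X-linked gene in a
#' male (`c/(c+1)`). `c = 0` gives 0. The single-copy autosomal case is the
#' classic 1/3 (33%) expectation.
#'
#' @param origin `"autosome"` or `"chrX"`.
#' @param c non-negative integer Y copy number (vectorized).
#' @return Expected allele frequency fraction(s) in `[0, 1)`.
#' @examples
#' expectedDuplicationAF("autosome", 1)  # 1/3
#' expectedDuplicationAF("chrX", 1)      # 1/2
#' @export
expectedDuplicationAF <- function(origin = c("autosome", "chrX"), c) {
    origin <- match.arg(origin)
    if (any(c < 0)) stop("Y copy number c must be >= 0")
    source_doses <- if (origin == "autosome") 2 else 1
    ifelse(c == 0, 0, c / (c + source_doses))
}

#' Per-gene allele-frequency summary
#'
#' Summarizes duplication candidate sites by gene: for each site, the allele
#' frequency is averaged over male-class strains (unweighted); those
#' per-site means are then averaged over the sites of a gene, with the
#' standard error of the mean (SEM) across sites (`NA` for single-site
#' genes).
#'
#' When the leave-one-out result from [strainSpecificSites()] is supplied,
#' its sites are unioned with the male-specific sites per gene (a gene whose
#' Y copy is missing from one strain's MSY has *no* sites passing the main
#' filter -- that strain sits at 0% -- and is recovered entirely through the
#' leave-one-out pass). A strain that misses every known site of a gene is
#' reported under `strains_lacking`; smaller per-strain absences are listed
#' in `strain_specific_snvs` as `"strain(count)"`.
#'
#' @param sites A [VariantPanel] of male-specific sites
#'   (from [maleSpecificSites()]).
#' @param genes data.frame gene annotation with columns `gene`, `chromosome`,
#'   `start`, `end` (1-based inclusive). Each site must fall in at most one
#'   gene; sites outside every gene are dropped.
#' @param sex_calls sex calls covering the panel samples.
#' @param strain_sites optional result of [strainSpecificSites()] computed on
#'   the full panel.
#' @return data.frame with one row per gene: `gene`, `n_snvs`, `mean_af`,
#'   `sem_af`, `strains_lacking` (comma-separated), `strain_specific_snvs`.
#' @export
geneAFSummary <- function(sites, genes, sex_calls, strain_sites = NULL) {
    sx <- .splitSexes(sites, sex_calls)
    gr <- GRanges(genes$chromosome, IRanges(genes$start, genes$end))
    ## map each site of a VariantPanel to its gene (<=1 allowed) and compute
    ## the across-male-strain mean AF per site
    site_table <- function(vp) {
        if (nrow(vp) == 0)
            return(data.frame(key = character(0), gene = character(0),
                              af = numeric(0)))
        ov <- findOverlaps(rowRanges(vp), gr)
        q <- S4Vectors::queryHits(ov)
        if (anyDuplicated(q)) {
            bad <- q[duplicated(q)][1]
            stop("site ", as.character(seqnames(rowRanges(vp)))[bad], ":",
                 start(rowRanges(vp))[bad], " overlaps more than one gene")
        }
        af <- alleleFrequency(vp)[, sx$male, drop = FALSE]
        if (!is.matrix(af)) af <- matrix(af, nrow = nrow(vp))
        data.frame(
            key = paste0(as.character(seqnames(rowRanges(vp)))[q], ":",
                         start(rowRanges(vp))[q]),
            gene = genes$gene[S4Vectors::subjectHits(ov)],
            af = rowMeans(af, na.rm = TRUE)[q],
            stringsAsFactors = FALSE)
    }
    main <- site_table(sites)
    loo <- lapply(strain_sites, site_table)

    gs <- unique(c(main$gene, unlist(lapply(loo, `[[`, "gene"), use.names = FALSE)))
    rows <- lapply(gs, function(g) {
        tab <- rbind(main[main$gene == g, , drop = FALSE],
                     do.call(rbind, lapply(loo, function(t) t[t$gene == g, , drop = FALSE])))
        tab <- tab[!duplicated(tab$key), , drop = FALSE]
        v <- tab$af
        cnt <- vapply(loo, function(t) sum(t$gene == g), integer(1))
        cnt <- cnt[cnt > 0]
        lacking <- names(cnt)[cnt == length(v)]
        partial <- cnt[cnt < length(v)]
        data.frame(gene = g, n_snvs = length(v), mean_af = mean(v),
                   sem_af = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                   strains_lacking = paste(lacking, collapse = ","),
                   strain_specific_snvs = if (length(partial))
                       paste0(names(partial), "(", partial, ")", collapse = ", ")
                   else "",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
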