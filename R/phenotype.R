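#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The p value is exact by
#' enumeration of the U null distribution when `min(nA, nB) <= 8` and there
#' are no ties; otherwise the normal approximation with the mid-rank tie
#' correction is used. The U statistic is for the first group (number of
#' (a, b) pairs with a > b, ties counting one half).
#'
#' @param a,b non-empty numeric vectors of measurements.
#' @return list with `U` and `p`.
#' @examples
#' mannWhitney(c(4, 5, 6), c(1, 2, 3))  # complete separation: p = 0.1
#' @export
mannWhitney <- function(a, b) {
    if (length(a) == 0 || length(b) == 0)
        stop("both groups must be non-empty")
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && min(length(a), length(b)) <= 8
    wt <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for an explicit family size `m` (at least the number of
#' p values; phenotype panels test each phenotype once per consomic
#' comparison, so `m` is the number of phenotypes measured in the panel).
#'
#' @param p p values in `[0, 1]`.
#' @param m family size (default `length(p)`).
#' @return Adjusted p values in `[0, 1]`.
#' @export
bonferroni <- function(p, m = length(p)) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
    if (m < length(p)) stop("family size m must be >= number of p values")
    pmin(1, p * m)
}

#' Consomic-vs-parental phenotype comparisons
#'
#' For every (phenotype, treatment) measured in both strains, compares the
#' consomic strain against the parental strain (same sex, default male) by
#' Mann-Whitney, Bonferroni-adjusts over the family of phenotypes tested in
#' the panel, and flags adjusted p < `alpha`. Optionally computes
#' male-vs-female tests within the named parental strains and derives the
#' sex-difference flags used by [classifySexDifference()].
#'
#' @param data long-format data.frame with columns `phenotype`, `treatment`,
#'   `strain`, `sex`, `value`.
#' @param consomic,parental strain names for the consomic comparison.
#' @param sex sex used for the consomic-vs-parental comparison
#'   (default `"male"`).
#' @param parent_strains strains for which male-vs-female sex-difference
#'   flags are computed (default: `parental` and the MSY donor if present).
#' @param family_size Bonferroni family size (default: number of
#'   phenotype-treatment combinations tested).
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame with one row per (phenotype, treatment): raw and
#'   adjusted consomic-vs-parental p, `significant`, and one logical
#'   `mf_significant_<strain>` column per parent strain (adjusted over the
#'   same family).
#' @export
comparePhenotypes <- function(data, consomic, parental, sex = "male",
                              parent_strains = parental,
                              family_size = NULL, alpha = 0.05) {
    keys <- unique(data[, c("phenotype", "treatment")])
    m <- if (is.null(family_size)) nrow(keys) else family_size
    pick <- function(ph, tr, st, sx)
        data$value[data$phenotype == ph & data$treatment == tr &
                   data$strain == st & data$sex == sx]
    rows <- lapply(seq_len(nrow(keys)), function(i) {
        ph <- keys$phenotype[i]; tr <- keys$treatment[i]
        va <- pick(ph, tr, consomic, sex); vb <- pick(ph, tr, parental, sex)
        p <- if (length(va) && length(vb)) mannWhitney(va, vb)$p else NA_real_
        out <- data.frame(phenotype = ph, treatment = tr,
                          consomic = consomic, parental = parental,
                          p_raw = p, stringsAsFactors = FALSE)
        for (st in parent_strains) {
            vm <- pick(ph, tr, st, "male"); vf <- pick(ph, tr, st, "female")
            out[[paste0("mf_p_", st)]] <-
                if (length(vm) && length(vf)) mannWhitney(vm, vf)$p else NA_real_
        }
        out
    })
    res <- do.call(rbind, rows)
    res$p_adj <- bonferroni(res$p_raw, m)
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
    for (st in parent_strains) {
        adj <- bonferroni(res[[paste0("mf_p_", st)]], m)
        res[[paste0("mf_significant_", st)]] <- !is.na(adj) & adj < alpha
    }
    res
}

#' Sex-difference classification of consomic-significant phenotypes
#'
#' Classifies each phenotype row by which of the two parental strains shows
#' a significant male-vs-female difference: `both` when both flags are set,
#' `<A>_only` / `<B>_only` when exactly one is, `neither` otherwise. Rows
#' are counted as given (duplicated phenotype entries are distinct rows).
#'
#' @param flag_a,flag_b logical vectors (`NA` not allowed).
#' @param labels length-2 character vector naming the two strains
#'   (default `c("A", "B")`).
#' @return list with `class` (character vector per row) and `counts`
#'   (named integer vector over `both`, `<A>_only`, `<B>_only`, `neither`).
#' @export
classifySexDifference <- function(flag_a, flag_b, labels = c("A", "B")) {
    if (length(flag_a) != length(flag_b))
        stop("flag vectors must have equal length")
    if (anyNA(flag_a) || anyNA(flag_b))
        stop("missing sex-difference flag")
    lev <- c("both", paste0(labels[1], "_only"), paste0(labels[2], "_only"),
             "neither")
    cls <- ifelse(flag_a & flag_b, lev[1],
           ifelse(flag_a & !flag_b, lev[2],
           ifelse(!flag_a & flag_b, lev[3], lev[4])))
    counts <- table(factor(cls, levels = lev))
    list(class = cls, counts = setNames(as.integer(counts), lev))
}

#' Load the packaged consomic sex-difference table
#'
#' Published phenotype comparisons for the two MSY consomic panels
#' (FHH with a BN Y chromosome, and SS with a BN Y chromosome): one row per
#' phenotype/treatment found significantly altered in the consomic, with
#' yes/no flags for a male-vs-female difference in each parental strain.
#' Flags are `"Yes"`/`"No"`; `"-"` marks a strain not part of that panel.
#'
#' @return data.frame with columns `phenotype`, `treatment`, `consomic`,
#'   `bn_mf_significant`, `fhh_mf_significant`, `ss_mf_significant`.
#' @export
consomicSexDifferenceTable <- function() {
    path <- system.file("extdata", "consomic_sex_differences.tsv",
                        package = "msySeg", mustWork = TRUE)
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Per-chromosome phenotypic contribution fold
#'
#' For each chromosome consomic, the contribution metric is the fraction of
#' measured phenotypes found significant, normalized per megabase
#' (`(n_sig/n_measured)/size_mb`) or per ten genes
#' (`(n_sig/n_measured)/(n_genes/10)`). The MSY fold is reported against
#' both the mean and the maximum of the other chromosomes' metrics ("higher
#' than any other chromosome"). Chromosomes with no measured phenotypes are
#' skipped with a warning.
#'
#' @param sig data.frame with columns `chromosome`, `n_significant`,
#'   `n_measured`.
#' @param sizes_mb named numeric vector of chromosome sizes in Mb.
#' @param gene_counts named numeric vector of gene counts per chromosome.
#' @param msy_name MSY chromosome name (default `"chrY"`).
#' @return list with `table` (per-chromosome metrics) and `fold`
#'   (`per_mb_vs_mean`, `per_mb_vs_max`, `per_10_genes_vs_mean`,
#'   `per_10_genes_vs_max`).
#' @export
contributionFold <- function(sig, sizes_mb, gene_counts, msy_name = "chrY") {
    skip <- sig$n_measured == 0
    if (any(skip)) {
        warning("skipping chromosome(s) with no measured phenotypes: ",
                paste(sig$chromosome[skip], collapse = ", "))
        sig <- sig[!skip, , drop = FALSE]
    }
    if (any(sig$n_significant > sig$n_measured))
        stop("n_significant cannot exceed n_measured")
    frac <- sig$n_significant / sig$n_measured
    size <- sizes_mb[sig$chromosome]
    genes <- gene_counts[sig$chromosome]
    if (anyNA(size) || any(size <= 0)) stop("missing or non-positive chromosome size")
    if (anyNA(genes) || any(genes <= 0)) stop("missing or non-positive gene count")
    tab <- data.frame(chromosome = sig$chromosome,
                      n_significant = sig$n_significant,
                      n_measured = sig$n_measured,
                      sig_fraction = frac,
                      per_mb = frac / size,
                      per_10_genes = frac / (genes / 10))
    if (!msy_name %in% tab$chromosome)
        stop("MSY chromosome '", msy_name, "' not in the significance table")
    is_msy <- tab$chromosome == msy_name
    oth <- tab[!is_msy, , drop = FALSE]
    fold <- list(
        per_mb_vs_mean = tab$per_mb[is_msy] / mean(oth$per_mb),
        per_mb_vs_max = tab$per_mb[is_msy] / max(oth$per_mb),
        per_10_genes_vs_mean = tab$per_10_genes[is_msy] / mean(oth$per_10_genes),
        per_10_genes_vs_max = tab$per_10_genes[is_msy] / max(oth$per_10_genes))
    list(table = tab, fold = fold)
}
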