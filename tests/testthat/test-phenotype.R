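test_that("Mann-Whitney gives the exact enumeration p for small groups", {
    res <- mannWhitney(c(4, 5, 6), c(1, 2, 3))
    expect_equal(res$p, 0.1)              # 2/20 assignments as extreme
    expect_equal(res$U, 9)
    same <- mannWhitney(c(1, 2, 3), c(1, 2, 3))  # fully tied: no shift
    expect_equal(same$p, 1)
    expect_equal(same$U, 4.5)
    expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("swapping groups maps U to nA*nB - U and keeps p", {
    set.seed(71)
    for (i in 1:25) {
        a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1))
        f <- mannWhitney(a, b); r <- mannWhitney(b, a)
        expect_equal(f$U + r$U, length(a) * length(b))
        expect_equal(f$p, r$p)
    }
})

test_that("Mann-Whitney agrees with the assignment-enumeration oracle", {
    set.seed(72)
    for (i in 1:100) {
        nA <- sample(2:6, 1); nB <- sample(2:6, 1)
        a <- rnorm(nA); b <- rnorm(nB, mean = sample(c(0, 1), 1))
        got <- mannWhitney(a, b)
        exp <- oracle_mw(a, b)
        expect_equal(got$U, exp$U)
        expect_equal(got$p, exp$p, tolerance = 1e-12)
    }
})

test_that("the normal approximation tracks enumeration at n = 10 vs 10", {
    set.seed(73)
    a <- rnorm(10, 0.8); b <- rnorm(10)
    got <- mannWhitney(a, b)             # min(n) > 8: approximation path
    exp <- oracle_mw(a, b)
    expect_equal(got$U, exp$U)
    expect_lt(abs(got$p - exp$p), 0.01)
})

test_that("Bonferroni multiplies and caps, preserving order", {
    expect_equal(bonferroni(0.01, 10), 0.1)
    expect_equal(bonferroni(0.5, 4), 1)
    p <- c(0.001, 0.02, 0.04)
    adj <- bonferroni(p, 50)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj) >= 0))
    expect_true(all(adj <= 1))
    expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
    expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
})

test_that("sex-difference classes partition the rows", {
    a <- c(TRUE, TRUE, FALSE, FALSE)
    b <- c(TRUE, FALSE, TRUE, FALSE)
    res <- classifySexDifference(a, b, labels = c("FHH", "BN"))
    expect_equal(res$class,
                 c("both", "FHH_only", "BN_only", "neither"))
    expect_equal(sum(res$counts), 4L)
    allf <- classifySexDifference(rep(FALSE, 6), rep(FALSE, 6))
    expect_equal(unname(allf$counts["neither"]), 6L)
    expect_error(classifySexDifference(c(TRUE, NA), c(TRUE, TRUE)), "missing")
    expect_error(classifySexDifference(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("the packaged consomic table reproduces the published class counts", {
    tab <- consomicSexDifferenceTable()
    expect_equal(nrow(tab), 53)
    fhh <- tab[tab$consomic == "FHH-YBN/Mcwi", ]
    res <- classifySexDifference(fhh$fhh_mf_significant == "Yes",
                                 fhh$bn_mf_significant == "Yes",
                                 labels = c("FHH", "BN"))
    expect_equal(unname(res$counts),
                 c(15L, 2L, 10L, 0L))
    ss <- tab[tab$consomic == "SS-YBN/Mcwi", ]
    res2 <- classifySexDifference(ss$ss_mf_significant == "Yes",
                                  ss$bn_mf_significant == "Yes",
                                  labels = c("SS", "BN"))
    expect_equal(unname(res2$counts), c(22L, 1L, 3L, 0L))
})

test_that("contribution folds follow the per-Mb and per-10-genes metrics", {
    sig <- data.frame(chromosome = c("chr1", "chr2", "chrY"),
                      n_significant = c(5L, 5L, 5L), n_measured = c(50L, 50L, 50L))
    sizes <- c(chr1 = 10, chr2 = 10, chrY = 10)
    genes <- c(chr1 = 100, chr2 = 100, chrY = 100)
    f <- contributionFold(sig, sizes, genes)
    expect_equal(f$fold$per_mb_vs_mean, 1)
    expect_equal(f$fold$per_10_genes_vs_max, 1)

    sig$n_significant <- c(5L, 5L, 50L)        # MSY fraction 10x others
    f10 <- contributionFold(sig, sizes, genes)
    expect_equal(f10$fold$per_mb_vs_mean, 10)
    expect_equal(f10$fold$per_mb_vs_max, 10)

    ## hand-computed table: fractions .2/.1 over 100/2 Mb, genes 1000/30
    sig2 <- data.frame(chromosome = c("chr1", "chrY"),
                       n_significant = c(20L, 10L), n_measured = c(100L, 100L))
    f2 <- contributionFold(sig2, c(chr1 = 100, chrY = 2),
                           c(chr1 = 1000, chrY = 30))
    expect_equal(f2$table$per_mb, c(0.2 / 100, 0.1 / 2))
    expect_equal(f2$fold$per_mb_vs_mean, (0.1 / 2) / (0.2 / 100))
    expect_equal(f2$fold$per_10_genes_vs_mean, (0.1 / 3) / (0.2 / 100))
    expect_warning(contributionFold(
        rbind(sig2, data.frame(chromosome = "chr3", n_significant = 0L,
                               n_measured = 0L)),
        c(chr1 = 100, chrY = 2, chr3 = 50),
        c(chr1 = 1000, chrY = 30, chr3 = 500)), "chr3")
})

test_that("the consomic pipeline controls type-I error after Bonferroni", {
    eff <- expand.grid(phenotype = paste0("p", 1:8),
                       strain = c("SS", "SS-YBN", "BN"),
                       stringsAsFactors = FALSE)
    eff$base <- 10; eff$sex_effect <- 0; eff$noise_sd <- 1; eff$n_per_group <- 10
    false_calls <- vapply(1:40, function(i) {
        tab <- simulatePhenotypes(eff, seed = 5000 + i)
        res <- comparePhenotypes(tab, consomic = "SS-YBN", parental = "SS",
                                 parent_strains = c("SS", "BN"))
        sum(res$significant)
    }, numeric(1))
    ## family-wise error across 8 null phenotypes stays below alpha-ish
    expect_lte(mean(false_calls > 0), 0.15)
    expect_lte(mean(false_calls) / 8, 0.05 / 8 * 3)
})

test_that("comparePhenotypes flags a planted consomic effect", {
    eff <- expand.grid(phenotype = paste0("p", 1:5),
                       strain = c("SS", "SS-YBN", "BN"),
                       stringsAsFactors = FALSE)
    eff$base <- 10
    eff$base[eff$phenotype == "p1" & eff$strain == "SS-YBN"] <- 16
    eff$sex_effect <- ifelse(eff$strain == "BN", 8, 0)
    eff$noise_sd <- 1; eff$n_per_group <- 10
    tab <- simulatePhenotypes(eff, seed = 77)
    res <- comparePhenotypes(tab, consomic = "SS-YBN", parental = "SS",
                             parent_strains = c("SS", "BN"))
    expect_true(res$significant[res$phenotype == "p1"])
    expect_false(any(res$significant[res$phenotype != "p1"]))
    expect_true(all(res$mf_significant_BN))
    expect_false(any(res$mf_significant_SS))
    cls <- classifySexDifference(res$mf_significant_SS[res$significant],
                                 res$mf_significant_BN[res$significant],
                                 labels = c("SS", "BN"))
    expect_equal(unname(cls$counts["BN_only"]),
                 sum(res$significant))
})
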