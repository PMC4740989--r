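toy_panel <- function(af_by_sample, coverage = 10) {
    ## af_by_sample: sites x samples matrix of allele fractions (NA = no depth)
    samples <- colnames(af_by_sample)
    n <- nrow(af_by_sample)
    ref <- alt <- matrix(0L, n, length(samples),
                         dimnames = list(NULL, samples))
    for (j in seq_along(samples)) for (i in seq_len(n)) {
        v <- af_by_sample[i, j]
        if (!is.na(v)) {
            alt[i, j] <- as.integer(round(v * coverage))
            ref[i, j] <- coverage - alt[i, j]
        }
    }
    VariantPanel(chrom = rep("chr1", n), pos = seq_len(n) * 100L,
                 ref_allele = rep("A", n), alt_allele = rep("G", n),
                 ref = ref, alt = alt, samples = samples)
}

test_that("allele frequency is alt/(ref+alt), missing at zero depth", {
    expect_equal(alleleFrequency(10, 5), 1 / 3)
    expect_true(is.na(alleleFrequency(0, 0)))
    expect_equal(alleleFrequency(0, 7), 1)
    expect_error(alleleFrequency(-1, 2), "non-negative")
    m <- alleleFrequency(matrix(c(10, 0), 1), matrix(c(5, 0), 1))
    expect_equal(m[1, 1], 1 / 3)
    expect_true(is.na(m[1, 2]))
})

test_that("segregation config enforces threshold ordering", {
    expect_error(segregationConfig(female_max_af = 0.5, male_af_lower = 0.1),
                 "female_max_af")
    expect_error(segregationConfig(male_af_upper = 1.2), "male_af_upper")
    cfg <- segregationConfig()
    expect_equal(cfg$male_af_lower, 0.001)
    expect_equal(cfg$male_af_upper, 0.999)
})

test_that("male-specific filter keeps 33%-in-males, 0%-in-females sites", {
    af <- cbind(M1 = c(0.3, 0.3, 1.0), M2 = c(0.4, 0.3, 0.5),
                F1 = c(0.0, 0.2, 0.0))
    panel <- toy_panel(af)
    sx <- sex_df(c("M1", "M2"), "F1")
    kept <- maleSpecificSites(panel, sx)
    ## site 1 passes; site 2 fails (female at 0.2); site 3 fails (male fixed)
    expect_equal(start(rowRanges(kept)), 100L)
})

test_that("sites with missing depth in any sample are excluded", {
    af <- cbind(M1 = c(0.3, NA), M2 = c(0.3, 0.3), F1 = c(0, 0))
    panel <- toy_panel(af)
    kept <- maleSpecificSites(panel, sex_df(c("M1", "M2"), "F1"))
    expect_equal(nrow(kept), 1L)
    expect_error(maleSpecificSites(panel, sex_df("M1", "F1")), "sex call")
})

test_that("male-specific filtering is idempotent", {
    set.seed(8)
    panel <- random_panel(40, c("M1", "M2", "M3"), c("F1", "F2"))
    sx <- sex_df(c("M1", "M2", "M3"), c("F1", "F2"))
    once <- maleSpecificSites(panel, sx)
    twice <- maleSpecificSites(once, sx)
    expect_equal(nrow(once), nrow(twice))
    expect_identical(altCounts(once), altCounts(twice))
})

test_that("leave-one-out attributes absences one strain at a time", {
    ## gene sites absent in FHL only -> under FHL; a site absent in two
    ## strains appears under neither
    af <- cbind(ACI = c(0.3, 0.3, 0.3), FHH = c(0.3, 0.3, 0.0),
                FHL = c(0.0, 0.0, 0.0), SS = c(0.3, 0.3, 0.3),
                F1 = c(0, 0, 0))
    panel <- toy_panel(af)
    sx <- sex_df(c("ACI", "FHH", "FHL", "SS"), "F1")
    ss <- strainSpecificSites(panel, sx)
    expect_equal(names(ss), "FHL")
    expect_equal(start(rowRanges(ss$FHL)), c(100L, 200L))  # site 3 under neither

    all_carry <- toy_panel(cbind(ACI = c(0.3), FHH = c(0.5), FHL = c(0.4),
                                 SS = c(0.3), F1 = c(0)))
    expect_length(strainSpecificSites(all_carry, sx), 0)
    expect_error(strainSpecificSites(panel[, c("ACI", "F1")],
                                     sex_df("ACI", "F1")), ">= 2")
})

test_that("segregation filters agree with brute-force oracles", {
    cfg <- segregationConfig()
    set.seed(101)
    males <- c("M1", "M2", "M3", "M4")
    females <- c("F1", "F2")
    sx <- sex_df(males, females)
    for (rep in 1:100) {
        panel <- random_panel(sample(5:50, 1), males, females)
        af <- alleleFrequency(panel)
        exp_ms <- oracle_male_specific(af, females, males, cfg)
        got_ms <- maleSpecificSites(panel, sx, cfg)
        expect_identical(start(rowRanges(got_ms)),
                         start(rowRanges(panel))[exp_ms])
        exp_ss <- oracle_strain_specific(af, females, males, cfg)
        got_ss <- strainSpecificSites(panel, sx, cfg)
        expect_identical(names(got_ss), names(exp_ss))
        for (s in names(exp_ss))
            expect_identical(start(rowRanges(got_ss[[s]])),
                             start(rowRanges(panel))[exp_ss[[s]]])
    }
})

test_that("expected duplication AF follows c/(c+2) and c/(c+1)", {
    expect_equal(expectedDuplicationAF("autosome", 1), 1 / 3)
    expect_equal(expectedDuplicationAF("chrX", 1), 0.5)
    expect_equal(expectedDuplicationAF("autosome", 2), 0.5)
    expect_equal(expectedDuplicationAF("autosome", 0), 0)
    expect_error(expectedDuplicationAF("autosome", -1), ">= 0")
    ## strictly increasing in c, approaching 1
    cc <- 0:40
    v <- expectedDuplicationAF("autosome", cc)
    expect_true(all(diff(v) > 0))
    expect_gt(expectedDuplicationAF("autosome", 1e6), 0.999)
})

test_that("per-gene summary averages site means and reports SEM", {
    af <- cbind(M1 = c(0.28, 0.36), M2 = c(0.32, 0.32), F1 = c(0, 0))
    panel <- toy_panel(af, coverage = 25)
    sx <- sex_df(c("M1", "M2"), "F1")
    genes <- data.frame(gene = "g1", chromosome = "chr1",
                        start = 50, end = 250)
    ms <- maleSpecificSites(panel, sx)
    summ <- geneAFSummary(ms, genes, sx)
    ## site means 0.30 and 0.34 -> mean 0.32, SEM = sd/sqrt(2) = 0.02
    expect_equal(summ$mean_af, 0.32)
    expect_equal(summ$sem_af, 0.02)
    expect_equal(summ$n_snvs, 2L)

    single <- geneAFSummary(ms[1, ], genes, sx)
    expect_true(is.na(single$sem_af))
})

test_that("a site overlapping two genes is rejected by name", {
    af <- cbind(M1 = 0.3, F1 = 0)
    panel <- toy_panel(af)
    sx <- sex_df("M1", "F1")
    genes <- data.frame(gene = c("g1", "g2"), chromosome = "chr1",
                        start = c(50, 90), end = c(150, 190))
    ms <- maleSpecificSites(panel, sx)
    expect_error(geneAFSummary(ms, genes, sx), "more than one gene")
})

test_that("a strain lacking every site of a gene is reported as lacking", {
    af <- cbind(ACI = c(0.3, 0.35), FHH = c(0.33, 0.30),
                FHL = c(0.0, 0.0), F1 = c(0, 0))
    panel <- toy_panel(af, coverage = 20)
    sx <- sex_df(c("ACI", "FHH", "FHL"), "F1")
    genes <- data.frame(gene = "Med14", chromosome = "chr1",
                        start = 50, end = 250)
    ms <- maleSpecificSites(panel, sx)
    expect_equal(nrow(ms), 0L)     # FHL at 0% blocks the main filter
    ss <- strainSpecificSites(panel, sx)
    summ <- geneAFSummary(ms, genes, sx, ss)
    expect_equal(summ$n_snvs, 2L)
    expect_equal(summ$strains_lacking, "FHL")
})
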