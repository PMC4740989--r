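test_that("SNV clustering chains within 20 bases and drops singletons", {
    got <- clusterSNVs(data.frame(chromosome = "chr1",
                                  position = c(100, 110, 135)))
    expect_equal(got$position, c(100, 110))      # 110 -> 135 gap is 25
    expect_equal(unique(got$cluster_id), 1L)

    chain <- clusterSNVs(data.frame(chromosome = "chr1",
                                    position = c(100, 118, 136)))
    expect_equal(chain$position, c(100, 118, 136))  # transitive chaining

    expect_equal(nrow(clusterSNVs(data.frame(chromosome = "chr1",
                                             position = 500))), 0L)
    expect_equal(nrow(clusterSNVs(data.frame(chromosome = character(0),
                                             position = integer(0)))), 0L)
})

test_that("clustering is order-invariant and never grows the input", {
    set.seed(21)
    for (i in 1:20) {
        n <- sample(2:30, 1)
        df <- data.frame(chromosome = sample(c("c1", "c2"), n, TRUE),
                         position = sample.int(500, n))
        shuf <- df[sample.int(n), ]
        a <- clusterSNVs(df); b <- clusterSNVs(shuf)
        expect_equal(a, b)
        expect_lte(nrow(a), n)
    }
})

test_that("clustering agrees with a pairwise-link closure oracle", {
    set.seed(31)
    for (i in 1:100) {
        n <- sample(2:25, 1)
        chrom <- sample(c("c1", "c2"), n, TRUE)
        pos <- sample.int(300, n)
        df <- unique(data.frame(chromosome = chrom, position = pos))
        got <- clusterSNVs(df)
        comp <- oracle_cluster(df$chromosome, df$position)
        kept <- df[!is.na(comp), ]
        kept <- kept[order(kept$chromosome, kept$position), ]
        expect_equal(got$position, kept$position)
        expect_equal(got$chromosome, kept$chromosome)
        ## same partition: cluster ids co-classify identical pairs
        if (nrow(got) > 1) {
            ok <- oracle_cluster(got$chromosome, got$position)
            expect_equal(outer(got$cluster_id, got$cluster_id, "=="),
                         outer(ok, ok, "=="))
        }
    }
})

test_that("probes embed alternate alleles and match only variant reads", {
    set.seed(41)
    ctx <- random_dna(200)
    positions <- c(90, 101)
    ref_bases <- substring(ctx, positions, positions)
    alt <- vapply(ref_bases, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    probe <- buildProbe(ctx, positions, alt, context_start = 1,
                        flank = 11, placement = "middle")
    expect_equal(width(probe), (101 - 90 + 1) + 22)
    offs <- S4Vectors::mcols(probe)$snv_offsets[[1]]
    expect_equal(as.character(Biostrings::subseq(probe[[1]], offs[1], offs[1])),
                 unname(alt[1]))
    ## reference context does not contain the probe; an alt-carrying read does
    expect_equal(nrow(locateOnMsy(probe, Biostrings::DNAStringSet(c(c1 = ctx)))), 0)
    alt_ctx <- ctx
    substring(alt_ctx, positions[1], positions[1]) <- alt[1]
    substring(alt_ctx, positions[2], positions[2]) <- alt[2]
    expect_equal(nrow(locateOnMsy(probe,
        Biostrings::DNAStringSet(c(c1 = alt_ctx)))), 1)
    expect_error(buildProbe(substring(ctx, 1, 105), positions, alt,
                            flank = 11), "too short")
})

test_that("ends placement puts the outermost SNV on the probe boundary", {
    ctx <- random_dna(200)
    probe <- buildProbe(ctx, c(90, 101), c("A", "C"), flank = 11,
                        placement = "ends")
    offs <- S4Vectors::mcols(probe)$snv_offsets[[1]]
    expect_equal(offs[1], 1L)
    expect_equal(width(probe), 12 + 22)
})

test_that("probe placement on contigs agrees with a naive scan oracle", {
    set.seed(51)
    for (i in 1:100) {
        probe <- random_dna(24)
        ## sometimes plant the reverse complement on the second contig
        contigB <- if (i %% 3 == 0)
            paste0(random_dna(20), revcomp_chr(probe), random_dna(20))
        else random_dna(150)
        contigs <- Biostrings::DNAStringSet(c(
            A = paste0(random_dna(60), probe, random_dna(60)), B = contigB))
        got <- locateOnMsy(probe, contigs)
        exp <- oracle_locate(probe, contigs)
        expect_equal(got$contig, exp$contig)
        expect_equal(got$position, exp$position)
        expect_equal(got$strand, exp$strand)
    }
})

test_that("degenerate probe bases and absent probes are handled", {
    contigs <- Biostrings::DNAStringSet(c(c1 = random_dna(100)))
    expect_error(locateOnMsy(paste0("N", random_dna(23)), contigs),
                 "degenerate")
    expect_equal(nrow(locateOnMsy(random_dna(30), contigs)), 0)
    expect_error(locateOnMsy(random_dna(30), Biostrings::DNAStringSet()),
                 "non-empty")
})

## build a gene + locus pair for mechanism tests
mech_fixture <- function(mechanism, seed = 1) {
    set.seed(seed)
    exons <- data.frame(start = c(1, 201, 401), end = c(100, 300, 500))
    gene <- random_dna(500)
    exon_seq <- vapply(seq_len(3), function(i)
        substring(gene, exons$start[i], exons$end[i]), character(1))
    insert <- switch(mechanism,
        retroposed = paste(exon_seq, collapse = ""),
        transposed = gene,
        partial_transposed = substring(gene, 1, 300))
    locus <- paste0(random_dna(80), insert, random_dna(80))
    list(gene = gene, exons = exons, locus = locus)
}

test_that("mechanism classification separates retro/transposed/partial", {
    fx <- mech_fixture("retroposed")
    expect_equal(classifyMechanism(fx$gene, fx$exons, fx$locus,
                                   source_chromosome = "chr2"), "retroposed")
    fx <- mech_fixture("transposed", 2)
    expect_equal(classifyMechanism(fx$gene, fx$exons, fx$locus,
                                   source_chromosome = "chr2"), "transposed")
    fx <- mech_fixture("partial_transposed", 3)
    expect_equal(classifyMechanism(fx$gene, fx$exons, fx$locus,
                                   source_chromosome = "chr2"),
                 "partial_transposed")
    expect_equal(classifyMechanism(fx$gene, fx$exons, random_dna(400),
                                   source_chromosome = "chrY"),
                 "msy_duplication")
    expect_equal(classifyMechanism(fx$gene, fx$exons, random_dna(400),
                                   source_chromosome = "chr2"), "unplaced")
})

test_that("intronless source genes default to retroposed with a warning", {
    set.seed(4)
    gene <- random_dna(300)
    exons <- data.frame(start = 1, end = 300)
    locus <- paste0(random_dna(50), gene, random_dna(50))
    expect_warning(
        mech <- classifyMechanism(gene, exons, locus,
                                  source_chromosome = "chr2"),
        "intronless")
    expect_equal(mech, "retroposed")
})

test_that("mechanism calls tolerate the planted marker mismatches", {
    ## the MSY copy differs from the source by its marker SNVs
    set.seed(5)
    fx <- mech_fixture("retroposed")
    mutated <- fx$locus
    positions <- 80 + c(50, 58)            # inside the inserted cDNA
    for (p in positions) {
        b <- substring(mutated, p, p)
        substring(mutated, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    expect_equal(classifyMechanism(fx$gene, fx$exons, mutated,
                                   source_chromosome = "chr2",
                                   max_mismatch = 4), "retroposed")
})

test_that("pseudogene assessment combines ORF disruption and expression", {
    set.seed(6)
    n_cod <- 60
    intact <- paste(c("ATG", replicate(n_cod - 2, {
        repeat { cd <- random_dna(3); if (!cd %in% c("TAA", "TAG", "TGA")) break }
        cd
    }), "TAA"), collapse = "")
    broken <- paste0(substring(intact, 1, 90), "TAA",
                     substring(intact, 94, nchar(intact)))
    expect_equal(assessPseudogene(broken, rpm = 0)$status, "pseudogene")
    expect_true(assessPseudogene(broken, rpm = 0)$premature_stop)
    expect_equal(assessPseudogene(intact, rpm = 12)$status, "functional")
    expect_equal(assessPseudogene(intact, rpm = 0)$status, "indeterminate")
    expect_equal(assessPseudogene(broken, rpm = 12)$status, "indeterminate")
    expect_error(assessPseudogene(intact, rpm = -1), ">= 0")
})

test_that("frame scan handles sequences that are not codon-aligned", {
    set.seed(7)
    body <- paste(replicate(40, {
        repeat { cd <- random_dna(3); if (!cd %in% c("TAA", "TAG", "TGA")) break }
        cd
    }), collapse = "")
    orf <- paste0("ATG", body, "TAA")
    shifted <- paste0("GG", orf)          # ORF in frame 2
    res <- assessPseudogene(shifted, rpm = 5)
    expect_false(res$premature_stop)
    expect_equal(res$status, "functional")
    expect_equal(res$frame, 2L)
})
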