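## Brute-force oracles, independent of the package implementations.

suppressPackageStartupMessages({
    library(Biostrings)
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## enumerate the male/female AF conditions site by site
oracle_male_specific <- function(af, females, males, cfg) {
    pass <- logical(nrow(af))
    for (i in seq_len(nrow(af))) {
        ok <- TRUE
        for (s in females) {
            v <- af[i, s]
            if (is.na(v) || v > cfg$female_max_af) ok <- FALSE
        }
        for (s in males) {
            v <- af[i, s]
            if (is.na(v) || v < cfg$male_af_lower || v > cfg$male_af_upper)
                ok <- FALSE
        }
        pass[i] <- ok
    }
    which(pass)
}

oracle_strain_specific <- function(af, females, males, cfg) {
    out <- list()
    for (s in males) {
        pass <- logical(nrow(af))
        for (i in seq_len(nrow(af))) {
            ok <- TRUE
            for (f in females) {
                v <- af[i, f]
                if (is.na(v) || v > cfg$female_max_af) ok <- FALSE
            }
            v <- af[i, s]
            if (is.na(v) || v > cfg$female_max_af) ok <- FALSE
            for (m in setdiff(males, s)) {
                v <- af[i, m]
                if (is.na(v) || v < cfg$male_af_lower || v > cfg$male_af_upper)
                    ok <- FALSE
            }
            pass[i] <- ok
        }
        if (any(pass)) out[[s]] <- which(pass)
    }
    out
}

## pairwise-link transitive closure clustering, then drop singletons
oracle_cluster <- function(chrom, pos, max_gap = 20) {
    n <- length(pos)
    if (n == 0) return(integer(0))
    linked <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        linked[i, j] <- chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= max_gap
    comp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n))
            if (linked[i, j] && comp[j] != comp[i]) {
                comp[comp == comp[j]] <- comp[i]; changed <- TRUE
            }
        if (!changed) break
    }
    sizes <- table(comp)
    keep <- comp %in% names(sizes)[sizes >= 2]
    ifelse(keep, comp, NA_integer_)
}

## naive O(n*m) substring scan, both strands
revcomp_chr <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
oracle_locate <- function(probe, contigs) {
    probe <- as.character(probe)
    hits <- data.frame(contig = character(0), position = integer(0),
                       strand = character(0))
    for (nm in names(contigs)) {
        subj <- as.character(contigs[[nm]])
        for (strand in c("+", "-")) {
            p <- if (strand == "+") probe else revcomp_chr(probe)
            w <- nchar(p)
            for (i in seq_len(nchar(subj) - w + 1)) {
                if (substring(subj, i, i + w - 1) == p)
                    hits <- rbind(hits, data.frame(contig = nm, position = i,
                                                   strand = strand))
            }
        }
    }
    hits
}

oracle_count_hits <- function(reads, probe) {
    probe <- as.character(probe)
    rc <- revcomp_chr(probe)
    n <- 0L
    for (r in as.character(reads)) {
        if (grepl(probe, r, fixed = TRUE) || grepl(rc, r, fixed = TRUE))
            n <- n + 1L
    }
    n
}

## exact two-sided Mann-Whitney by enumeration of all group assignments
oracle_mw <- function(a, b) {
    pooled <- c(a, b)
    nA <- length(a); n <- length(pooled)
    U_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    idx <- utils::combn(n, nA)
    mid <- nA * length(b) / 2
    stat <- apply(idx, 2, function(k) {
        x <- pooled[k]; y <- pooled[-k]
        sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    })
    p <- mean(abs(stat - mid) >= abs(U_obs - mid) - 1e-9)
    list(U = U_obs, p = p)
}

## small random panel builder for oracle-equivalence tests
random_panel <- function(n_sites, males, females, coverage = 30) {
    samples <- c(males, females)
    ref <- matrix(0L, n_sites, length(samples),
                  dimnames = list(NULL, samples))
    alt <- ref
    for (j in seq_along(samples)) {
        depth <- sample(0:coverage, n_sites, replace = TRUE)
        a <- vapply(depth, function(d)
            if (d == 0) 0L else rbinom(1, d, sample(c(0, 0.33, 0.5, 1), 1)),
            integer(1))
        alt[, j] <- a
        ref[, j] <- depth - a
    }
    VariantPanel(chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
                 pos = sample.int(10000, n_sites),
                 ref_allele = rep("A", n_sites), alt_allele = rep("G", n_sites),
                 ref = ref, alt = alt, samples = samples)
}

sex_df <- function(males, females) {
    data.frame(sample = c(males, females),
               declared_sex = NA_character_,
               y_marker_reads = c(rep(5L, length(males)),
                                  rep(0L, length(females))),
               inferred_class = c(rep("male_class", length(males)),
                                  rep("female", length(females))),
               stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
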