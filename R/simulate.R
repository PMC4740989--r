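## ---- deterministic RNG substreams -----------------------------------------

#' Derive a per-stage RNG seed
#'
#' One top-level seed plus a stage name gives a deterministic substream
#' seed, so stages rerun independently reproduce their outputs.
#'
#' @param seed top-level integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
    h <- 0
    for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483629
    as.integer((as.numeric(seed) + h) %% 2147483647)
}

## run expr under a stage-derived seed, restoring the caller's RNG state
.withStageSeed <- function(seed, stage, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()))
    set.seed(stageSeed(seed, stage))
    expr
}

.randomBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.STOPS <- c("TAA", "TAG", "TGA")

## random open reading frame of n_codons codons: ATG ... TAA, no internal stop
.randomORF <- function(n_codons) {
    stopifnot(n_codons >= 3)
    body <- replicate(n_codons - 2, {
        repeat {
            cd <- paste(.randomBases(3), collapse = "")
            if (!cd %in% .STOPS) break
        }
        cd
    })
    strsplit(paste0("ATG", paste(body, collapse = ""), "TAA"), "")[[1]]
}

## ---- configuration --------------------------------------------------------

#' Specification of one duplicated gene
#'
#' Ground-truth description of a gene whose copies were inserted onto the
#' MSY, used by [simulatePanel()].
#'
#' @param gene gene name.
#' @param origin_chromosome source chromosome name.
#' @param origin_kind `"autosome"` or `"chrX"` (drives the expected marker
#'   allele frequency `c/(c+2)` vs `c/(c+1)`).
#' @param y_copy_number number of MSY copies `c` (>= 0; 0 means no Y copy
#'   and no male-specific alternate reads).
#' @param mechanism duplication mechanism planted on the MSY contig:
#'   `retroposed` (spliced, intronless insert), `transposed` (insert keeps
#'   the normal introns), `partial_transposed` (only a proper subset of
#'   exons inserted, introns kept), or `msy_duplication` (gene native to
#'   the MSY).
#' @param n_marker_snvs number of marker SNVs (>= 2; planted in exons as
#'   close pairs so that clusters of two-plus SNVs within 20 bases exist).
#' @param strains_lacking male strains whose MSY lacks the copy.
#' @param expressed whether the MSY copy is transcribed.
#' @param premature_stop plant an in-frame stop codon in the MSY copy.
#' @param n_exons,exon_len,intron_len gene structure (defaults 3 x 240 bp
#'   exons with 150 bp introns; `n_exons = 1` makes an intronless source).
#' @return Validated list of class `DuplicatedGeneSpec`.
#' @export
dupGeneSpec <- function(gene, origin_chromosome,
                        origin_kind = c("autosome", "chrX"),
                        y_copy_number = 1L,
                        mechanism = c("retroposed", "transposed",
                                      "partial_transposed", "msy_duplication"),
                        n_marker_snvs = 10L, strains_lacking = character(0),
                        expressed = TRUE, premature_stop = FALSE,
                        n_exons = 3L, exon_len = 240L, intron_len = 150L) {
    origin_kind <- match.arg(origin_kind)
    mechanism <- match.arg(mechanism)
    if (y_copy_number < 0) stop("y_copy_number must be >= 0")
    if (n_marker_snvs < 2) stop("n_marker_snvs must be >= 2 (clusters need pairs)")
    if (mechanism %in% c("transposed", "partial_transposed") && n_exons < 2)
        stop("mechanism '", mechanism, "' needs >= 2 exons (introns required)")
    if ((n_exons * exon_len) %% 3 != 0)
        stop("total exonic length must be a multiple of 3 (coding frame)")
    structure(list(gene = gene, origin_chromosome = origin_chromosome,
                   origin_kind = origin_kind,
                   y_copy_number = as.integer(y_copy_number),
                   mechanism = mechanism,
                   n_marker_snvs = as.integer(n_marker_snvs),
                   strains_lacking = strains_lacking, expressed = expressed,
                   premature_stop = premature_stop,
                   n_exons = as.integer(n_exons),
                   exon_len = as.integer(exon_len),
                   intron_len = as.integer(intron_len)),
              class = "DuplicatedGeneSpec")
}

.DEFAULT_MALES <- c("ACI", "FHH", "FHL", "SBH", "SBN", "SR", "SS", "BBDP",
                    "LE_Stm", "MHS", "MNS", "WAG", "F344", "LEW", "LH", "LL",
                    "LN", "SHRSP")
.DEFAULT_FEMALES <- c("LE_F", "BN_F", "WKY_F", "SD_F", "F344_F")

#' Simulation configuration
#'
#' Parameters of the synthetic genome panel. Defaults reproduce the study
#' conditions the analysis assumes: a 23-genome panel (18 male-class, 5
#' female), 50x coverage with binomial read sampling at each site, a
#' scaled-down genome (autosomes and X at 10 Mb, MSY at 2 Mb), a background
#' SNV rate of 100 SNVs/Mb/strain and a two-fold MSY rate elevation.
#'
#' @param n_male_samples,n_female_samples,n_contaminated_females panel
#'   composition; contaminated females are counted inside
#'   `n_female_samples` and carry trace Y-marker reads.
#' @param coverage constant per-site read depth (binomial n).
#' @param chromosome_lengths named vector, lengths in Mb (must include
#'   `chrY`).
#' @param background_snv_rate background SNVs per Mb per strain.
#' @param msy_rate_multiplier ground-truth MSY SNV rate elevation (> 0).
#' @param duplicated_genes list of [dupGeneSpec()] entries.
#' @param contamination_fraction fraction of a contaminated female's reads
#'   carrying the Y marker (default 0.001).
#' @param max_table_background_sites background SNVs materialized as rows
#'   of the variant table (full background counts are always reported in
#'   the per-chromosome count table; only a subsample is materialized as
#'   sites to keep panels small).
#' @param seed top-level integer seed; fixed seed gives identical outputs.
#' @return Validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_male_samples = 18L, n_female_samples = 5L,
                             n_contaminated_females = 0L, coverage = 50L,
                             chromosome_lengths = c(chr1 = 10, chr2 = 10,
                                 chr5 = 10, chr8 = 10, chr10 = 10, chr13 = 10,
                                 chrX = 10, chrY = 2),
                             background_snv_rate = 100,
                             msy_rate_multiplier = 2,
                             duplicated_genes = list(),
                             contamination_fraction = 0.001,
                             max_table_background_sites = 200L,
                             seed = 1L) {
    chk <- function(ok, field)
        if (!ok) stop("invalid configuration field: ", field)
    chk(n_male_samples >= 0, "n_male_samples")
    chk(n_female_samples >= 0, "n_female_samples")
    chk(n_contaminated_females >= 0 &&
        n_contaminated_females <= n_female_samples, "n_contaminated_females")
    chk(coverage >= 1, "coverage")
    chk(all(chromosome_lengths > 0) && "chrY" %in% names(chromosome_lengths),
        "chromosome_lengths")
    chk(background_snv_rate >= 0, "background_snv_rate")
    chk(msy_rate_multiplier > 0, "msy_rate_multiplier")
    chk(contamination_fraction >= 0 && contamination_fraction < 1,
        "contamination_fraction")
    chk(all(vapply(duplicated_genes, inherits, logical(1),
                   "DuplicatedGeneSpec")), "duplicated_genes")
    for (g in duplicated_genes)
        chk(g$origin_chromosome %in% names(chromosome_lengths),
            paste0("duplicated_genes[", g$gene, "]$origin_chromosome"))
    structure(list(n_male_samples = as.integer(n_male_samples),
                   n_female_samples = as.integer(n_female_samples),
                   n_contaminated_females = as.integer(n_contaminated_females),
                   coverage = as.integer(coverage),
                   chromosome_lengths = chromosome_lengths,
                   background_snv_rate = background_snv_rate,
                   msy_rate_multiplier = msy_rate_multiplier,
                   duplicated_genes = duplicated_genes,
                   contamination_fraction = contamination_fraction,
                   max_table_background_sites = as.integer(max_table_background_sites),
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

## ---- gene construction helpers --------------------------------------------

## build one gene: base-vector genomic sequence, local exon coords, marker
## SNV local positions with ref/alt alleles chosen to not create stop codons
.buildGene <- function(spec) {
    n_ex <- spec$n_exons; elen <- spec$exon_len; ilen <- spec$intron_len
    n_codons <- (n_ex * elen) %/% 3L
    orf <- .randomORF(n_codons)                     # exonic bases, in frame
    exon_starts <- (seq_len(n_ex) - 1L) * (elen + ilen) + 1L
    exons <- data.frame(start = exon_starts, end = exon_starts + elen - 1L)
    glen <- n_ex * elen + (n_ex - 1L) * ilen
    seq <- character(glen)
    for (i in seq_len(n_ex))
        seq[exons$start[i]:exons$end[i]] <- orf[((i - 1L) * elen + 1L):(i * elen)]
    intron_mask <- seq == ""
    seq[intron_mask] <- .randomBases(sum(intron_mask))

    ## marker SNVs in close pairs (8-12 bp apart) so clusters exist; anchors
    ## spread across exons, >= 50 bp between pairs
    n_snv <- spec$n_marker_snvs
    n_pairs <- n_snv %/% 2L
    ## a partial insert drops the last exon, so its markers must avoid it
    usable_ex <- if (spec$mechanism == "partial_transposed") n_ex - 1L else n_ex
    anchors_per_exon <- max(1L, ceiling(n_pairs / usable_ex))
    slots <- list()
    for (e in seq_len(usable_ex))
        for (a in seq_len(anchors_per_exon))
            slots[[length(slots) + 1L]] <- c(e, 20L + (a - 1L) * 60L)
    if (length(slots) < n_pairs)
        stop("gene ", spec$gene, ": too many marker SNVs for its exon space")
    pos <- integer(0)
    for (j in seq_len(n_pairs)) {
        e <- slots[[j]][1]; off <- slots[[j]][2]
        gap <- sample(8:12, 1)
        p1 <- exons$start[e] + off
        pos <- c(pos, p1, p1 + gap)
    }
    if (n_snv %% 2L == 1L)            # odd count: extend the last pair to a triple
        pos <- c(pos, pos[length(pos)] + sample(8:12, 1))
    pos <- sort(pos)
    if (max(pos) > exons$end[n_ex] - 3L)
        stop("gene ", spec$gene, ": marker SNVs exceed exon bounds")

    ## cDNA coordinate of a local exonic position
    cdna_pos <- vapply(pos, function(p) {
        e <- max(which(exons$start <= p))
        (e - 1L) * elen + (p - exons$start[e] + 1L)
    }, integer(1))
    ref <- seq[pos]
    alt <- vapply(seq_along(pos), function(i) {
        q <- cdna_pos[i]
        ci <- (q - 1L) %/% 3L            # 0-based codon index
        within <- q - ci * 3L            # 1..3
        codon <- orf[(ci * 3L + 1L):(ci * 3L + 3L)]
        for (b in setdiff(c("A", "C", "G", "T"), ref[i])) {
            cd <- codon; cd[within] <- b
            if (!paste(cd, collapse = "") %in% .STOPS) return(b)
        }
        stop("no stop-free alternate base")   # unreachable: <=3 stop codons
    }, character(1))

    list(seq = seq, exons = exons, snv_pos = pos, snv_ref = ref,
         snv_alt = alt, cdna_pos = cdna_pos, n_codons = n_codons)
}

## the MSY-borne insert sequence for a gene (base vector), alt alleles
## substituted at marker SNVs, optional premature stop planted mid-ORF
.buildInsert <- function(spec, gene) {
    seq <- gene$seq
    seq[gene$snv_pos] <- gene$snv_alt
    exons <- gene$exons
    if (spec$premature_stop) {
        ## stop codon around 40% into the ORF, clear of marker SNVs
        ci <- round(gene$n_codons * 0.4)
        repeat {
            q <- (ci - 1L) * 3L + 1L     # cDNA pos of codon start
            if (!any(gene$cdna_pos %in% q:(q + 2L))) break
            ci <- ci + 1L
        }
        e <- (q - 1L) %/% spec$exon_len + 1L
        local <- exons$start[e] + (q - 1L) - (e - 1L) * spec$exon_len
        seq[local:(local + 2L)] <- c("T", "A", "A")
    }
    switch(spec$mechanism,
        retroposed = unlist(lapply(seq_len(nrow(exons)), function(i)
            seq[exons$start[i]:exons$end[i]])),
        transposed = ,
        msy_duplication = seq,
        partial_transposed = seq[1:(exons$end[nrow(exons) - 1L])])
}

## ---- panel simulation ------------------------------------------------------

#' Simulate a genome panel with planted MSY duplications
#'
#' Generates a male/female variant panel with the statistical structure the
#' segregation analysis assumes. At each marker SNV of a planted duplicated
#' gene, a male sample's alternate read count is Binomial(`coverage`, p)
#' with p the expected duplication allele frequency (`c/(c+2)` autosomal
#' origin, `c/(c+1)` X origin); females have zero alternate reads at
#' MSY-derived sites; strains listed as lacking a gene have zero alternate
#' reads at its sites. Background SNVs are drawn per strain and chromosome
#' as Poisson(rate x length), with the MSY rate elevated by
#' `msy_rate_multiplier`; a subsample is materialized as strain-private
#' homozygous rows of the variant table. Per-sample read sets carrying (or
#' not) the Sry marker are generated for sex inference, with contaminated
#' females carrying a trace marker fraction.
#'
#' @param config A [simulationConfig()].
#' @return list with components `panel` ([VariantPanel]), `samples` (sample
#'   sheet: `sample`, `declared_sex`, `true_sex`, `contaminated`), `reads`
#'   (named list of per-sample [Biostrings::DNAStringSet]), `sry_probes`
#'   (Y-marker probes for [inferSex()]), `msy` (MSY contig `DNAStringSet`),
#'   `genes` (annotation: `table` with chromosome coordinates, `exons`
#'   local to each gene, `sequences` of the source genes), `snv_counts`
#'   (per strain x chromosome background SNV counts for [densityTable()]),
#'   and `truth` (planted ground truth per gene: mechanism, copies and MSY
#'   insert coordinates, expected AF, strains lacking, flags).
#' @export
simulatePanel <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withStageSeed(config$seed, "panel", .simulatePanelImpl(config))
}

.simulatePanelImpl <- function(config) {
    males <- c(.DEFAULT_MALES, paste0("M", 19:99))[seq_len(config$n_male_samples)]
    females <- c(.DEFAULT_FEMALES, paste0("F", 6:99))[seq_len(config$n_female_samples)]
    contaminated <- if (config$n_contaminated_females > 0)
        females[seq_len(config$n_contaminated_females)] else character(0)
    all_samples <- c(males, females)
    for (g in config$duplicated_genes) {
        bad <- setdiff(g$strains_lacking, males)
        if (length(bad)) stop("invalid configuration field: duplicated_genes[",
                              g$gene, "]$strains_lacking (unknown strain ",
                              paste(bad, collapse = ","), ")")
    }

    ## ---- genes and marker sites
    gene_rows <- list(); exon_rows <- list(); gene_seqs <- character(0)
    site_chrom <- character(0); site_pos <- integer(0)
    site_ref <- character(0); site_alt <- character(0)
    site_gene <- character(0); site_p <- numeric(0)
    truth_genes <- list()
    built <- list()
    next_start <- lapply(config$chromosome_lengths, function(x) 10000L)
    for (spec in config$duplicated_genes) {
        gene <- .buildGene(spec)
        built[[spec$gene]] <- gene
        chrom <- spec$origin_chromosome
        gstart <- next_start[[chrom]]
        glen <- length(gene$seq)
        next_start[[chrom]] <- gstart + glen + 5000L
        if (next_start[[chrom]] > config$chromosome_lengths[[chrom]] * 1e6)
            stop("chromosome ", chrom, " too short for its genes")
        gene_rows[[spec$gene]] <- data.frame(
            gene = spec$gene, chromosome = chrom, start = gstart,
            end = gstart + glen - 1L, stringsAsFactors = FALSE)
        exon_rows[[spec$gene]] <- data.frame(
            gene = spec$gene, exon = seq_len(nrow(gene$exons)),
            start = gene$exons$start, end = gene$exons$end)
        gene_seqs[spec$gene] <- paste(gene$seq, collapse = "")

        p <- expectedDuplicationAF(
            if (spec$origin_kind == "chrX") "chrX" else "autosome",
            spec$y_copy_number)
        n <- length(gene$snv_pos)
        site_chrom <- c(site_chrom, rep(chrom, n))
        site_pos <- c(site_pos, gstart + gene$snv_pos - 1L)
        site_ref <- c(site_ref, gene$snv_ref)
        site_alt <- c(site_alt, gene$snv_alt)
        site_gene <- c(site_gene, rep(spec$gene, n))
        site_p <- c(site_p, rep(p, n))
        truth_genes[[spec$gene]] <- list(
            gene = spec$gene, origin_chromosome = chrom,
            origin_kind = spec$origin_kind, y_copy_number = spec$y_copy_number,
            mechanism = spec$mechanism, expected_af = p,
            n_marker_snvs = n, snv_positions = gstart + gene$snv_pos - 1L,
            strains_lacking = spec$strains_lacking,
            expressed = spec$expressed, premature_stop = spec$premature_stop)
    }

    ## ---- marker-site count matrices
    n_sites <- length(site_pos)
    cov <- config$coverage
    ref_mat <- matrix(cov, n_sites, length(all_samples),
                      dimnames = list(NULL, all_samples))
    alt_mat <- matrix(0L, n_sites, length(all_samples),
                      dimnames = list(NULL, all_samples))
    for (s in males) {
        lacking <- vapply(site_gene, function(g)
            s %in% truth_genes[[g]]$strains_lacking, logical(1))
        p_here <- ifelse(lacking, 0, site_p)
        a <- rbinom(n_sites, cov, p_here)
        alt_mat[, s] <- a
        ref_mat[, s] <- cov - a
    }
    storage.mode(alt_mat) <- "integer"; storage.mode(ref_mat) <- "integer"

    ## ---- background SNVs: full per-strain x chromosome counts (Poisson),
    ##      plus a materialized subsample of strain-private hom-alt rows
    chroms <- names(config$chromosome_lengths)
    rate <- config$background_snv_rate *
        ifelse(chroms == "chrY", config$msy_rate_multiplier, 1)
    cnt <- do.call(rbind, lapply(males, function(s) {
        data.frame(strain = s, chromosome = chroms,
                   snv_count = rpois(length(chroms),
                                     rate * config$chromosome_lengths),
                   stringsAsFactors = FALSE)
    }))
    n_bg <- min(config$max_table_background_sites, sum(cnt$snv_count))
    if (n_bg > 0 && length(males) > 0) {
        bg_chrom <- sample(setdiff(chroms, "chrY"), n_bg, replace = TRUE)
        bg_pos <- vapply(bg_chrom, function(ch)
            sample.int(9000L, 1L), integer(1))   # upstream of the gene blocks
        bg_strain <- sample(males, n_bg, replace = TRUE)
        bg_ref_al <- .randomBases(n_bg)
        bg_alt_al <- vapply(bg_ref_al, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        bg_ref <- matrix(cov, n_bg, length(all_samples),
                         dimnames = list(NULL, all_samples))
        bg_alt <- matrix(0L, n_bg, length(all_samples),
                         dimnames = list(NULL, all_samples))
        for (i in seq_len(n_bg)) {      # strain-private homozygous alternate
            bg_alt[i, bg_strain[i]] <- cov
            bg_ref[i, bg_strain[i]] <- 0L
        }
        site_chrom <- c(site_chrom, bg_chrom)
        site_pos <- c(site_pos, bg_pos)
        site_ref <- c(site_ref, bg_ref_al)
        site_alt <- c(site_alt, bg_alt_al)
        ref_mat <- rbind(ref_mat, bg_ref)
        alt_mat <- rbind(alt_mat, bg_alt)
    }

    ord <- order(site_chrom, site_pos)
    panel <- VariantPanel(chrom = site_chrom[ord], pos = site_pos[ord],
                          ref_allele = site_ref[ord], alt_allele = site_alt[ord],
                          ref = ref_mat[ord, , drop = FALSE],
                          alt = alt_mat[ord, , drop = FALSE],
                          samples = all_samples,
                          declared_sex = c(rep("male", length(males)),
                                           rep("female", length(females))))

    ## ---- MSY contig with planted inserts
    inserts <- list()
    for (spec in config$duplicated_genes) {
        if (spec$y_copy_number == 0 || spec$mechanism == "msy_duplication")
            next
        gene <- built[[spec$gene]]
        ins <- .buildInsert(spec, gene)
        ## marker-bearing transcript fragment: insert region around the first
        ## SNV pair (drives the copy-specific RNA reads)
        ins_snv <- if (spec$mechanism == "retroposed") gene$cdna_pos
                   else gene$snv_pos
        lo <- max(1L, ins_snv[1] - 18L)
        hi <- min(length(ins), ins_snv[2] + 18L)
        truth_genes[[spec$gene]]$marker_fragment <-
            paste(ins[lo:hi], collapse = "")
        for (k in seq_len(spec$y_copy_number))
            inserts[[length(inserts) + 1L]] <-
                list(gene = spec$gene, copy = k, seq = ins)
    }
    spacing <- 400L
    total <- sum(vapply(inserts, function(i) length(i$seq), integer(1))) +
        spacing * (length(inserts) + 1L)
    contig <- .randomBases(max(total, 2000L))
    at <- spacing + 1L
    for (i in seq_along(inserts)) {
        len <- length(inserts[[i]]$seq)
        strand <- sample(c("+", "-"), 1)
        placed <- if (strand == "+") inserts[[i]]$seq else
            rev(chartr("ACGT", "TGCA", inserts[[i]]$seq))
        contig[at:(at + len - 1L)] <- placed
        inserts[[i]]$position <- at
        inserts[[i]]$strand <- strand
        inserts[[i]]$length <- len
        at <- at + len + spacing
    }
    msy <- DNAStringSet(paste(contig, collapse = ""))
    names(msy) <- "MSY_contig1"
    for (i in seq_along(inserts)) {
        g <- inserts[[i]]$gene
        truth_genes[[g]]$msy_hits <- rbind(
            truth_genes[[g]]$msy_hits,
            data.frame(contig = "MSY_contig1",
                       position = inserts[[i]]$position,
                       strand = inserts[[i]]$strand,
                       length = inserts[[i]]$length))
    }

    ## ---- per-sample read sets for sex inference
    sry_region <- paste(.randomBases(300), collapse = "")
    sry_probe <- DNAStringSet(substring(sry_region, 100, 139))
    names(sry_probe) <- "Sry1"
    read_len <- 100L; n_reads <- 40L
    mk_reads <- function(n_marker) {
        reads <- vapply(seq_len(n_reads), function(i) {
            if (i <= n_marker) {
                start <- sample(61:100, 1)   # window containing probe 100..139
                substring(sry_region, start, start + read_len - 1L)
            } else paste(.randomBases(read_len), collapse = "")
        }, character(1))
        DNAStringSet(reads)
    }
    n_trace <- max(1L, round(config$contamination_fraction * n_reads))
    reads <- c(
        setNames(lapply(males, function(s) mk_reads(n_reads %/% 2L)), males),
        setNames(lapply(females, function(s)
            mk_reads(if (s %in% contaminated) n_trace else 0L)), females))

    list(panel = panel,
         samples = data.frame(
             sample = all_samples,
             declared_sex = c(rep("male", length(males)),
                              rep("female", length(females))),
             true_sex = c(rep("male", length(males)),
                          rep("female", length(females))),
             contaminated = all_samples %in% contaminated,
             stringsAsFactors = FALSE),
         reads = reads, sry_probes = sry_probe, msy = msy,
         genes = list(table = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))),
                      exons = do.call(rbind, c(exon_rows, list(make.row.names = FALSE))),
                      sequences = if (length(gene_seqs)) {
                          gs <- DNAStringSet(gene_seqs); gs } else DNAStringSet()),
         snv_counts = cnt,
         truth = list(genes = truth_genes, seed = config$seed))
}

## ---- read simulation -------------------------------------------------------

#' Simulate marker-bearing reads
#'
#' Draws `total_reads` reads of length `read_length`. Each read carries the
#' marker fragment of one gene copy with probability proportional to that
#' copy's expression weight, embedded at a random offset in random flanking
#' sequence and reported on a random strand; with probability proportional
#' to `background_weight` the read is pure background (no marker). The
#' expected marker-hit count for copy k is
#' `total_reads * weight_k / (sum(weights) + background_weight)`.
#'
#' @param markers named [Biostrings::DNAStringSet]: one marker-bearing
#'   fragment per copy (each must fit in a read).
#' @param weights non-negative expression weights, one per marker; all-zero
#'   weights with `total_reads > 0` and no background is an error.
#' @param total_reads number of reads.
#' @param read_length read length (>= the longest marker).
#' @param seed integer seed.
#' @param background_weight weight of markerless background reads
#'   (default 0). Use `weights = 0` with a positive `background_weight`
#'   for female / negative-control read sets.
#' @return A `DNAStringSet` of reads; `mcols()$copy` records the true
#'   source (`NA` for background).
#' @export
simulateReads <- function(markers, weights, total_reads, read_length,
                          seed = 1L, background_weight = 0) {
    if (length(weights) != length(markers))
        stop("one weight per marker required")
    if (any(weights < 0) || background_weight < 0)
        stop("weights must be >= 0")
    if (total_reads > 0 && sum(weights) + background_weight == 0)
        stop("all weights are zero: no read source to draw from")
    if (length(markers) > 0 && read_length < max(width(markers)))
        stop("read_length shorter than the longest marker fragment")
    if (total_reads == 0) {
        out <- DNAStringSet()
        mcols(out) <- DataFrame(copy = character(0))
        return(out)
    }
    .withStageSeed(seed, "reads", {
        probs <- c(weights, background_weight)
        src <- sample.int(length(probs), total_reads, replace = TRUE,
                          prob = probs)
        mstr <- as.character(markers)
        reads <- vapply(src, function(k) {
            if (k > length(markers))
                return(paste(.randomBases(read_length), collapse = ""))
            frag <- mstr[k]
            w <- nchar(frag)
            lflank <- sample.int(read_length - w + 1L, 1L) - 1L
            paste0(paste(.randomBases(lflank), collapse = ""), frag,
                   paste(.randomBases(read_length - w - lflank), collapse = ""))
        }, character(1))
        out <- DNAStringSet(reads)
        flip <- runif(total_reads) < 0.5
        if (any(flip)) out[flip] <- reverseComplement(out[flip])
        names(out) <- sprintf("read%06d", seq_len(total_reads))
        mcols(out) <- DataFrame(copy = ifelse(src > length(markers),
                                              NA_character_,
                                              names(markers)[src]))
        out
    })
}

## ---- phenotype simulation ---------------------------------------------------

#' Simulate a long-format phenotype table
#'
#' For each row of `effects`, draws `n_per_group` male and `n_per_group`
#' female values: male ~ Normal(`base + sex_effect`, `noise_sd`), female ~
#' Normal(`base`, `noise_sd`).
#'
#' @param effects data.frame with columns `phenotype`, `strain`, `base`,
#'   `sex_effect`, `noise_sd`, `n_per_group`, and optionally `treatment`.
#' @param seed integer seed.
#' @return Long-format data.frame (`phenotype`, `treatment`, `strain`,
#'   `sex`, `value`).
#' @export
simulatePhenotypes <- function(effects, seed = 1L) {
    if (any(effects$n_per_group < 2)) stop("n_per_group must be >= 2")
    if (any(effects$noise_sd <= 0)) stop("noise_sd must be > 0")
    if (is.null(effects$treatment)) effects$treatment <- "control"
    .withStageSeed(seed, "phenotypes", {
        rows <- lapply(seq_len(nrow(effects)), function(i) {
            e <- effects[i, ]
            n <- e$n_per_group
            data.frame(phenotype = e$phenotype, treatment = e$treatment,
                       strain = e$strain,
                       sex = rep(c("male", "female"), each = n),
                       value = c(rnorm(n, e$base + e$sex_effect, e$noise_sd),
                                 rnorm(n, e$base, e$noise_sd)),
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    })
}
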