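#' Demo simulation configuration
#'
#' A ready-made panel mirroring the structure of the published duplication
#' set: ten duplicated genes -- seven retroposed (one lacking from the FHL
#' MSY, one pseudogenized by a premature stop with no expression, four
#' silent but ORF-intact), two transposed (one with two Y copies) and one
#' partial insertion -- over an 18-male / 5-female panel at 50x coverage.
#'
#' @param seed top-level seed.
#' @return A [simulationConfig()].
#' @export
demoConfig <- function(seed = 1L) {
    genes <- list(
        dupGeneSpec("Med14", "chrX", "chrX", 1, "retroposed",
                    n_marker_snvs = 12, strains_lacking = "FHL",
                    expressed = TRUE),
        dupGeneSpec("Ube2q2", "chr8", "autosome", 1, "retroposed",
                    n_marker_snvs = 10, expressed = TRUE),
        dupGeneSpec("Limd2", "chr10", "autosome", 1, "retroposed",
                    n_marker_snvs = 10, expressed = FALSE,
                    premature_stop = TRUE),
        dupGeneSpec("Ect2", "chr2", "autosome", 1, "retroposed",
                    n_marker_snvs = 10, expressed = FALSE),
        dupGeneSpec("Havcr2", "chr10", "autosome", 1, "retroposed",
                    n_marker_snvs = 10, expressed = FALSE),
        dupGeneSpec("Prrc2c", "chr13", "autosome", 1, "retroposed",
                    n_marker_snvs = 8, expressed = FALSE),
        dupGeneSpec("Vom2r67", "chr1", "autosome", 1, "retroposed",
                    n_marker_snvs = 8, expressed = FALSE),
        dupGeneSpec("Xpr1", "chr13", "autosome", 2, "transposed",
                    n_marker_snvs = 10, expressed = FALSE),
        dupGeneSpec("Cntn4", "chr2", "autosome", 1, "transposed",
                    n_marker_snvs = 8, expressed = FALSE),
        dupGeneSpec("Lsm1", "chr5", "autosome", 1, "partial_transposed",
                    n_marker_snvs = 8, expressed = FALSE))
    simulationConfig(duplicated_genes = genes, seed = seed)
}

## union of male-specific and leave-one-out sites falling inside one gene
.geneSites <- function(gene_row, ms, strain_sites) {
    pick <- function(vp) {
        rr <- rowRanges(vp)
        hit <- as.character(seqnames(rr)) == gene_row$chromosome &
            start(rr) >= gene_row$start & start(rr) <= gene_row$end
        data.frame(position = start(rr)[hit],
                   alt = mcols(rr)$alt_allele[hit],
                   stringsAsFactors = FALSE)
    }
    tabs <- c(list(pick(ms)), lapply(strain_sites, pick))
    tab <- do.call(rbind, tabs)
    tab <- tab[!duplicated(tab$position), , drop = FALSE]
    tab[order(tab$position), , drop = FALSE]
}

## recover the MSY copy's coding sequence around a located insert: try the
## spliced cDNA first, then the genomic form spliced after matching
.extractMsyORF <- function(gene_seq, exons, contig, max_mm) {
    exons <- exons[order(exons$start), , drop = FALSE]
    gseq <- DNAString(as.character(gene_seq))
    cdna <- do.call(Biostrings::xscat, lapply(seq_len(nrow(exons)), function(i)
        subseq(gseq, exons$start[i], exons$end[i])))
    for (subject in list(contig, reverseComplement(contig))) {
        m <- matchPattern(cdna, subject, max.mismatch = max_mm)
        if (length(m) > 0)
            return(as.character(m[[1]]))
        g <- matchPattern(gseq, subject, max.mismatch = max_mm)
        if (length(g) > 0) {
            region <- as.character(g[[1]])
            return(paste(vapply(seq_len(nrow(exons)), function(i)
                substring(region, exons$start[i], exons$end[i]),
                character(1)), collapse = ""))
        }
    }
    NULL
}

#' Run the full duplication-detection pipeline
#'
#' Executes every stage in dependency order: simulate (or accept) a panel,
#' infer sample sex from Y-marker reads, apply the male/female segregation
#' filter and the leave-one-out strain-specific filter, summarize allele
#' frequencies per gene, cluster male-specific SNVs, build marker probes,
#' locate them on the MSY contigs, classify the duplication mechanism,
#' quantify marker expression (RPM) from a simulated transcript read set,
#' and assess pseudogene status.
#'
#' @param config A [simulationConfig()] (e.g. [demoConfig()]), or a path to
#'   a YAML/JSON file with its fields (gene entries under
#'   `duplicated_genes` are passed to [dupGeneSpec()]).
#' @param outdir optional output directory; when given, writes the variant
#'   table (`panel.vcf`), sex calls, the per-gene report TSV and a JSON
#'   run summary.
#' @param total_rna_reads,read_length transcript read-set size for the
#'   expression stage.
#' @param rpm_threshold pseudogene expression threshold (RPM).
#' @return list with `report` (one row per detected gene: SNV count, mean
#'   AF +/- SEM, strains lacking, MSY placement, mechanism, RPM,
#'   expression status), `sex_calls`, `summary`, `sim` (the generated data
#'   incl. the ground-truth record).
#' @export
runAll <- function(config, outdir = NULL, total_rna_reads = 20000L,
                   read_length = 100L, rpm_threshold = 0.01) {
    if (is.character(config)) config <- readSimulationConfig(config)
    stopifnot(inherits(config, "SimulationConfig"))
    sim <- simulatePanel(config)

    sex <- inferSex(sim$reads, sim$sry_probes,
                    declared_sex = setNames(sim$samples$declared_sex,
                                            sim$samples$sample))
    ms <- maleSpecificSites(sim$panel, sex)
    ss <- strainSpecificSites(sim$panel, sex)
    summ <- geneAFSummary(ms, sim$genes$table, sex, ss)

    ## transcript read set from the generator's ground truth
    frag <- vapply(sim$truth$genes, function(t)
        if (is.null(t$marker_fragment)) NA_character_ else t$marker_fragment,
        character(1))
    w <- vapply(sim$truth$genes, function(t)
        as.numeric(isTRUE(t$expressed)), numeric(1))
    have <- !is.na(frag)
    rna <- simulateReads(DNAStringSet(setNames(frag[have], names(frag)[have])),
                         weights = w[have], total_reads = total_rna_reads,
                         read_length = read_length, seed = config$seed,
                         background_weight = 2)

    rows <- lapply(seq_len(nrow(summ)), function(i) {
        g <- summ$gene[i]
        grow <- sim$genes$table[sim$genes$table$gene == g, ]
        ex <- sim$genes$exons[sim$genes$exons$gene == g,
                              c("start", "end"), drop = FALSE]
        gseq <- sim$genes$sequences[[g]]
        sites <- .geneSites(grow, ms, ss)
        base <- data.frame(gene = g, chromosome = grow$chromosome,
                           summ[i, c("n_snvs", "mean_af", "sem_af",
                                     "strains_lacking", "strain_specific_snvs")],
                           msy_contig = NA_character_,
                           msy_position = NA_integer_, msy_strand = NA_character_,
                           n_msy_hits = 0L, mechanism = "unplaced",
                           rpm = NA_real_, expression_status = NA_character_,
                           row.names = NULL, stringsAsFactors = FALSE)
        clust <- clusterSNVs(data.frame(chromosome = grow$chromosome,
                                        position = sites$position))
        if (nrow(clust) == 0) return(base)
        first <- clust[clust$cluster_id == 1, ]
        alt <- sites$alt[match(first$position, sites$position)]
        probe <- buildProbe(as.character(gseq), first$position, alt,
                            context_start = grow$start, flank = 11,
                            placement = "middle", probe_id = g,
                            source_gene = g)
        hits <- locateOnMsy(probe, sim$msy)
        if (nrow(hits) == 0) return(base)
        mm <- nrow(sites) + 3L
        mech <- classifyMechanism(gseq, ex, sim$msy[[hits$contig[1]]],
                                  source_chromosome = grow$chromosome,
                                  max_mismatch = mm)
        gene_rpm <- rpm(countMarkerHits(rna, probe), length(rna))
        orf <- .extractMsyORF(gseq, ex, sim$msy[[hits$contig[1]]], mm)
        status <- if (is.null(orf)) "indeterminate"
                  else assessPseudogene(orf, gene_rpm, rpm_threshold)$status
        base$msy_contig <- hits$contig[1]
        base$msy_position <- hits$position[1]
        base$msy_strand <- hits$strand[1]
        base$n_msy_hits <- nrow(hits)
        base$mechanism <- mech
        base$rpm <- gene_rpm
        base$expression_status <- status
        base
    })
    report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        writeVcfMinimal(sim$panel, file.path(outdir, "panel.vcf"))
        writeTsv(sex, file.path(outdir, "sex_calls.tsv"))
        writeTsv(report, file.path(outdir, "duplication_report.tsv"))
        writeXStringSet(sim$msy, file.path(outdir, "msy_contigs.fa"))
        jsonlite::write_json(
            list(package_version = as.character(utils::packageVersion("msySeg")),
                 config_hash = sprintf("%08x", stageSeed(
                     0L, paste(deparse(unclass(config)), collapse = ""))),
                 seed = config$seed,
                 n_samples = ncol(sim$panel),
                 n_male_class = sum(sex$inferred_class == "male_class"),
                 n_sites = nrow(sim$panel),
                 n_male_specific = nrow(ms),
                 genes = report$gene,
                 mechanisms = report$mechanism),
            file.path(outdir, "run_summary.json"), auto_unbox = TRUE)
    }
    list(report = report, sex_calls = sex, summary = summ, sim = sim)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names match [simulationConfig()]; entries of `duplicated_genes`
#' are passed to [dupGeneSpec()]. The format is chosen by file extension.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [simulationConfig()].
#' @export
readSimulationConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(raw$duplicated_genes)) {
        dg <- raw$duplicated_genes
        if (is.data.frame(dg))             # JSON arrays simplify to a frame
            dg <- lapply(seq_len(nrow(dg)), function(i) as.list(dg[i, ]))
        raw$duplicated_genes <- lapply(dg, function(g) {
            g <- g[!vapply(g, function(v) all(is.na(v)), logical(1))]
            if (!is.null(g$strains_lacking))
                g$strains_lacking <- unlist(g$strains_lacking)
            do.call(dupGeneSpec, g)
        })
    }
    if (!is.null(raw$chromosome_lengths))
        raw$chromosome_lengths <- unlist(raw$chromosome_lengths)
    do.call(simulationConfig, raw)
}
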