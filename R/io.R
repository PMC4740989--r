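#' Read a minimal VCF into a VariantPanel
#'
#' Reads a VCF 4.x file with a per-sample `AD` (allelic depth) FORMAT field
#' and returns a [VariantPanel]. Multi-allelic records are split into
#' biallelic records (one per alternate allele, with that allele's depth);
#' positions stay 1-based.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return A [VariantPanel].
#' @export
readVcfMinimal <- function(path) {
    if (!file.exists(path)) stop("VCF file not found: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
        stop("VCF ", path, " lacks the per-sample AD FORMAT field")
    vcf <- VariantAnnotation::expand(vcf)
    ad <- VariantAnnotation::geno(vcf)$AD
    n <- nrow(vcf); samples <- colnames(vcf)
    ref_m <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
    alt_m <- ref_m
    ## uniform AD lengths come back as an n x samples x alleles array,
    ## ragged ones as a matrix of integer vectors
    if (is.array(ad) && length(dim(ad)) == 3) {
        ref_m[] <- ad[, , 1]; alt_m[] <- ad[, , 2]
        if (anyNA(ref_m) || anyNA(alt_m))
            stop("malformed AD entries in ", path)
    } else {
        for (j in seq_along(samples)) {
            for (i in seq_len(n)) {
                v <- ad[i, j][[1]]
                if (length(v) < 2 || all(is.na(v)))
                    stop("malformed AD for sample ", samples[j],
                         " at record ", i)
                ref_m[i, j] <- v[1]; alt_m[i, j] <- v[2]
            }
        }
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    VariantPanel(chrom = as.character(seqnames(rr)), pos = start(rr),
                 ref_allele = as.character(VariantAnnotation::ref(vcf)),
                 alt_allele = as.character(VariantAnnotation::alt(vcf)),
                 ref = ref_m, alt = alt_m, samples = samples)
}

#' Write a VariantPanel as a minimal VCF
#'
#' Emits a biallelic VCF 4.2 subset: CHROM, POS, ID, REF, ALT and a
#' per-sample `AD` FORMAT field (`ref,alt`). [readVcfMinimal()] reads the
#' output back identically.
#'
#' @param panel A [VariantPanel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfMinimal <- function(panel, path) {
    rr <- rowRanges(panel)
    ref <- refCounts(panel); alt <- altCounts(panel)
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", colnames(panel)), collapse = "\t"))
    body <- vapply(seq_len(nrow(panel)), function(i) {
        paste(c(as.character(seqnames(rr))[i], start(rr)[i], ".",
                mcols(rr)$ref_allele[i], mcols(rr)$alt_allele[i], ".", ".",
                ".", "AD", paste0(ref[i, ], ",", alt[i, ])), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
    invisible(path)
}

#' @rdname pipelineIO
#' @param genes gene annotation data.frame (`gene`, `chromosome`, `start`,
#'   `end`).
#' @export
writeGeneTable <- function(genes, path) {
    write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Tabular readers/writers for pipeline files
#'
#' Plain TSV round-trips for the pipeline's tabular interfaces: gene
#' annotation, sample sheets / sex calls, long-format phenotype tables and
#' per-chromosome count tables.
#'
#' @param path file path.
#' @name pipelineIO
#' @return The read data.frame, or `path` invisibly for writers.
#' @export
readGeneTable <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname pipelineIO
#' @param x data.frame to write.
#' @export
writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname pipelineIO
#' @export
readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a probe panel TSV
#'
#' Columns: `copy`, `sequence`, and optionally `snv_offsets`
#' (comma-separated 1-based offsets).
#'
#' @param path TSV path.
#' @return A probe panel as from [markerProbes()].
#' @export
readProbePanel <- function(path) {
    df <- readTsv(path)
    offs <- if ("snv_offsets" %in% names(df))
        lapply(strsplit(as.character(df$snv_offsets), ","), as.integer)
    else NULL
    markerProbes(setNames(df$sequence, df$copy), copy = df$copy,
                 snv_offsets = offs)
}
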