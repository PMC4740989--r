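#' Cluster male-specific SNVs by proximity
#'
#' Chains consecutive same-chromosome sites whose inter-site distance is at
#' most `max_gap` bases (transitive single linkage: positions 100, 118, 136
#' at 18-base spacing form one cluster). Clusters with a single SNV are
#' discarded -- two or more nearby SNVs are needed so that a single short
#' read can carry multiple identifying variants.
#'
#' @param sites A [VariantPanel] (typically from [maleSpecificSites()]), or a
#'   data.frame with columns `chromosome` and `position`.
#' @param max_gap maximum distance in bases between consecutive cluster
#'   members (default 20).
#' @return data.frame with columns `cluster_id`, `chromosome`, `position`
#'   (one row per clustered SNV, sorted); zero rows when nothing clusters.
#' @export
clusterSNVs <- function(sites, max_gap = 20L) {
    if (is(sites, "VariantPanel")) {
        df <- data.frame(chromosome = as.character(seqnames(rowRanges(sites))),
                         position = start(rowRanges(sites)))
    } else df <- sites[, c("chromosome", "position")]
    if (nrow(df) == 0)
        return(data.frame(cluster_id = integer(0), chromosome = character(0),
                          position = integer(0)))
    df <- df[order(df$chromosome, df$position), , drop = FALSE]
    new_chain <- c(TRUE, df$chromosome[-1] != df$chromosome[-nrow(df)] |
                         diff(df$position) > max_gap)
    df$cluster_id <- cumsum(new_chain)
    keep <- df$cluster_id %in% names(which(table(df$cluster_id) >= 2))
    df <- df[keep, , drop = FALSE]
    df$cluster_id <- as.integer(factor(df$cluster_id))
    rownames(df) <- NULL
    df[, c("cluster_id", "chromosome", "position")]
}

#' Build a marker probe over an SNV cluster
#'
#' Extracts reference context around a cluster of male-specific SNVs and
#' substitutes the alternate allele at each SNV position, producing a probe
#' whose every exact match necessarily covers all its identifying SNVs. With
#' `placement = "middle"` the cluster is centered (probe spans cluster +/-
#' `flank`); with `placement = "ends"` the outermost (leftmost) SNV sits at
#' the probe boundary and the probe extends `2 * flank` past the cluster.
#'
#' @param context a [Biostrings::DNAString] (or character) of reference
#'   sequence, with `context_start` giving the chromosome coordinate of its
#'   first base.
#' @param positions chromosome coordinates of the clustered SNVs.
#' @param alt_alleles alternate base per SNV.
#' @param context_start 1-based coordinate of `context[1]` (default 1).
#' @param flank bases of context beyond the cluster span on each side
#'   (default 11, giving a 24-mer for a 2-SNV cluster spanning 2 bases).
#' @param placement `"middle"` or `"ends"`.
#' @param probe_id,source_gene metadata carried on the probe.
#' @return A length-1 [Biostrings::DNAStringSet] with metadata columns
#'   `probe_id`, `source_gene`, `placement`, `snv_offsets` (1-based offsets
#'   of the SNVs within the probe) and `genome_start`.
#' @export
buildProbe <- function(context, positions, alt_alleles, context_start = 1L,
                       flank = 11L, placement = c("middle", "ends"),
                       probe_id = "probe1", source_gene = NA_character_) {
    placement <- match.arg(placement)
    context <- as.character(context)
    positions <- as.integer(positions)
    o <- order(positions)
    positions <- positions[o]; alt_alleles <- alt_alleles[o]
    span_lo <- min(positions); span_hi <- max(positions)
    probe_lo <- if (placement == "middle") span_lo - flank else span_lo
    probe_hi <- if (placement == "middle") span_hi + flank else span_hi + 2L * flank
    if (probe_lo < context_start ||
        probe_hi > context_start + nchar(context) - 1L)
        stop("reference context too short to cover the cluster with flank ", flank)
    seq <- substring(context, probe_lo - context_start + 1L,
                     probe_hi - context_start + 1L)
    offs <- positions - probe_lo + 1L
    chars <- strsplit(seq, "")[[1]]
    chars[offs] <- toupper(alt_alleles)
    probe <- DNAStringSet(paste(chars, collapse = ""))
    names(probe) <- probe_id
    mcols(probe) <- DataFrame(probe_id = probe_id, source_gene = source_gene,
                              placement = placement,
                              snv_offsets = IntegerList(list(offs)),
                              genome_start = probe_lo)
    .validateProbes(probe)
    probe
}

.validateProbes <- function(probes, min_len = 24L) {
    if (any(width(probes) < min_len))
        stop("marker probes must be at least ", min_len, " nt")
    offs <- mcols(probes)$snv_offsets
    if (!is.null(offs)) {
        bad <- any(unlist(offs) < 1L) ||
            any(max(offs) > width(probes))
        if (bad) stop("snv_offsets outside probe bounds")
    }
    invisible(probes)
}

#' Locate a probe on MSY contigs
#'
#' Exact search of the probe and its reverse complement against a set of
#' MSY contigs. Probes with embedded SNVs of >= 24 nt make spurious matches
#' negligible, so hits localize the duplicated copy.
#'
#' @param probe a length-1 [Biostrings::DNAStringSet] (or `DNAString` /
#'   character) over `{A,C,G,T}`.
#' @param contigs a named [Biostrings::DNAStringSet] of MSY contigs;
#'   must be non-empty.
#' @return data.frame with columns `contig`, `position` (1-based start on
#'   the contig's forward strand) and `strand` (`"+"`/`"-"`); zero rows when
#'   the probe is absent.
#' @export
locateOnMsy <- function(probe, contigs) {
    if (length(contigs) == 0) stop("contig set must be non-empty")
    p <- if (is(probe, "DNAStringSet")) probe[[1]] else DNAString(as.character(probe))
    freq <- alphabetFrequency(p)
    if (sum(freq[c("A", "C", "G", "T")]) != length(p))
        stop("probe contains degenerate (non-ACGT) bases")
    if (is.null(names(contigs)))
        names(contigs) <- paste0("contig", seq_along(contigs))
    rc <- reverseComplement(p)
    hits <- lapply(seq_along(contigs), function(i) {
        fwd <- matchPattern(p, contigs[[i]])
        rev <- matchPattern(rc, contigs[[i]])
        rbind(
            if (length(fwd)) data.frame(contig = names(contigs)[i],
                                        position = BiocGenerics::start(fwd),
                                        strand = "+") else NULL,
            if (length(rev)) data.frame(contig = names(contigs)[i],
                                        position = BiocGenerics::start(rev),
                                        strand = "-") else NULL)
    })
    out <- do.call(rbind, hits)
    if (is.null(out))
        out <- data.frame(contig = character(0), position = integer(0),
                          strand = character(0))
    rownames(out) <- NULL
    out
}

#' Classify the duplication mechanism at an MSY locus
#'
#' Decides how a source gene reached the MSY by comparing its exon/intron
#' structure against the sequence around the placed locus. A spliced
#' (intron-free, exon-contiguous) insert is `retroposed`; an insert
#' retaining normal introns is `transposed`; an insert carrying only a
#' proper subset of exons is `partial_transposed`; a source gene natively
#' annotated on the MSY is `msy_duplication`. Because the Y-borne copy
#' carries the marker SNVs that identified it, exon/cDNA matching tolerates
#' up to `max_mismatch` mismatches; introns (which carry no marker SNVs)
#' are matched with at most 1 mismatch per kilobase.
#'
#' For an intronless source gene the retro/transposed distinction is
#' undefined; the call defaults to `retroposed` with a warning.
#'
#' @param gene_seq genomic source sequence of the gene ([Biostrings::DNAString]
#'   or character), exons and introns included.
#' @param exons data.frame with `start`, `end` (1-based, inclusive)
#'   coordinates of exons *within* `gene_seq`.
#' @param locus_seq MSY sequence around the placed locus (both strands are
#'   searched).
#' @param source_chromosome chromosome of the source gene; a Y/MSY name
#'   short-circuits to `msy_duplication`.
#' @param msy_names chromosome names treated as MSY (default `"chrY"`, `"Y"`).
#' @param max_mismatch mismatch allowance for exon/cDNA matches (default 5;
#'   the pipeline passes the number of planted/observed marker SNVs).
#' @return One of `"retroposed"`, `"transposed"`, `"partial_transposed"`,
#'   `"msy_duplication"`, or `"unplaced"` when nothing matches.
#' @export
classifyMechanism <- function(gene_seq, exons, locus_seq,
                              source_chromosome = NA_character_,
                              msy_names = c("chrY", "Y"),
                              max_mismatch = 5L) {
    if (!is.na(source_chromosome) && source_chromosome %in% msy_names)
        return("msy_duplication")
    gene_seq <- DNAString(as.character(gene_seq))
    locus <- DNAString(as.character(locus_seq))
    locus_rc <- reverseComplement(locus)
    present <- function(x, mm) {
        length(matchPattern(x, locus, max.mismatch = mm)) > 0 ||
        length(matchPattern(x, locus_rc, max.mismatch = mm)) > 0
    }
    exons <- exons[order(exons$start), , drop = FALSE]
    exon_seqs <- lapply(seq_len(nrow(exons)),
                        function(i) subseq(gene_seq, exons$start[i], exons$end[i]))
    n_ex <- length(exon_seqs)
    ## introns = gaps between consecutive exons
    introns <- list()
    if (n_ex > 1) {
        for (i in seq_len(n_ex - 1)) {
            lo <- exons$end[i] + 1L; hi <- exons$start[i + 1L] - 1L
            if (hi >= lo) introns <- c(introns, list(subseq(gene_seq, lo, hi)))
        }
    }
    if (length(introns) == 0) {
        cdna <- do.call(Biostrings::xscat, exon_seqs)
        if (present(cdna, max_mismatch)) {
            warning("intronless source gene: retro/transposed distinction ",
                    "undefined, defaulting to retroposed")
            return("retroposed")
        }
        return("unplaced")
    }
    intron_mm <- vapply(introns, function(s) max(1L, length(s) %/% 1000L), integer(1))
    intron_in <- mapply(function(s, mm) present(s, mm), introns, intron_mm)
    exon_in <- vapply(exon_seqs, function(s) present(s, max_mismatch), logical(1))
    if (any(intron_in)) {
        if (all(exon_in)) return("transposed")
        if (any(exon_in)) return("partial_transposed")
        return("unplaced")
    }
    cdna <- do.call(Biostrings::xscat, exon_seqs)
    if (present(cdna, max_mismatch)) return("retroposed")
    if (all(exon_in)) return("retroposed")
    if (any(exon_in)) return("partial_transposed")
    "unplaced"
}

#' Assess pseudogene status of an MSY gene copy
#'
#' Joint evidence rule: a disrupted open reading frame (premature stop
#' codon) together with marker expression below `rpm_threshold` calls the
#' copy a `pseudogene`; an intact ORF with expression at or above the
#' threshold is `functional`; conflicting evidence is `indeterminate`.
#' When the sequence length is not a multiple of 3 all three frames are
#' scanned and the frame whose first stop falls latest is taken as the ORF.
#'
#' @param orf_seq coding sequence of the MSY copy (character or
#'   [Biostrings::DNAString]).
#' @param rpm observed marker expression in reads per million (>= 0).
#' @param rpm_threshold expression threshold (default 0.01 RPM; a copy with
#'   a handful of reads among billions sits far below this).
#' @return list with `status` (`"pseudogene"`, `"functional"`,
#'   `"indeterminate"`), `premature_stop` (flag) and `frame` used (0-2).
#' @export
assessPseudogene <- function(orf_seq, rpm, rpm_threshold = 0.01) {
    if (rpm < 0) stop("rpm must be >= 0")
    s <- as.character(orf_seq)
    frames <- if (nchar(s) %% 3 == 0) 0L else 0:2
    best <- NULL
    for (f in frames) {
        sub <- substring(s, 1L + f, nchar(s))
        sub <- substring(sub, 1L, 3L * (nchar(sub) %/% 3L))
        if (nchar(sub) < 3) next
        aa <- as.character(suppressWarnings(
            translate(DNAString(sub), if.fuzzy.codon = "X")))
        stops <- gregexpr("\\*", aa)[[1]]
        internal <- stops[stops > 0 & stops < nchar(aa)]
        first_stop <- if (length(internal)) min(internal) else Inf
        if (is.null(best) || first_stop > best$first_stop)
            best <- list(frame = f, first_stop = first_stop)
    }
    premature <- is.finite(best$first_stop)
    status <- if (premature && rpm < rpm_threshold) "pseudogene"
              else if (!premature && rpm >= rpm_threshold) "functional"
              else "indeterminate"
    list(status = status, premature_stop = premature, frame = best$frame)
}
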