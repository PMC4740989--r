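Package: msySeg
Title: Male/Female Variant Segregation to Detect Gene Duplications onto
    the Male-Specific Y Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects autosomal and X-linked genes duplicated onto the
    male-specific region of the Y chromosome (MSY) from male versus female
    whole-genome variant calls, using allele-frequency segregation filtering
    (female 0%, male 0.1-99.9%), leave-one-out strain-specific SNV absence,
    and the analytic expectation that a single Y-borne copy of an autosomal
    gene yields ~33% alternate-allele read fraction in males. Clusters
    male-specific SNVs into marker probes, localizes them on MSY contigs,
    classifies the duplication mechanism (retroposed, transposed, partial),
    and assesses pseudogene status from ORF disruption plus near-zero
    marker expression. Quantifies copy-specific expression of multi-copy Y
    genes (e.g. Sry paralogs) by exact marker-SNV probe matching in RNA-seq
    reads with reads-per-million normalization, computes per-chromosome SNV
    density and the MSY fold-elevation, and scores MSY phenotypic
    contribution in consomic strain panels (Mann-Whitney with Bonferroni
    adjustment, sex-difference classification, per-Mb and per-10-genes
    contribution folds). A synthetic-data module generates genome panels,
    read sets and phenotype tables with known ground truth so the whole
    pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, GeneRegulation
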