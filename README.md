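# msySeg

Detecting gene duplications onto the male-specific Y chromosome (MSY) from
male/female whole-genome variant data, and scoring what the MSY does —
to copy-specific expression and to whole-organism phenotypes — in inbred
rat strain panels.

## The problem

The MSY never recombines and passes clonally from father to son. When an
autosomal or X-linked gene acquires a copy on the MSY, short reads from the
Y-borne copy still align to the source locus (reference assemblies often
lack a complete MSY), where they masquerade as heterozygous variants. But
the masquerade has a signature: **every male** carries the variant at a
predictable allele fraction, and **no female** carries it at all. For `c`
Y-borne copies the expected alternate-read fraction in a male is

```
AF = c / (c + 2)   (autosomal source gene: two source doses)
AF = c / (c + 1)   (X-linked source gene: one X dose in males)
```

so a single duplicated autosomal copy sits at 1/3 — the classic "33%
heterozygote" that is in fact a male-specific duplication.

msySeg implements this segregation analysis as a tested pipeline:

- **Sex inference** — classify each sequenced genome as female or
  male-class by exact Y-marker (Sry coding) probe matching in its reads;
  Sry-contaminated declared-females are treated as males.
- **Segregation filter** — keep sites with female allele frequency 0% and
  every male-class genome inside the 0.1–99.9% window; a leave-one-out
  pass finds strains whose MSY lacks a given copy.
- **Per-gene summaries** — SNV counts, mean allele frequency ± SEM across
  sites, against the analytic `c/(c+2)` / `c/(c+1)` expectation.
- **Duplication mapping** — cluster male-specific SNVs (two or more within
  20 bases), build marker probes that necessarily cover their SNVs, place
  them on MSY contigs, classify the mechanism (retroposed = spliced,
  intronless insert; transposed = introns retained; partial insertions),
  and call pseudogenes from ORF disruption plus near-zero expression.
- **Marker expression** — copy-specific transcript counting (e.g. the 11
  rat Sry paralogs) by exact probe matching with reads-per-million (RPM)
  normalization, Y-vs-homolog transcript fractions, and a
  distinguishability analysis that flags copies no short read can resolve
  ("nd").
- **SNV density** — per-chromosome SNVs/Mb and the MSY fold-elevation
  across strains.
- **Consomic phenotype statistics** — Mann-Whitney tests with Bonferroni
  adjustment for consomic-vs-parental comparisons, male-vs-female
  sex-difference classification, and per-Mb / per-10-genes contribution
  folds.
- **Synthetic data** — a generator that plants duplications with known
  mechanism, copy number, strain absences and expression into a
  male/female panel (binomial read sampling at fixed coverage), so the
  whole pipeline runs and is testable without external archives.

## Worked example

The demo panel plants ten duplications — seven retroposed (one absent from
the FHL strain's MSY, one pseudogenized by a premature stop), two
transposed (one in two Y copies) and one partial insertion — into an
18-male / 5-female panel at 50× coverage:

```r
library(msySeg)
res <- runAll(demoConfig(seed = 1))
res$report
```

```
      gene chromosome n_snvs mean_af  sem_af strains_lacking          mechanism n_msy_hits    rpm expression_status
1  Vom2r67       chr1      8   0.327 0.00581                         retroposed          1      0     indeterminate
2    Limd2      chr10     10   0.331 0.00575                         retroposed          1      0        pseudogene
3   Havcr2      chr10     10   0.327 0.00562                         retroposed          1      0     indeterminate
4   Prrc2c      chr13      8   0.339 0.00490                         retroposed          1      0     indeterminate
5     Xpr1      chr13     10   0.500 0.00429                         transposed          2      0     indeterminate
6     Ect2       chr2     10   0.334 0.00373                         retroposed          1      0     indeterminate
7    Cntn4       chr2      8   0.331 0.00716                         transposed          1      0     indeterminate
8     Lsm1       chr5      8   0.329 0.00741                 partial_transposed          1      0     indeterminate
9   Ube2q2       chr8     10   0.332 0.00423                         retroposed          1      0     indeterminate
10   Med14       chrX     12   0.465 0.00665             FHL         retroposed          1 244150        functional
```

Reading the table: single-copy autosomal genes sit at mean AF ≈ 1/3 and
the two-copy `Xpr1` at 2/(2+2) = 0.5 (`n_msy_hits = 2`: both Y copies
located). The X-linked `Med14` would sit at 1/2 but its absence from FHL
(recovered by the leave-one-out filter, `strains_lacking = FHL`) pulls the
18-male average to 0.5 × 17/18 ≈ 0.47. `Limd2` combines a premature stop
in its MSY ORF with zero marker RPM and is called a pseudogene; silent but
ORF-intact copies stay `indeterminate`; expressed intact copies are
`functional`.

The packaged consomic phenotype table reproduces the published
sex-difference classification for the FHH-Y^BN panel:

```r
tab <- consomicSexDifferenceTable()
fhh <- tab[tab$consomic == "FHH-YBN/Mcwi", ]
classifySexDifference(fhh$fhh_mf_significant == "Yes",
                      fhh$bn_mf_significant == "Yes",
                      labels = c("FHH", "BN"))$counts
#>     both FHH_only  BN_only  neither
#>       15        2       10        0
```

(and `both = 22, SS_only = 1, BN_only = 3` for the SS-Y^BN panel).

A command-line surface over the same functions ships at
`inst/scripts/msy-seg.R` (subcommands `simulate`, `sex-call`, `segregate`,
`map-duplications`, `quantify`, `snv-density`, `phenotype`, `run-all`).

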