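---
title: "Detecting MSY gene duplications by male/female variant segregation"
author: "msySeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting MSY gene duplications by male/female variant segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msySeg)
```

## The model

The male-specific region of the Y chromosome (MSY) is haploid, clonal and
male-restricted. A gene copied from an autosome or the X onto the MSY
therefore produces a diagnostic read-count pattern at any position where
the Y-borne copy differs from its source: reads from the Y copy co-align
with reads from the source locus (reference assemblies frequently lack a
complete MSY), and the alternate-allele fraction in a male is determined
by dose counting. A male carries two autosomal doses plus `c` Y doses of
an autosomal source gene, so

$$\mathrm{AF}_{\mathrm{auto}} = \frac{c}{c+2}, \qquad
  \mathrm{AF}_{\mathrm{X}} = \frac{c}{c+1},$$

the X case having a single source dose in males. `c = 1` gives the 1/3
("33%") expectation for the common single-copy autosomal duplication;
the function is strictly increasing in `c` and approaches 1, which also
means copy number is only weakly identifiable from AF at large `c` — the
package exposes `expectedDuplicationAF()` but deliberately does not
invert it into a copy-number estimator.

Females carry no Y, so their AF at a genuine MSY-derived site is exactly
zero. The segregation filter (`maleSpecificSites()`) encodes both sides:
every female at AF ≤ 0 and every male-class sample inside an inclusive
window of 0.001–0.999 (0.1%–99.9%). The window's role is to demand
*presence without fixation* in males: a fixed variant (AF = 1) is an
ordinary strain difference, not a duplication signature.

Three further stages build on the filtered sites:

1. **Leave-one-out strain absences** (`strainSpecificSites()`): one male
   at a time is moved to the female side of the filter. A site passing
   for strain *s* is evidence that *s*'s MSY lacks the copy carrying it.
   The definition is strictly one-at-a-time: a site absent from two
   strains satisfies neither single-strain pass and is attributed to
   neither — a conservative choice that avoids enumerating subsets.
2. **Per-gene summaries** (`geneAFSummary()`): per site, AF is averaged
   over male-class strains (unweighted — each strain is one inbred
   genome, so depth-weighting would weight sequencing runs, not
   biology); per gene, the site means are averaged with SEM across
   sites, `NA` for single-site genes. Sites recovered only by the
   leave-one-out pass are unioned in, since a gene absent from one
   strain has *no* sites passing the main filter. A strain flagged at
   every site of a gene is reported as lacking the gene; smaller
   per-strain absences are listed as strain-specific SNV counts.
3. **Mapping and mechanism** (`clusterSNVs()`, `buildProbe()`,
   `locateOnMsy()`, `classifyMechanism()`, `assessPseudogene()`),
   described below.

## Sex inference

Samples are classified from their reads, not their labels
(`inferSex()`): a sample with at least one read containing a Y-marker
(Sry coding) probe — or its reverse complement — as an exact substring is
male-class. There is deliberately no minimum count: any Sry evidence
implies Y-bearing DNA in the library, and a contaminated female's variant
calls may carry Y-derived alleles with the same per-read probability as
her Sry reads, so she must be filtered as a male. The monotonicity this
implies (adding reads can only move a call female → male-class) is
asserted as a property test.

Exact substring matching of ≥ 24-nt probes on both strands replaces
alignment with an identity/E-value criterion. For 100%-identity hits at
these lengths the two coincide for practical purposes, and exact matching
is deterministic and dependency-free. The same design is used for all
marker counting (`countMarkerHits()`), with two further rules: a read
containing a probe twice counts once (the unit is the positive read), and
probes below 24 nt are rejected at panel construction, keeping the
false-match probability per read far below one in 4^24.

## Probes, mechanism, pseudogenes

Male-specific SNVs are chained into clusters when consecutive
same-chromosome sites lie within `max_gap = 20` bases, transitively: a
run at 18-base spacings is one cluster. (The alternative — pairwise-only
linking — was rejected because it makes cluster membership depend on
arbitrary tie-breaks; the transitive reading is order-invariant and is
cross-checked against a closure oracle in the tests.) Singleton clusters
are discarded: two or more SNVs in one read-length window are what make a
single read carry multiple identifying variants.

`buildProbe()` substitutes the alternate alleles into reference context so
that any exact probe match necessarily covers all its SNVs, with the
cluster centered (`placement = "middle"`, default flank 11 nt, giving a
24-mer for a two-base cluster) or the outermost SNV on the probe boundary
(`"ends"`). `locateOnMsy()` is an exact search of probe and reverse
complement over the supplied MSY contigs.

`classifyMechanism()` compares the gene's exon/intron structure against
the placed locus: intron sequence present → transposed (all exons) or
partial insertion (a proper subset); introns absent but the spliced cDNA
contiguous → retroposed; a source gene natively annotated on the MSY
short-circuits to its own class. Two numerical choices matter here.
First, the Y-borne copy *differs from the source by exactly the marker
SNVs that identified it*, so exon/cDNA matching tolerates `max_mismatch`
mismatches (the pipeline passes the observed SNV count plus a margin of
3 to absorb a planted stop codon); introns carry no marker SNVs and are
matched at ≤ 1 mismatch per kb. Second, an intronless source gene cannot
discriminate retro- from transposition; the call defaults to retroposed
with a warning, since a spliced single-exon insert is indistinguishable
from a genomic one by sequence content alone.

`assessPseudogene()` demands *joint* evidence: a premature stop in the
translated MSY ORF **and** marker expression below `rpm_threshold`
(default 0.01 reads per million — a copy with a handful of reads among
billions sits orders of magnitude below this) → pseudogene; intact ORF
and expression at or above threshold → functional; any conflict →
indeterminate. Sequences whose length is not a multiple of three are
frame-scanned and the frame with the latest first stop is taken as the
ORF.

## Expression quantification

`rpm()` is hits/total × 10⁶; `yFraction()` is y/(y + homolog), 0.5 being
an equal transcript split between the MSY copy and its X/autosomal
homolog. `copyProfile()` classifies datasets by whether any probe other
than a focal copy is positive (RPM > 0 — the natural threshold when the
unit is an exactly matched read). `distinguishability()` formalizes the
"nd" (not determined) notion: a copy is nd iff no window of at most the
read length contains an allele combination unique to it. Windows are
enumerated starting at each variant position; this is sufficient because
signature uniqueness is monotone in window content, so only maximal
windows need checking.

## Density and phenotype statistics

`densityTable()` normalizes per-strain SNV counts to chromosome size in
Mb. `msyFold()` divides each strain's MSY density by the **unweighted
mean** of its non-MSY chromosome densities — matching a per-chromosome
box-plot framing in which each chromosome is one observation — and
reports mean ± SEM across strains. The length-weighted genome-wide
alternative is exposed as `weighted = TRUE`; with near-uniform background
rates the two differ negligibly, but the unweighted mean is the default
because the per-chromosome framing is the quantity the fold is meant to
describe.

`mannWhitney()` is two-sided, exact by enumeration when
`min(nA, nB) ≤ 8` with no ties, and a tie-corrected normal approximation
otherwise; `bonferroni()` multiplies by an explicit family size `m` and
caps at 1. The family is the number of phenotypes tested per consomic
comparison (`comparePhenotypes()` defaults `m` to the number of
phenotype/treatment combinations in the panel) — the per-consomic panel
is the natural testing unit, and the same family is applied to the
male-vs-female parental tests so the two flag types are comparable.
Significance is adjusted p < 0.05 throughout.

`classifySexDifference()` counts rows as given — duplicated
phenotype/treatment rows in the packaged consomic table are kept as
distinct rows, because the published class counts are row-level counts.
`contributionFold()` computes `(n_sig/n_measured)/size_mb` and the
per-10-genes analogue, reporting the MSY fold against both the mean and
the maximum of the other chromosomes ("higher than any other").
Chromosomes with no measured phenotypes are skipped with a warning rather
than treated as zero evidence. The package reports per-panel folds and
their plain mean; it does not attach an SEM to a two-panel mean, which
would be statistically empty.

## The synthetic-data generator

`simulatePanel()` emulates the study design the analysis assumes:

- a 23-genome panel by default — 18 male-class, 5 female — with optional
  Sry contamination of declared females (trace marker fraction, default
  0.1% of reads, classified male downstream but carrying no alternate
  counts in the variant table);
- per-site read depth fixed at `coverage` (default 50) with alternate
  counts Binomial(coverage, AF expectation) — constant-depth binomial
  rather than Poisson-depth sampling, so every oracle SD in the tests has
  a closed form;
- a scaled-down genome (autosomes and X at 10 Mb, MSY at 2 Mb) with
  background SNVs at 100 SNVs/Mb/strain, the MSY rate elevated by
  `msy_rate_multiplier` (default 2). Background counts are drawn
  per strain × chromosome as Poisson(rate × length); only a subsample is
  materialized as variant-table rows (strain-private homozygous sites,
  which the segregation filter must reject), keeping panels small while
  the full counts feed the density module;
- planted genes with marker SNVs in close exonic pairs (8–12 bases
  apart), alternate bases chosen to never create stop codons, inserts
  spliced/unspliced/truncated per mechanism and placed on either strand
  of the MSY contig; premature stops are planted in-frame and clear of
  marker positions;
- one top-level seed with deterministic per-stage substreams derived from
  stage names (`stageSeed()`), so reruns of any stage are byte-identical.

What the generator does **not** emulate: sequencing error, indels, read
mapping and mapping ambiguity, repeat content (rat MSY is highly
repetitive), depth variation, or linked selection. Passing tests
therefore demonstrate that the *inference logic* is correct under the
stated statistical model — not that real repeat-dense MSY data will be as
clean. In particular, exact probe matching has no tolerance for
sequencing errors inside the probe; on real data this biases marker
counts downward by roughly the per-probe error rate, uniformly across
copies.

Zero-depth entries are treated as missing, and a site with missing AF in
any required sample is excluded from candidacy rather than imputed as
AF = 0: absence of evidence is not reference homozygosity. Under low
coverage this costs sensitivity (a true male-specific site is dropped
whenever any sample has no reads); the alternative — imputing 0 — would
instead create false strain-absence calls, which we consider the worse
error.

## Problem sizes and test tolerances

The test suite runs everything at scales chosen to make the statistical
assertions sharp but quick: parameter recovery uses 200 genes × 30 SNVs
at 50× coverage over an 18-male panel (each gene's mean must fall within
3 SEM of its analytic expectation, ≥ 95% of genes); the density fold
uses 7 strains (mean within 3 SEM of the planted two-fold elevation);
oracle equivalences use 100 randomized instances per operation with
brute-force enumeration (Mann-Whitney enumeration is capped at groups of
size 6, where C(12,6) = 924 assignments are exhaustively scored); the
end-to-end demo uses ten genes. These sizes are the package's own test
design; the functions themselves impose no such limits.

## Known limitations

- Copy-number estimation from AF is not provided (flat response at large
  `c`, see above); multi-copy genes are reported with all probe hits.
- `classifyMechanism()` assumes the insert is co-linear with the source
  gene (no inversions or internal rearrangements within the insert).
- The pseudogene call examines a single ORF per locus; genes with
  alternative reading frames or programmed frameshifts are out of scope.
- Phenotype comparisons are two-group rank tests; no mixed models,
  repeated-measures structure or covariate adjustment.
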