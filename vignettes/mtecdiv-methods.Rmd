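---
title: "Quantifying self-antigen representation diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying self-antigen representation diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtecdiv)
```

## The problem

Medullary thymic epithelial cells (mTECs) tolerize developing T cells by
promiscuously expressing genes that are otherwise restricted to single
peripheral tissues. How completely an mTEC population *mirrors* the
periphery has three layers: which genes are expressed at all, which splice
isoforms of those genes are produced, and which RNA-edited variants
(A-to-I by ADAR enzymes, C-to-U by APOBEC1) appear. `mtecdiv` implements
the statistics for all three layers over multi-tissue RNA-seq panels, plus
a synthetic panel generator with planted ground truth so that every
detector can be validated by exact recovery rather than by eyeballing.

## Expression breadth

Gene-level counts are normalized by each gene's **exonic length** (the
length of the union of its exon intervals) to reads per nucleotide
(reads/nt). A gene is *expressed* in a sample when it reaches at least
0.01 reads/nt; the boundary is inclusive. Union length is used because it
is the only length that makes reads/nt comparable across isoform-rich
genes. FPKM-based rules use the reference formula
$\mathrm{FPKM} = 10^9 \, c \,/\, (N \, \ell)$ with $c$ the gene count,
$N$ the sample's aligned-read total and $\ell$ the exonic length;
externally quantified FPKM tables are accepted verbatim.

Samples of unequal depth are made comparable by subsampling count columns
to a fixed number of reads with a multivariate hypergeometric draw. This
operates on count tables rather than alignments, which is exact for the
totals and means of read-level sampling; it is an approximation only in
that reads are exchangeable within a gene.

## TRA detection and mirroring

A tissue-restricted antigen (TRA) gene is highly expressed
($\mathrm{FPKM} > 5$, strict) in exactly one non-excluded tissue and lowly
expressed ($\mathrm{FPKM} < 0.3$, strict) in every other. Values in the
middle band $[0.3, 5]$ make a gene neither high nor low: they disqualify
TRA status in that tissue *and* block it elsewhere. The mTEC-like
reference samples are excluded from the restriction test, so promiscuous
expression in the reference cannot veto a TRA call. Mirror coverage of
tissue $t$ is the fraction of its TRA genes with reference FPKM above 0.3.

The leave-one-out matrix asks a sharper question pairwise: of the genes
expressed (reads/nt strictly above 0.01) in tissue $t_1$ and in no other
sample except possibly $t_2$, what fraction is expressed in $t_2$? The
matrix is asymmetric by construction (the denominator depends on $t_1$)
and is left unsymmetrized; diagonal and zero-denominator entries are
undefined. The two expression rules (FPKM > 0.3 for mirror coverage,
reads/nt > 0.01 for leave-one-out) are deliberately separate
configuration fields because the analyses use different units.

## Splice-junction diversity

All junction logic runs on STAR-style junction tables. Internally the
package stores introns as 0-based half-open intervals; the 1-based
inclusive `SJ.out.tab` dialect is converted only at the I/O boundary, so
no off-by-one arithmetic leaks into the analysis. A junction belongs to a
gene when both flanking exonic bases fall inside the gene's span and the
strands are compatible; with overlapping genes the tie goes to the longer
span, then to the lexicographically smaller id. A gene is *alternatively
spliced* in a sample when two of its detected junctions (at least one
unique read) share a donor or an acceptor position.

A *TRA junction* of tissue $t$ needs at least 10 unique reads in $t$,
zero reads in every other non-excluded tissue (the "not in any other
tissue" rule is read as zero tolerance; `max_other_reads` exposes the
looser reading), and a host gene expressed (FPKM > 0.3) in at least one
other tissue -- restriction at the isoform level inside a shared gene.
Junction coverage in the reference uses a 1-read detection floor: the
10-read rule defines restriction, not detection. Coverage differences
between two reference samples are tested per tissue with a two-sided
Fisher exact test on covered/uncovered counts; the choice of Fisher for
this comparison is a design assumption, recorded here.

## RNA-editing statistics

Per site and sample, the editing level is edited reads over covering
reads, undefined at zero coverage. The four-way support classification
(no coverage / below 10 reads / well-supported unedited / well-supported
edited) drives heat-map style summaries. The **editing rate** of a sample
is the fraction of annotated editable sites covered at `min_total` reads
or more at which the edited variant is seen (`min_edited` or more edited
reads). Two presets reflect two uses: the global rate uses
`min_edited = 1`; the stringent known-site screen uses `min_edited = 5`.
The coverage floor for "expressed" defaults to 1 read and is
configurable, since that floor is genuinely a free choice.

Per-site two-sample comparisons use a two-sided Fisher exact test under
the point-probability rule (the p-value sums all hypergeometric outcomes
no more likely than the observed table, with the conventional $10^{-7}$
relative slack against floating-point ties); two-sided conventions
differ across software, so the rule is stated. Benjamini-Hochberg
correction excludes undefined tests from the test count. The aggregate
editing level over a site panel is total edited over total covering
reads -- the coverage-weighted mean of site levels -- and its association
with editing-enzyme expression (median-of-ratios normalized counts) is
summarized by Pearson correlation by default, Spearman on request.

Hyper-edited reads are classified from per-read mismatch profiles: at
least 5 mismatches of which at least 80% are A>G on the plus strand or
T>C on the minus strand. The published screen's phrasing of the 80% rule
is ambiguous, so both thresholds are exposed as arguments. The density
statistic is unique hyper-editing sites per million aligned reads. The
full realignment-based discovery of hyper-edited reads from unmapped data
is out of scope: this package classifies already-extracted mismatch
records and normalizes site counts.

## The synthetic panel

The generator emulates a panel of single-sample tissues plus one
mTEC-like reference:

* **Housekeeping genes** (10% of the panel) planted above FPKM 5 in every
  sample; they also host the planted restricted junctions, since a TRA
  junction needs a host gene expressed in other tissues.
* **TRA genes** (40 per tissue by default) above FPKM 5 at home, below
  0.3 elsewhere; the first $\lceil 0.6 \times 40 \rceil = 24$ of each
  tissue's block are planted as expressed in the reference, so mirror
  coverage is exactly 0.6 per tissue.
* **Background genes** moderately expressed everywhere (FPKM 0.6-3), so
  they can never satisfy the restriction test.
* **Restricted junctions** (20 per tissue): an alternative acceptor in
  the first intron of a housekeeping host, supported by 10-50 reads at
  home and absent elsewhere; 40% are planted into the reference, making
  junction coverage exactly 0.40.
* **Editing sites** (500): 30% receive a nonzero Beta(1.5, 4) true level;
  coverage is negative binomial (mean 60, size 3) and edited reads
  binomial at the true level.
* **Hyper reads**: 100 planted reads satisfy the classifier; 900
  background reads are constructed to violate it (too few mismatches, an
  A>G fraction of exactly 0.75, or non-editing mismatch types), so exact
  recovery is well-defined.

Counts are drawn negative-binomially (dispersion 0.15) around target
FPKM levels and then *clamped* to the planted threshold relations, so the
relations hold deterministically rather than in expectation -- recovery
tests need exact ground truth, and a clamp (unlike a rescale) achieves it
in one pass because the aligned-read total is fixed at `library_size`
(5 million by default; gene counts sum to less, as reads also align
outside any gene panel). Every planted relation is re-verified after
generation. The default sizes (5 tissues, 5,000 genes, 500 sites) keep a
full generate-and-recover cycle in a few seconds on one CPU while leaving
hundreds of planted objects per detector.

What the generator does **not** emulate: replicate samples (one sample
per tissue, as in typical promiscuous-expression panels; replicates are a
config extension), sequencing error, batch effects, length biases within
a gene, or the long low-expression tail that immature mTEC populations
show in real data -- the dispersion and level distributions are exposed in
the configuration precisely because real noise models vary. Passing the
recovery tests therefore demonstrates correctness of the detectors under
their stated definitions, not robustness to every artifact of real
RNA-seq.

## Numerical choices and degenerate inputs

* Thresholds follow the printed inequalities: strict for FPKM rules,
  inclusive for "at least" rules (0.01 reads/nt, 10-read junction
  support, classifier thresholds).
* Quartile binning ranks ascending, keeps ties in stable input order and
  assigns remainder genes to the lower quartiles first, so bin sizes
  differ by at most one.
* Undefined quantities (empty TRA set, zero-coverage site, zero
  denominator in leave-one-out) are reported as `NA`, never as 0.
* Median-of-ratios factors require a gene positive in all samples and
  suggest a pseudocount otherwise.
* All randomness flows through per-call seeds with a save/restore of the
  session RNG state, so identical configurations are byte-identical on
  disk and library code never perturbs a user's stream.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
ds <- generate_synthetic_dataset(cfg)
sets <- detect_tra_genes(ds$panel, tra_call_config(excluded_samples = "mTEC_like"))
mirror_coverage(sets, ds$panel, "mTEC_like")
#> tissue01 tissue02 tissue03 tissue04 tissue05
#>      0.6      0.6      0.6      0.6      0.6
```

The recovered coverage equals the planted mirror fraction exactly -- the
property the whole synthetic design exists to make testable.
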