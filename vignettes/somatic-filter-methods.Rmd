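---
title: "Somatic filtering and cohort statistics for NASH-HCC genomics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic filtering and cohort statistics for NASH-HCC genomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nashhcc)
```

## Scope and model

`nashhcc` re-implements, as tested and reusable code, the computational
arm of a dietary-cholesterol NASH-HCC study design: paired tumor/normal
exome data are screened for somatic single-nucleotide variants through a
cascade of statistical filters; candidate somatic indels are screened by
rule-based summary criteria; PASS variants are annotated, tabulated into a
gene-by-sample recurrence matrix, and summarized into cohort statistics
(per-sample mutation burden, recurrence frequencies, cross-cohort
chi-square contrasts); expression matrices are tested for differential
expression; and gene lists are tested for pathway over-representation.
Because the original sequencing data are not an input here, a first-class
synthetic-data module generates every input with known ground truth, so the
pipeline's sensitivity and specificity are measurable rather than assumed.

## The SNV filter cascade

At a candidate site the tumor and normal pileups are reduced to
high-quality (HQ) reads — base quality strictly above Q10 — and the
candidate alternate allele is the plurality non-reference HQ base in the
tumor (ties break to the alphabetically smallest base, so calls are
deterministic). Seven conditions must all hold:

1. **Allele-fraction gate.** Tumor alt fraction > 15% (strict) and normal
   alt fraction <= 2% (inclusive), both over HQ reads.
2. **Tumor-vs-normal Fisher test** on (alt, ref) x (tumor, normal) HQ
   counts, one-sided toward tumor enrichment by default, p < 0.05.
3. **Coverage gate.** HQ depth >= 10X in both samples.
4. **Sequencing-error screen.** With k alt reads in n HQ tumor reads, the
   lower-tail exact binomial p = P(X <= k) under X ~ Binomial(n, f = 0.1)
   must exceed 0.01. A genuine variant has many alt reads, so p is near 1;
   support so weak it is consistent with a 10% error process fails. The
   tail orientation is configurable because the pass rule "p > 0.01" does
   not by itself fix a direction; the lower-tail reading is the one under
   which real variants pass, and it is the package default.
5. **Base-quality screen.** Wilcoxon rank-sum of alt vs ref base qualities
   in the tumor, one-sided toward "alt lower"; p > 0.01 passes, so a pass
   means no significant evidence that alt support rides on poor bases.
6. **Repeat-alignment screen.** Fisher test of (alt, ref) x
   (repeat-aligned, uniquely aligned) HQ tumor reads, one-sided toward alt
   enrichment among repeat-aligned (multi-mapping) reads; p > 0.01 passes.
7. **Read-end screen.** Fisher test of (alt, ref) x (within 10 bp of
   either read end, interior); p > 0.01 passes.

Screens 5–7 are one-sided in the artifact direction on purpose: two-sided
versions would also fail sites whose alt reads are *better* than average,
which is not an artifact signal. All seven stages are always computed — a
failing site still gets a complete per-stage p-value profile in the VCF,
which is what makes the per-artifact-class diagnostics below possible.
Degenerate screens (for instance no reference reads left for the rank-sum
comparison) pass with p = 1: absence of evidence of an artifact.

Boundary semantics are literal throughout: "> 15%" excludes 15% exactly,
">= 10X" includes 10, "p > 0.01" excludes 0.01. The same literalism applies
to the indel criteria below.

## The indel filter

Indel candidates arrive as per-site summaries (candidate generation by an
upstream caller is out of scope; the synthetic module emits summaries of
the same shape). A candidate fails if any of: total coverage < 30X; mean
mapping quality of supporting reads < 30; mean mismatches per supporting
read >= 2; mean base quality of supporting reads < 20; median offset from
the nearer read end <= 10 bp; or the rarer strand carries < 20% of
supporting reads. "Forward- or reverse-aligned ... < 20%" is read as
min(forward fraction, reverse fraction) < 0.20 — the interpretation under
which a fully one-stranded candidate fails, which is the artifact the rule
exists to catch. Surviving candidates are checked against a known-sites
list by exact (chrom, pos, ref, alt) match, standing in for a dbSNP-style
germline exclusion.

## Statistical conventions

All tests live in one module with fixed orientations. Exact tests (Fisher,
binomial, hypergeometric) use the standard conditional/tail definitions;
the two-sided Fisher p sums the probabilities of tables no more probable
than the observed one. The rank-sum test is exact (no ties, combined
n <= 12) or a mid-rank normal approximation with tie and continuity
corrections. Unpaired comparisons default to Welch's t: the burden contrast
the package targets has unequal group sizes (5 vs 3) and visibly unequal
spreads (84 vs 13), exactly the situation pooled variance mishandles; the
pooled test remains available. The summary-statistic t entry point computes
identically to the raw-data path, which is what lets published
"mean +/- SD, n" tables serve as inputs. Group dispersions written
"mean +/- x" are treated as SD (the source convention for such tables);
the burden contrast stays significant under the SE reading too, and the
tests assert only the significance bound. When both groups have zero
variance and equal means, p = 1 by convention; zero variance with unequal
means is refused as degenerate rather than silently producing p = 0.

One adjustment-related caveat is worth recording: Benjamini–Hochberg
step-up adjustment is *not* idempotent as a map on p-value vectors —
BH(0.2, 0.9) = (0.4, 0.9) while BH(0.4, 0.9) = (0.8, 0.9). An adjusted
vector is a fixed point only when fully tied to its top value. Adjusted
values are therefore computed once from raw p-values, never re-adjusted;
the test suite documents the non-idempotence explicitly.

## Mutation landscape

Consequence annotation works on toy genomes whose gene models are CDS-only
(one or two CDS blocks, in-frame, ATG start, stop end, no internal stop by
construction): a coding SNV's reference and mutated codons are translated
on the coding strand (reverse-complemented for minus-strand genes) and
classified as synonymous, missense, stopgain or stoploss; loci outside all
CDS intervals are noncoding. Splice, UTR and promoter classes are not
modeled. The classifier is tested base-by-base against an oracle that
mutates and translates the entire CDS.

Recurrence counts non-synonymous records only (a flag admits all), as a
binary gene x sample indicator; a gene is recurrent when mutated in >= 2
samples of a group. Mutation burden is the number of distinct
non-synonymously mutated genes per sample (a per-call counter would double
count multi-hit genes; the per-gene reading is the one consistent with the
recurrence matrix). Frequencies are reported as count/n with percentages
rounded half-up to one decimal, so 5/37 prints as 13.5%. Ortholog mapping
is many-to-one with deduplication, preserving query order.

## Differential expression

Input matrices are on the log2 scale (two-color log2 ratios, or
log2-transformed abundances); a fold change is an additive shift and
">= 2-fold" means |delta log2| >= 1 (inclusive). Two-group calling uses a
per-gene Welch t-test with the fold gate at raw p < 0.05 — no multiplicity
adjustment, matching the procedure it reproduces, with the fold gate
supplying the conservatism (the null false-positive rate stays well under
alpha because a null gene must also clear a 1-log2-unit observed shift).
The paired arm uses per-pair differences, a paired t-test, and BH
adjustment across genes, reporting genes with raw p < 0.05 and adjusted
p <= 0.15; with the FDR bound at 1 this reduces exactly to the raw-p rule.
Display normalization subtracts each gene's cross-sample mean. Sample
clustering is agglomerative with distance 1 - Pearson correlation and
average linkage (the usual choice for expression heat maps; configurable
in principle but deliberately not parameterized here), with samples sorted
by id beforehand so the tree is invariant to input column order.

## Pathway enrichment

Over-representation uses the hypergeometric upper tail P(X >= k) for the
overlap k between a query and each set, after intersecting both with the
gene universe (defaulting to all genes in the gene-model file). BH spans
every set in the collection, including zero-overlap sets — excluding them
would make the family data-dependent. Significance additionally requires a
minimum overlap: 4 genes for expression queries, 3 for mutation queries,
applied as a conjunction with adjusted p < 0.05 (the gate is a post-hoc
filter, not a pre-filter of the BH family). The per-sample mutation rule
runs the mutation-gated test per sample and reports pathways significant
in >= 3 samples.

## The synthetic-data generators

The generators emulate the statistical structure of the target study, not
its scale. Defaults are the study conditions: 5 NASH and 3 steatosis
tumor/normal pairs; Poisson depth with mean 80 per sample per site
(re-drawn if zero at a truth locus, so truth pileups are never empty);
somatic VAF 0.3 — high-purity tumors; read length 100 with uniform read-end
offsets for ordinary reads; germline heterozygotes at VAF 0.5 in both
samples; per-base background error 0.001; 20 planted somatic SNVs per NASH
sample against 3 per steatosis sample, giving a burden contrast of the same
character (if not the same magnitude) as the 7.8-fold one the cohort
statistics reproduce from published summaries. Somatic events are planted
inside CDS, as befits exome data. The three artifact classes are built to
be invisible to every stage except their own: artifact sites carry the same
VAF as true somatics and clean normals, but their alt reads are all within
10 bp of a read end, all repeat-aligned, or drawn from a low base-quality
distribution (Q 11–19 — above the HQ cut, so the allele-fraction gate still
sees them and only the rank-sum screen can reject them). Background loci
(500 per sample by default; smaller in the test suite) carry only
sequencing error and make specificity measurable. The expression module
plants 50 genes at 2.5-fold (log2 effect 1.32) among 1000 with noise SD
0.25 on the log2 scale; the pathway module plants 3 of 15 twenty-gene sets
loaded with ~70% signal genes. What the generators do *not* model: mapping
and alignment itself, indel realignment, GC and capture bias, sequencing
error profiles that vary along the read, subclonal VAF mixtures, and
correlated expression modules. Passing recovery tests therefore
demonstrates that the filters reject what they claim to reject under their
own error model — not performance on real reads.

## Problem sizes and determinism

Every generator consumes a seed through isolated streams, so identical
seed and configuration reproduce every output byte for byte; the
acceptance script threads a single `--seed` through all of them. The test
suite and acceptance script run at deliberate desk scale: 100 planted
somatic events, 100 germline, 30 per artifact class for cascade recovery;
all 2x2 tables with totals <= 20 for the enumeration sweeps; 10,000
replicates for type-I-error calibration; 1,000 random null queries for the
enrichment family-wise error rate; 50 replicates for the expression
Monte-Carlo calibration. Headline counts of the original study that depend
on its deposited exome-scale data (for example its 634/248 DE gene counts
or its 82 recurrent genes) are procedure-level here: the procedures are
implemented and property-tested, but those specific numbers are not
reproducible from synthetic data and are not claimed.

## Known limitations

Only the plurality alternate allele is considered per site (no
multi-allelic calls). The toy gene models have no UTRs or splice sites, so
"noncoding" conflates intergenic and intronic. The indel module filters
pre-computed candidate summaries and does not itself detect indels. The
enrichment module tests over-representation only — no ranked (GSEA-style)
or topology-aware analysis. The pipeline's two expression arms share the
generator but the paired arm is synthetic-only: no real FPKM input ships
with the package.
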