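# nashhcc

Somatic mutation and expression analysis for studies of
steatohepatitis-driven liver cancer.

## The problem

Dietary-cholesterol mouse models of NASH-driven hepatocellular carcinoma
(NASH-HCC) are analyzed by comparing paired tumor/normal exomes and
expression profiles between a NASH group and a simple-steatosis group. The
computational core of such a study is (i) deciding which tumor-only variants
are real somatic events rather than germline leakage or sequencing/alignment
artifacts, and (ii) turning the surviving calls into cohort statistics:
which genes recur, how heavy the mutation burden is per group, and which
pathways are struck by mutations or by expression changes. `nashhcc`
implements that pipeline as a tested R package for analysts who want the
filtering and statistics to be reproducible and measurable on data with
known ground truth.

## Methods at the core

**Somatic SNV filter cascade.** At each paired site, over high-quality
reads (base quality Q > 10), a call must satisfy all of:

1. tumor alt fraction > 15% and normal alt fraction ≤ 2%;
2. tumor-vs-normal Fisher exact test on (alt, ref) counts, *P* < 0.05;
3. HQ coverage ≥ 10× in both samples;
4. exact binomial screen against sequencing error: *P*(X ≤ k) > 0.01 under
   X ~ Binomial(n = HQ depth, f = 0.1);
5. Wilcoxon rank-sum of alt vs ref base qualities (alt not lower), *P* > 0.01;
6. Fisher screen for alt enrichment among repeat-aligned reads, *P* > 0.01;
7. Fisher screen for alt enrichment within 10 bp of read ends, *P* > 0.01.

**Somatic indel filter.** Candidates fail on: coverage < 30×, supporting-read
mapping quality < 30, mismatches per supporting read ≥ 2, supporting base
quality < 20, median end offset ≤ 10 bp, rarer-strand support < 20%, or
presence in a known-sites list (dbSNP-style exclusion).

**Cohort statistics.** Gene × sample recurrence matrices over
non-synonymous calls (recurrent = mutated in ≥ 2 samples); per-sample
mutated-gene burden compared by Welch's *t* (raw data or published
mean ± SD summaries); frequencies as k/n with half-up one-decimal
percentages; chi-square 2×2 contrasts between cohorts.

**Expression and enrichment.** Per-gene Welch *t* with a ≥ 2-fold gate on
log2 matrices; paired *t* with Benjamini–Hochberg FDR (report *P* < 0.05,
FDR ≤ 0.15); 1 − Pearson / average-linkage clustering; hypergeometric
pathway over-representation with BH across all sets and minimum-overlap
gates (≥ 4 expression genes, ≥ 3 mutated genes, ≥ 3 samples for the
per-sample mutation rule).

A synthetic-data module generates genomes, gene models, paired pileups,
indel candidates, expression matrices and gene-set collections with planted
truth (somatic/germline/artifact sites, fold changes, enriched pathways),
so every stage's sensitivity and specificity are measured, not assumed.

## Worked example

```r
library(nashhcc)

# simulate 5 NASH tumor/normal pairs at depth 80, VAF 0.3, with planted truth
cfg <- sim_config(seed = 1, n_samples_per_group = c(NASH = 5L),
                  n_somatic_per_sample = 20L, n_germline = 20L,
                  depth_mean = 80, somatic_vaf = 0.3, n_background = 100L)
g   <- make_genome(cfg)
sim <- simulate_paired_pileups(g, cfg)
calls <- call_snvs(sim$pileup, sim$manifest)
#> call_snvs: 326 candidate sites, 98 PASS; failures: af_gate=137,
#>   tn_fisher=130, hq_coverage=0, seq_error=36, baseq_rank=34,
#>   repeat_align=31, end_bias=30
```

Of 326 sites where any alternate allele was observed, 98 pass all seven
stages (98/100 planted somatic events; every germline and artifact site is
rejected, and the per-stage tally shows which screen caught what).

```r
# burden contrast from published per-group summaries (mean, SD, n)
b <- burden_compare(summary1 = c(335, 84, 5), summary2 = c(43, 13, 3))
b$fold
#> [1] 7.8
b$test
#> Welch two-sample t-test (summary statistics)
#> statistic = 7.62235, p = 0.00116937, alternative = two_sided
#> df = 4.312
```

The NASH group carries a 7.8-fold heavier non-synonymous burden than the
steatosis group, significant by Welch's *t* (p ≈ 0.0012).

## The analysis workflow

Numbered drivers under `analysis/` run the full study shape over the
package and write their tables under `results/`:

    01_simulate.R           synthetic cohort with planted truth
    02_call_variants.R      SNV cascade + indel filter, VCF output
    03_mutation_landscape.R annotation, recurrence, burden, frequencies
    04_expression_de.R      two-group DE, clustering, paired arm
    05_enrichment.R         expression- and mutation-query enrichment
    06_cohort_statistics.R  published-summary contrasts (fold, Welch, chi-square)

Run them in order with `Rscript analysis/01_simulate.R` etc.
`run_pipeline()` executes the same stages in one call and writes a
truth-recovery report.

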