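#!/usr/bin/env Rscript
# Stage 3: mutation landscape. Annotates PASS SNVs with gene and coding
# consequence on the toy genome, builds the gene x sample recurrence
# matrix, and computes the cohort statistics: per-sample non-synonymous
# burden with the NASH-vs-steatosis Welch contrast and fold ratio, the most
# recurrently mutated gene's per-group frequencies, and a chi-square
# comparison of those frequencies.

suppressPackageStartupMessages(library(nashhcc))

sim_dir <- "results/simulation"
var_dir <- "results/variants"
out <- "results/landscape"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- list(seqs = read_genome_fasta(file.path(sim_dir, "genome.fa")),
               models = read_gene_models(file.path(sim_dir, "gene_models.tsv")))
manifest <- read.delim(file.path(sim_dir, "pairs.tsv"))
recs <- read.delim(file.path(var_dir, "snv_records.tsv"))
pass <- recs[recs$filter == "PASS", ]

ann <- annotate_variants(pass, genome)
write.table(ann, file.path(out, "mutation_records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Consequences among PASS somatic SNVs:\n")
print(table(ann$consequence))

groups <- setNames(manifest$group, manifest$pair_id)
rec <- build_recurrence(ann, samples = manifest$pair_id, groups = groups)
write.table(data.frame(gene = rownames(rec$matrix), rec$matrix,
                       check.names = FALSE),
            file.path(out, "recurrence_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

nash <- names(groups)[groups == "NASH"]
rec_genes <- recurrent_genes(rec, 2L, group = "NASH")
cat(sprintf("\n%d genes recurrently mutated (>= 2 NASH samples): %s\n",
            length(rec_genes), paste(rec_genes, collapse = ", ")))

nonsyn <- ann[ann$consequence %in% c("missense", "stopgain", "stoploss"), ]
burden_counts <- vapply(manifest$pair_id, function(s) {
  length(unique(nonsyn$gene[nonsyn$sample == s]))
}, integer(1))
b <- burden_compare(burden_counts, groups)
cat(sprintf(
  "\nNon-synonymous mutated-gene burden: %s = %.1f +/- %.1f vs %s = %.1f +/- %.1f\n=> %.1f-fold difference, Welch t = %.2f, p = %.3g\n",
  names(b$means)[1], b$means[1], b$sds[1],
  names(b$means)[2], b$means[2], b$sds[2],
  b$fold, b$test$statistic, b$test$p_value))

if (length(rec_genes)) {
  rs <- rowSums(rec$matrix[, nash, drop = FALSE])
  top <- names(rs)[which.max(rs)]
  f1 <- mutation_frequency(top, rec, group = "NASH")
  f2 <- mutation_frequency(top, rec, group = "steatosis")
  chi <- frequency_compare(f1$count, f1$n, f2$count, f2$n)
  cat(sprintf(
    "\nMost recurrently mutated gene %s: %d/%d = %.1f%% of NASH vs %d/%d = %.1f%% of steatosis samples\n(chi-square = %.2f, p = %.3g)\n",
    top, f1$count, f1$n, f1$percent, f2$count, f2$n, f2$percent,
    chi$statistic, chi$p_value))
}

# recall of planted recurrence among PASS-called genes
som <- read.delim(file.path(sim_dir, "truth_somatic.tsv"))
nonsyn_nash <- nonsyn[nonsyn$sample %in% nash, ]
per_gene <- table(unique(nonsyn_nash[, c("gene", "sample")])$gene)
expected <- names(per_gene)[per_gene >= 2]
cat(sprintf("\nRecurrence recall (PASS-called genes in >= 2 NASH samples): %.2f\n",
            mean(expected %in% rec_genes)))

summary <- list(
  recurrent_genes = rec_genes, burden_fold = b$fold,
  burden_welch_p = b$test$p_value,
  burden_means = as.list(b$means)
)
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
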