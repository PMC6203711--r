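#!/usr/bin/env Rscript
# Stage 5: pathway enrichment. Hypergeometric over-representation of the DE
# gene list (>= 4 genes and BH-adjusted p < 0.05) and the per-sample
# mutation aggregation rule (>= 3 genes per sample, significant in >= 3
# samples), scored against the planted pathways.

suppressPackageStartupMessages(library(nashhcc))

sim_dir <- "results/simulation"
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

collection <- read_gmt(file.path(sim_dir, "pathways.gmt"))
planted <- readLines(file.path(sim_dir, "truth_pathways.txt"))
mat <- read_matrix(file.path(sim_dir, "expression.tsv"))
universe <- rownames(mat)
query <- c(readLines("results/expression/up_genes.txt"),
           readLines("results/expression/down_genes.txt"))

er <- enrich(query, collection, universe, min_genes = 4L)
write.table(er, file.path(out, "expression_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- er$set[er$significant]
cat(sprintf(
  "Expression query (%d genes) against %d pathways: %d significant (%s);\nplanted pathways (%s) recalled %.2f.\n",
  length(unique(query)), length(collection), length(sig),
  paste(sig, collapse = ", "), paste(planted, collapse = ", "),
  mean(planted %in% sig)))

# mutation arm: per-sample mutated genes of the NASH group against sets
# loaded with the most recurrently hit genes
config <- sim_config(seed = 20180, n_background = 200L)
models <- read_gene_models(file.path(sim_dir, "gene_models.tsv"))
ann <- read.delim("results/landscape/mutation_records.tsv")
manifest <- read.delim(file.path(sim_dir, "pairs.tsv"))
nash <- manifest$pair_id[manifest$group == "NASH"]
nonsyn <- ann[ann$consequence %in% c("missense", "stopgain", "stoploss"), ]
sample_lists <- lapply(setNames(nash, nash), function(s) {
  unique(nonsyn$gene[nonsyn$sample == s])
})
gene_hits <- sort(table(unlist(sample_lists)), decreasing = TRUE)
mut_special <- names(gene_hits)[seq_len(min(
  ceiling(0.7 * config$pathways$set_size), length(gene_hits)))]
gs_mut <- make_gene_sets(config, models$gene_id, special_genes = mut_special)
write_gmt(gs_mut$sets, file.path(out, "mutation_pathways.gmt"))

agg <- per_sample_mutation_enrichment(sample_lists, gs_mut$sets,
                                      models$gene_id, min_genes = 3L,
                                      min_samples = 3L)
write.table(agg$report, file.path(out, "mutation_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
hit <- agg$report$set[agg$report$reported]
cat(sprintf(
  "Mutation queries (%d NASH samples, >= 3 genes each, >= 3 samples): %d pathways reported (%s);\nplanted (%s) recalled %.2f.\n",
  length(sample_lists), length(hit), paste(hit, collapse = ", "),
  paste(gs_mut$planted, collapse = ", "),
  mean(gs_mut$planted %in% hit)))
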