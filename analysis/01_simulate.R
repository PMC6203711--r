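#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic inputs with known truth.
#
# Design mirrors the cohort the pipeline targets: 5 NASH tumor/normal pairs
# and 3 steatosis pairs, exome-style depth 80, somatic VAF 0.3, with a
# heavier planted somatic burden in the NASH group, plus planted germline
# variants, three artifact classes, background error-only loci, a
# 1000-gene expression universe with 50 genes at 2.5-fold, and a 15-set
# pathway collection with 3 enriched sets.

suppressPackageStartupMessages(library(nashhcc))

seed <- 20180
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

config <- sim_config(seed = seed, n_background = 200L)
genome <- make_genome(config)
write_genome_fasta(genome, file.path(out, "genome.fa"))
write_gene_models(genome$models, file.path(out, "gene_models.tsv"))

sim <- simulate_paired_pileups(genome, config)
write_pileups(sim$pileup, file.path(out, "pileups.tsv"))
write.table(sim$manifest, file.path(out, "pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (nm in names(sim$truth)) {
  write.table(sim$truth[[nm]], file.path(out, paste0("truth_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

ind <- simulate_indel_candidates(config)
write.table(ind$candidates, file.path(out, "indel_candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ind$known$table, file.path(out, "known_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(id = names(ind$truth), expected = unname(ind$truth)),
            file.path(out, "truth_indels.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

ex <- simulate_expression(config)
write_matrix(ex$matrix, file.path(out, "expression.tsv"))
write.table(data.frame(sample = names(ex$groups), group = unname(ex$groups)),
            file.path(out, "expression_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ex$truth, file.path(out, "truth_de_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gs <- make_gene_sets(config, rownames(ex$matrix), special_genes = ex$truth$gene)
write_gmt(gs$sets, file.path(out, "pathways.gmt"))
writeLines(gs$planted, file.path(out, "truth_pathways.txt"))

cat(sprintf(
  "Simulated %d tumor/normal pairs (%s), %d read observations, %d planted somatic\nSNVs, %d germline variants, %d artifact sites, %d indel candidates;\nexpression: %d genes x %d samples with %d planted DE genes; %d pathways (%d enriched).\nOutputs under %s/.\n",
  nrow(sim$manifest),
  paste(sprintf("%s=%d", names(config$n_samples_per_group),
                config$n_samples_per_group), collapse = ", "),
  nrow(sim$pileup), nrow(sim$truth$somatic), nrow(sim$truth$germline),
  nrow(sim$truth$artifacts), nrow(ind$candidates),
  nrow(ex$matrix), ncol(ex$matrix), nrow(ex$truth),
  length(gs$sets), length(gs$planted), out))
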