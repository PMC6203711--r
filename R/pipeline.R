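# End-to-end run on synthetic data: simulate -> call SNVs -> filter indels
# -> annotate -> landscape -> differential expression -> enrichment, with a
# manifest of inputs/outputs and a report juxtaposing recovered against
# planted truth. Deterministic under a fixed config seed.

.ARTIFACT_STAGE <- c(end_biased = "end_bias", repeat_biased = "repeat_align",
                     low_quality_alt = "baseq_rank")

#' Run the full synthetic-data pipeline
#'
#' Executes every stage on data generated from `config`, writes all
#' intermediate files under `out_dir`, and returns (and writes) a manifest
#' and a truth-recovery report: SNV sensitivity, germline leakage, artifact
#' rejection per class with the matching filter flag, background
#' false-positive rate, recurrent-gene recall, burden fold ratio with Welch
#' t-test, a chi-square frequency comparison for the most recurrently
#' mutated gene, DE recall and false-positive rate, and pathway-enrichment
#' recall for expression and mutation queries.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage chatter.
#' @return List: `manifest`, `report`, plus the in-memory stage outputs
#'   (`calls`, `records`, `recurrence`, `de`, `enrichment`, ...).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("nashhcc_"),
                         quiet = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    models = file.path(out_dir, "gene_models.tsv"),
    pileup = file.path(out_dir, "pileups.tsv"),
    pairs = file.path(out_dir, "pairs.tsv"),
    snv_vcf = file.path(out_dir, "somatic_snvs.vcf"),
    indel_candidates = file.path(out_dir, "indel_candidates.tsv"),
    known_sites = file.path(out_dir, "known_sites.tsv"),
    indel_vcf = file.path(out_dir, "somatic_indels.vcf"),
    records = file.path(out_dir, "mutation_records.tsv"),
    recurrence = file.path(out_dir, "recurrence_matrix.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    de = file.path(out_dir, "de_genes.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    report = file.path(out_dir, "report.json"),
    manifest = file.path(out_dir, "manifest.json")
  )

  # -- simulate ------------------------------------------------------------
  genome <- make_genome(config)
  write_genome_fasta(genome, paths$fasta)
  write_gene_models(genome$models, paths$models)
  sim <- simulate_paired_pileups(genome, config)
  write_pileups(sim$pileup, paths$pileup)
  utils::write.table(sim$manifest, paths$pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- somatic SNV calling (through the on-disk formats) --------------------
  pileup <- read_pileups(paths$pileup, manifest = sim$manifest)
  calls <- call_snvs(pileup, sim$manifest, quiet = quiet)
  write_snv_vcf(calls, paths$snv_vcf)
  validate_vcf(paths$snv_vcf)

  # -- somatic indel filtering ----------------------------------------------
  ind <- simulate_indel_candidates(config)
  utils::write.table(ind$candidates, paths$indel_candidates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ind$known$table, paths$known_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  verdicts <- filter_indels(ind$candidates,
                            known = read_known_sites(paths$known_sites),
                            quiet = quiet)
  write_indel_vcf(verdicts, paths$indel_vcf)
  validate_vcf(paths$indel_vcf)

  # -- annotation and mutation landscape ------------------------------------
  pass_records <- snv_calls_to_records(calls)
  pass_records <- pass_records[pass_records$filter == "PASS", , drop = FALSE]
  records <- annotate_variants(pass_records, genome)
  utils::write.table(records, paths$records, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sample_groups <- stats::setNames(sim$manifest$group, sim$manifest$pair_id)
  rec <- build_recurrence(records, samples = sim$manifest$pair_id,
                          groups = sample_groups)
  utils::write.table(data.frame(gene = rownames(rec$matrix), rec$matrix,
                                check.names = FALSE),
                     paths$recurrence, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  group_labels <- names(config$n_samples_per_group)
  burden <- NULL; freq_test <- NULL; top_gene <- NULL
  nonsyn <- records[records$consequence %in% NONSYNONYMOUS, , drop = FALSE]
  burden_counts <- vapply(sim$manifest$pair_id, function(s) {
    length(unique(nonsyn$gene[nonsyn$sample == s]))
  }, integer(1))
  if (length(group_labels) == 2 && all(config$n_samples_per_group >= 2)) {
    burden <- burden_compare(burden_counts, sample_groups)
    g1 <- group_labels[1]; g2 <- group_labels[2]
    rs <- rowSums(rec$matrix[, sample_groups == g1, drop = FALSE])
    if (length(rs) && max(rs) > 0) {
      top_gene <- names(rs)[which.max(rs)]
      f1 <- mutation_frequency(top_gene, rec, group = g1)
      f2 <- mutation_frequency(top_gene, rec, group = g2)
      freq_test <- frequency_compare(f1$count, f1$n, f2$count, f2$n)
    }
  }

  # -- differential expression ----------------------------------------------
  ex <- simulate_expression(config)
  write_matrix(ex$matrix, paths$expression)
  de <- de_genes(read_matrix(paths$expression), ex$groups, case = ex$case_group)
  utils::write.table(de$table, paths$de, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- enrichment -----------------------------------------------------------
  universe <- rownames(ex$matrix)
  gs <- make_gene_sets(config, universe, special_genes = ex$truth$gene)
  write_gmt(gs$sets, paths$gmt)
  de_query <- union(de$up, de$down)
  er <- enrich(de_query, read_gmt(paths$gmt), universe, min_genes = 4L)
  utils::write.table(er, paths$enrichment, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # mutation-query arm: per-sample mutated genes of the first group against
  # sets loaded with that group's planted somatic genes
  g1_samples <- sim$manifest$pair_id[sim$manifest$group == group_labels[1]]
  som_g1 <- unique(sim$truth$somatic[sim$truth$somatic$sample %in% g1_samples,
                                     c("gene", "sample")])
  # load planted sets with the most recurrently hit genes so the same
  # pathway is struck in several samples (as a real driver pathway is)
  gene_hits <- sort(table(som_g1$gene), decreasing = TRUE)
  mut_special <- names(gene_hits)[seq_len(min(
    ceiling(0.7 * config$pathways$set_size), length(gene_hits)))]
  gene_universe <- genome$models$gene_id
  gs_mut <- make_gene_sets(config, gene_universe,
                           special_genes = mut_special)
  sample_lists <- lapply(stats::setNames(g1_samples, g1_samples), function(s) {
    unique(nonsyn$gene[nonsyn$sample == s])
  })
  mut_enr <- per_sample_mutation_enrichment(sample_lists, gs_mut$sets,
                                            gene_universe, min_genes = 3L,
                                            min_samples = 3L)

  # -- truth-recovery report ------------------------------------------------
  call_key <- function(df) paste(df$sample, df$chrom, df$pos, df$alt)
  pass_key <- call_key(pass_records)
  som <- sim$truth$somatic
  sensitivity <- mean(paste(som$sample, som$chrom, som$pos, som$alt) %in%
                        pass_key)
  germ <- sim$truth$germline
  germline_pass <- sum(paste(germ$sample, germ$chrom, germ$pos, germ$alt) %in%
                         pass_key)
  art <- sim$truth$artifacts
  all_records <- snv_calls_to_records(calls)
  rec_key <- paste(all_records$sample, all_records$chrom, all_records$pos)
  artifact_rejection <- vapply(names(.ARTIFACT_STAGE), function(cls) {
    sub <- art[art$class == cls, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    hit <- match(paste(sub$sample, sub$chrom, sub$pos), rec_key)
    flagged <- vapply(seq_len(nrow(sub)), function(i) {
      j <- hit[i]
      if (is.na(j)) return(FALSE)  # not even called: count as not flagged
      filt <- strsplit(all_records$filter[j], ";")[[1]]
      .ARTIFACT_STAGE[[cls]] %in% filt
    }, logical(1))
    mean(flagged)
  }, numeric(1))
  n_background_sites <- config$n_background * nrow(sim$manifest)
  truth_keys <- c(paste(som$sample, som$chrom, som$pos),
                  paste(germ$sample, germ$chrom, germ$pos),
                  paste(art$sample, art$chrom, art$pos))
  bg_pass <- sum(!(paste(pass_records$sample, pass_records$chrom,
                         pass_records$pos) %in% truth_keys))
  background_fpr <- bg_pass / n_background_sites

  # recurrence recall: planted genes that are PASS-called non-synonymously
  # in >= 2 samples of a group must all be reported recurrent
  rec_recall <- NA_real_
  g1 <- group_labels[1]
  called_rec <- recurrent_genes(rec, 2L, group = g1)
  nonsyn_g1 <- nonsyn[nonsyn$sample %in% g1_samples, , drop = FALSE]
  tabulated <- table(unique(nonsyn_g1[, c("gene", "sample")])$gene)
  expected_rec <- names(tabulated)[tabulated >= 2]
  if (length(expected_rec)) {
    rec_recall <- mean(expected_rec %in% called_rec)
  }

  de_found <- union(de$up, de$down)
  de_truth <- ex$truth$gene
  de_recall <- if (length(de_truth)) mean(de_truth %in% de_found) else NA_real_
  null_genes <- setdiff(rownames(ex$matrix), de_truth)
  de_fpr <- if (length(null_genes)) {
    mean(null_genes %in% de_found)
  } else NA_real_

  enr_recall <- if (length(gs$planted)) {
    mean(gs$planted %in% er$set[er$significant])
  } else NA_real_
  mut_enr_recall <- if (length(gs_mut$planted)) {
    mean(gs_mut$planted %in%
           mut_enr$report$set[mut_enr$report$reported])
  } else NA_real_

  report <- list(
    snv = list(
      sensitivity = sensitivity,
      germline_pass = germline_pass,
      artifact_rejection = as.list(artifact_rejection),
      background_fpr = background_fpr,
      stage_failures = as.list(attr(calls, "stage_failures"))
    ),
    indel = list(
      criterion_failures = as.list(attr(verdicts, "criterion_failures")),
      n_pass = sum(vapply(verdicts, `[[`, logical(1), "pass"))
    ),
    landscape = list(
      recurrent_genes = called_rec,
      recurrent_recall = rec_recall,
      burden = if (!is.null(burden)) {
        list(means = as.list(burden$means), fold = burden$fold,
             welch_p = burden$test$p_value)
      },
      top_gene = top_gene,
      top_gene_chisq_p = if (!is.null(freq_test)) freq_test$p_value
    ),
    expression = list(
      n_up = length(de$up), n_down = length(de$down),
      recall = de_recall, fpr = de_fpr
    ),
    enrichment = list(
      expression_recall = enr_recall,
      mutation_recall = mut_enr_recall
    )
  )

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    paths = lapply(paths, basename),
    counts = list(
      pairs = nrow(sim$manifest),
      pileup_rows = nrow(sim$pileup),
      candidate_sites = length(calls),
      pass_snvs = nrow(pass_records),
      indel_candidates = nrow(ind$candidates),
      pass_indels = sum(vapply(verdicts, `[[`, logical(1), "pass")),
      genes = nrow(genome$models),
      expression_genes = nrow(ex$matrix)
    )
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, report = report, paths = paths,
                 genome = genome, sim = sim, calls = calls,
                 indel_verdicts = verdicts, records = records,
                 recurrence = rec, burden = burden, expression = ex,
                 de = de, gene_sets = gs, enrichment = er,
                 mutation_enrichment = mut_enr))
}
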