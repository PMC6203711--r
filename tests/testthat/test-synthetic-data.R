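# Generators: determinism, construction invariants, statistical calibration.

test_that("make_genome is deterministic and models are well-formed", {
  cfg <- test_config(n_genes = 10L, n_chromosomes = 1L, chrom_length = 20000L)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(g1$models, g2$models)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  m <- g1$models
  expect_equal(nrow(m), 10L)
  # non-overlapping, CDS length divisible by 3, ATG start, no internal stop
  o <- order(m$chrom, m$start)
  m <- m[o, ]
  expect_true(all(diff(m$start) > 0))
  expect_true(all(m$end[-nrow(m)] < m$start[-1]))
  for (i in seq_len(nrow(m))) {
    cds <- extract_cds(g1, m[i, ])
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- translate_cds(cds)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("genome sizing error is raised when genes cannot fit", {
  cfg <- test_config(n_genes = 100L, n_chromosomes = 1L, chrom_length = 1000L)
  expect_error(make_genome(cfg), "sizing error")
})

test_that("pileup simulation conserves truth counts and is deterministic", {
  cfg <- test_config(n_samples_per_group = c(NASH = 5L),
                     n_somatic_per_sample = 20L, n_germline = 10L,
                     artifact_counts = c(end_biased = 3L, repeat_biased = 3L,
                                         low_quality_alt = 3L),
                     n_background = 30L)
  g <- make_genome(cfg)
  sim1 <- simulate_paired_pileups(g, cfg)
  sim2 <- simulate_paired_pileups(g, cfg)
  expect_identical(sim1$pileup, sim2$pileup)
  expect_identical(sim1$truth, sim2$truth)

  expect_equal(nrow(sim1$truth$somatic), 100L)
  expect_equal(nrow(sim1$truth$germline), 50L)
  expect_equal(nrow(sim1$truth$artifacts), 45L)

  # no locus in more than one truth category per sample
  keys <- c(paste(sim1$truth$somatic$sample, sim1$truth$somatic$chrom,
                  sim1$truth$somatic$pos),
            paste(sim1$truth$germline$sample, sim1$truth$germline$chrom,
                  sim1$truth$germline$pos),
            paste(sim1$truth$artifacts$sample, sim1$truth$artifacts$chrom,
                  sim1$truth$artifacts$pos))
  expect_equal(anyDuplicated(keys), 0L)

  # every truth locus exists in the emitted pileups, in both samples
  pk <- paste(sim1$pileup$sample, sim1$pileup$chrom, sim1$pileup$pos)
  for (i in seq_len(nrow(sim1$truth$somatic))) {
    s <- sim1$truth$somatic[i, ]
    expect_true(paste(paste0(s$sample, "_T"), s$chrom, s$pos) %in% pk)
    expect_true(paste(paste0(s$sample, "_N"), s$chrom, s$pos) %in% pk)
  }
})

test_that("planted somatic alt fractions match the configured VAF", {
  cfg <- test_config(n_samples_per_group = c(NASH = 5L),
                     n_somatic_per_sample = 30L, n_germline = 0L,
                     artifact_counts = c(end_biased = 0L, repeat_biased = 0L,
                                         low_quality_alt = 0L),
                     n_background = 0L, somatic_vaf = 0.3)
  g <- make_genome(cfg)
  sim <- simulate_paired_pileups(g, cfg)
  som <- sim$truth$somatic
  expect_gte(nrow(som), 100L)
  tum <- sim$pileup[endsWith(sim$pileup$sample, "_T"), ]
  key <- paste(sub("_T$", "", tum$sample), tum$chrom, tum$pos)
  som_key <- paste(som$sample, som$chrom, som$pos)
  at_truth <- tum[key %in% som_key, ]
  alt_map <- stats::setNames(som$alt, som_key)
  is_alt <- at_truth$base == alt_map[paste(sub("_T$", "", at_truth$sample),
                                           at_truth$chrom, at_truth$pos)]
  n_reads <- nrow(at_truth)
  se <- sqrt(0.3 * 0.7 / n_reads)
  expect_lt(abs(mean(is_alt) - 0.3), 3 * se)
})

test_that("germline loci show alt fractions above 2% in both samples", {
  cfg <- test_config(n_samples_per_group = c(NASH = 3L),
                     n_somatic_per_sample = 0L, n_germline = 40L,
                     artifact_counts = c(end_biased = 0L, repeat_biased = 0L,
                                         low_quality_alt = 0L),
                     n_background = 0L, depth_mean = 80)
  g <- make_genome(cfg)
  sim <- simulate_paired_pileups(g, cfg)
  germ <- sim$truth$germline
  frac_above <- vapply(seq_len(nrow(germ)), function(i) {
    gr <- germ[i, ]
    ok <- vapply(c("_T", "_N"), function(sfx) {
      rows <- sim$pileup[sim$pileup$sample == paste0(gr$sample, sfx) &
                           sim$pileup$chrom == gr$chrom &
                           sim$pileup$pos == gr$pos, ]
      mean(rows$base == gr$alt) > 0.02
    }, logical(1))
    all(ok)
  }, logical(1))
  expect_gte(mean(frac_above), 0.99)
})

test_that("artifact read features match their class", {
  cfg <- test_config(n_samples_per_group = c(NASH = 2L),
                     n_somatic_per_sample = 0L, n_germline = 0L,
                     artifact_counts = c(end_biased = 5L, repeat_biased = 5L,
                                         low_quality_alt = 5L),
                     n_background = 0L)
  g <- make_genome(cfg)
  sim <- simulate_paired_pileups(g, cfg)
  art <- sim$truth$artifacts
  tum <- sim$pileup[endsWith(sim$pileup$sample, "_T"), ]
  for (i in seq_len(nrow(art))) {
    a <- art[i, ]
    rows <- tum[tum$sample == paste0(a$sample, "_T") & tum$chrom == a$chrom &
                  tum$pos == a$pos, ]
    alt_rows <- rows[rows$base == a$alt, ]
    if (!nrow(alt_rows)) next
    if (a$class == "end_biased") {
      expect_true(all(pmin(alt_rows$dist_5prime, alt_rows$dist_3prime) < 10))
    } else if (a$class == "repeat_biased") {
      expect_true(all(alt_rows$repeat_flag == 1L))
    } else {
      expect_true(all(alt_rows$base_quality < 20))
    }
  }
})

test_that("expression simulation: null construction, determinism, MC mean", {
  cfg0 <- test_config(n_samples_per_group = c(A = 4L, B = 4L))
  cfg0$expression$log2_effect_size <- 0
  ex0 <- simulate_expression(cfg0)
  grp_diff <- rowMeans(ex0$matrix[, ex0$groups == "A"]) -
    rowMeans(ex0$matrix[, ex0$groups == "B"])
  expect_true(all(ex0$truth$log2fc == 0))

  cfg <- test_config(n_samples_per_group = c(A = 5L, B = 5L))
  ex1 <- simulate_expression(cfg)
  ex2 <- simulate_expression(cfg)
  expect_identical(ex1$matrix, ex2$matrix)

  # Monte-Carlo: mean planted up-gene difference over 50 sims within 3 SE
  diffs <- unlist(lapply(1:50, function(s) {
    cfg_s <- test_config(seed = 7000L + s,
                         n_samples_per_group = c(A = 5L, B = 5L))
    ex <- simulate_expression(cfg_s)
    up <- ex$truth$gene[ex$truth$direction == 1]
    rowMeans(ex$matrix[up, ex$groups == "A", drop = FALSE]) -
      rowMeans(ex$matrix[up, ex$groups == "B", drop = FALSE])
  }))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - log2(2.5)), 3 * se)

  cfg_bad <- test_config()
  cfg_bad$expression$noise_sd <- 0
  expect_error(simulate_expression(cfg_bad), "noise_sd")
})

test_that("gene-set collections satisfy construction invariants", {
  cfg <- test_config()
  cfg$pathways <- list(n_sets = 10L, set_size = 5L, planted_enriched = 2L)
  genes <- sprintf("E%04d", 1:200)
  special <- sample(genes, 30)
  gs <- make_gene_sets(cfg, genes, special)
  expect_length(gs$sets, 10L)
  expect_true(all(lengths(gs$sets) == 5L))
  expect_true(all(vapply(gs$sets, anyDuplicated, integer(1)) == 0L))
  expect_true(all(unlist(gs$sets) %in% genes))
  ov <- vapply(gs$sets, function(s) length(intersect(s, special)), integer(1))
  expect_true(min(ov[gs$planted]) >= max(ov[setdiff(names(gs$sets), gs$planted)]))
})
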