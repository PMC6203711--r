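# The seven-stage cascade on constructed pileups, with each stage's
# p-value verified against the enumeration oracles, plus batch behavior on
# simulated data.

make_reads <- function(sample, n_alt, n_ref, ref = "A", alt = "T",
                       alt_q = 30L, ref_q = 30L, alt_end = FALSE,
                       alt_repeat = FALSE, pos = 100L) {
  n <- n_alt + n_ref
  is_alt <- rep(c(TRUE, FALSE), c(n_alt, n_ref))
  d5 <- rep(50L, n)
  if (alt_end && n_alt > 0) d5[is_alt] <- 3L
  data.frame(
    sample = sample, chrom = "chr1", pos = pos, ref = ref,
    base = ifelse(is_alt, alt, ref),
    base_quality = ifelse(is_alt, alt_q, ref_q),
    mapping_quality = 60L,
    repeat_flag = as.integer(alt_repeat & is_alt),
    dist_5prime = d5, dist_3prime = 99L - d5, strand = "+",
    stringsAsFactors = FALSE
  )
}

make_site <- function(t_alt, t_ref, n_alt, n_ref, ...) {
  list(pair_id = "P1", chrom = "chr1", pos = 100L, ref = "A",
       tumor = make_reads("P1_T", t_alt, t_ref, ...),
       normal = make_reads("P1_N", n_alt, n_ref, ...))
}

test_that("select_alt_allele: plurality, none, deterministic tie-break", {
  tumor <- make_reads("t", 20, 30, alt = "G")
  expect_equal(select_alt_allele(tumor, "A"), "G")
  expect_true(is.na(select_alt_allele(make_reads("t", 0, 30), "A")))
  tie <- rbind(make_reads("t", 5, 10, alt = "T"),
               make_reads("t", 5, 0, alt = "C"))
  expect_equal(select_alt_allele(tie, "A"), "C")
  # low-quality alt reads do not nominate an allele
  lowq <- make_reads("t", 4, 30, alt_q = 5L)
  expect_true(is.na(select_alt_allele(lowq, "A")))
})

test_that("a clean somatic site passes all seven stages with oracle p-values", {
  site <- make_site(20, 30, 0, 50)
  call <- apply_cascade(site)
  expect_s3_class(call, "snv_call")
  expect_true(call$pass)
  expect_equal(call$filter_status, "PASS")
  expect_true(all(call$verdicts))
  expect_named(call$verdicts, c("af_gate", "tn_fisher", "hq_coverage",
                                "seq_error", "baseq_rank", "repeat_align",
                                "end_bias"))
  expect_equal(call$tests$tn_fisher$p_value,
               oracle_fisher(20, 0, 30, 50, "greater"), tolerance = 1e-9)
  expect_equal(call$tests$seq_error$p_value,
               oracle_binom_lower(20, 50, 0.1), tolerance = 1e-9)
  expect_equal(call$tests$repeat_align$p_value, 1)   # no repeat reads at all
  expect_equal(call$tests$end_bias$p_value, 1)       # all interior
})

test_that("high normal allele fraction fails the AF gate", {
  call <- apply_cascade(make_site(20, 30, 22, 28))
  expect_false(call$verdicts[["af_gate"]])
  expect_match(call$filter_status, "af_gate")
  # all stages still computed after the failure
  expect_false(is.null(call$tests$end_bias))
})

test_that("end-clustered alt reads fail only the end-bias screen", {
  site <- make_site(10, 40, 0, 50, alt_end = TRUE)
  call <- apply_cascade(site)
  expect_equal(call$tests$end_bias$p_value, 1 / choose(50, 10),
               tolerance = 1e-9)
  expect_equal(call$filter_status, "end_bias")
  expect_equal(sum(!call$verdicts), 1L)
})

test_that("repeat-aligned and low-quality alt reads fail their screens", {
  call_rep <- apply_cascade(make_site(15, 40, 0, 50, alt_repeat = TRUE))
  expect_false(call_rep$verdicts[["repeat_align"]])
  expect_equal(call_rep$tests$repeat_align$p_value,
               oracle_fisher(15, 0, 0, 40, "greater"), tolerance = 1e-9)

  call_bq <- apply_cascade(make_site(15, 40, 0, 50, alt_q = 15L, ref_q = 35L))
  expect_false(call_bq$verdicts[["baseq_rank"]])
  expect_true(call_bq$verdicts[["af_gate"]])  # Q15 still counts as HQ
})

test_that("no alt allele yields a no-call sentinel, not an error", {
  res <- apply_cascade(make_site(0, 40, 0, 40))
  expect_s3_class(res, "snv_nocall")
})

test_that("adding alt reads never flips stages 1-4 from pass to fail", {
  base_site <- make_site(12, 40, 0, 60)
  base_call <- apply_cascade(base_site)
  mono_stages <- c("af_gate", "tn_fisher", "hq_coverage", "seq_error")
  expect_true(all(base_call$verdicts[mono_stages]))
  for (extra in c(5L, 20L, 60L)) {
    bigger <- make_site(12L + extra, 40, 0, 60)
    call <- apply_cascade(bigger)
    expect_true(all(call$verdicts[mono_stages]),
                info = paste("extra alt reads:", extra))
  }
})

test_that("call_snvs: batch behavior, germline exclusion, determinism", {
  cfg <- test_config(n_samples_per_group = c(NASH = 3L),
                     n_somatic_per_sample = 10L, n_germline = 15L,
                     n_background = 30L, depth_mean = 60)
  g <- make_genome(cfg)
  sim <- simulate_paired_pileups(g, cfg)
  calls <- call_snvs(sim$pileup, sim$manifest, quiet = TRUE)
  recs <- snv_calls_to_records(calls)
  pass <- recs[recs$filter == "PASS", ]
  germ <- sim$truth$germline
  expect_equal(sum(paste(germ$sample, germ$chrom, germ$pos, germ$alt) %in%
                     paste(pass$sample, pass$chrom, pass$pos, pass$alt)), 0L)

  # re-running on the same pileup yields byte-identical VCFs
  v1 <- tempfile(fileext = ".vcf"); v2 <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls, v1)
  write_snv_vcf(call_snvs(sim$pileup, sim$manifest, quiet = TRUE), v2)
  expect_identical(readLines(v1), readLines(v2))
  expect_silent(validate_vcf(v1))

  # unsorted input is an ordering error
  shuffled <- sim$pileup[rev(seq_len(nrow(sim$pileup))), ]
  expect_error(call_snvs(shuffled, sim$manifest, quiet = TRUE),
               "ordering error")
})

test_that("empty stream yields an empty call set and header-only VCF", {
  empty <- make_mini_pileup()[0, ]
  calls <- call_snvs(empty, mini_manifest, quiet = TRUE)
  expect_length(calls, 0L)
  path <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls, path)
  expect_true(all(startsWith(readLines(path), "#")))
  expect_silent(validate_vcf(path))
})
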