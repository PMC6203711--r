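# The somatic SNV filter cascade. A candidate site passes only if all
# seven stages pass:
#
#   1 af_gate      tumor alt fraction > 15% AND normal alt fraction <= 2%
#                  (both over high-quality reads, Q > 10)
#   2 tn_fisher    tumor-vs-normal Fisher exact on (alt, ref) counts,
#                  p < 0.05
#   3 hq_coverage  high-quality depth >= 10X in both samples
#   4 seq_error    alt support not explicable as sequencing error:
#                  Binomial(n = HQ depth, f = 0.1) lower-tail p > 0.01
#   5 baseq_rank   alt base qualities not lower than ref (Wilcoxon rank
#                  sum, one-sided), p > 0.01
#   6 repeat_align alt reads not enriched among repeat-aligned reads
#                  (Fisher, one-sided), p > 0.01
#   7 end_bias     alt reads not enriched within 10 bp of read ends
#                  (Fisher, one-sided), p > 0.01
#
# Every stage is always computed (no short-circuit) so the emitted VCF
# carries a complete filter profile per site. Screens 5-7 are one-sided in
# the artifact direction, so "p > 0.01" reads "no significant artifact
# signal".

SNV_STAGES <- c("af_gate", "tn_fisher", "hq_coverage", "seq_error",
                "baseq_rank", "repeat_align", "end_bias")

SNV_FILTER_DESCRIPTIONS <- c(
  af_gate = "Tumor alt fraction <= 15% or normal alt fraction > 2% (HQ reads)",
  tn_fisher = "Tumor-vs-normal Fisher exact test p >= 0.05",
  hq_coverage = "High-quality (Q > 10) coverage < 10X in tumor or normal",
  seq_error = "Alt support consistent with sequencing error (binomial f = 0.1, p <= 0.01)",
  baseq_rank = "Alt base qualities lower than ref (Wilcoxon rank sum, p <= 0.01)",
  repeat_align = "Alt alleles enriched in repeat-aligned reads (Fisher, p <= 0.01)",
  end_bias = "Alt alleles enriched within 10 bp of read ends (Fisher, p <= 0.01)"
)

#' Parameters of the somatic SNV filter cascade
#'
#' Defaults are the published thresholds: tumor allele fraction > 0.15
#' (strict), normal <= 0.02 (inclusive), Fisher tumor-vs-normal alpha 0.05,
#' high-quality means base quality strictly above 10, coverage >= 10X,
#' sequencing-error rate f = 0.1, screen alpha 0.01 (binomial, Wilcoxon,
#' repeat and end-bias screens all pass when p > 0.01), and a 10 bp
#' read-end window.
#'
#' @param tumor_af_min Minimum tumor alt fraction (exclusive).
#' @param normal_af_max Maximum normal alt fraction (inclusive).
#' @param tn_fisher_alpha Alpha for the tumor-vs-normal Fisher test.
#' @param tn_fisher_alternative Alternative for that test; default
#'   `"greater"` (alt fraction higher in tumor).
#' @param hq_base_quality Base quality above which a read is high quality.
#' @param hq_coverage_min Minimum HQ depth per sample.
#' @param error_rate_f Null per-read error rate of the binomial screen.
#' @param screen_alpha Shared alpha of the four artifact screens (pass when
#'   p > `screen_alpha`).
#' @param end_window Read-end window in bases.
#' @return An `snv_params` list.
#' @export
snv_params <- function(tumor_af_min = 0.15, normal_af_max = 0.02,
                       tn_fisher_alpha = 0.05,
                       tn_fisher_alternative = "greater",
                       hq_base_quality = 10, hq_coverage_min = 10,
                       error_rate_f = 0.1, screen_alpha = 0.01,
                       end_window = 10) {
  probs <- c(tumor_af_min, normal_af_max, tn_fisher_alpha, error_rate_f,
             screen_alpha)
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("probabilities and fractions must lie in (0, 1)")
  }
  if (hq_coverage_min < 1) stop("hq_coverage_min must be >= 1")
  if (end_window < 0) stop("end_window must be >= 0")
  structure(list(
    tumor_af_min = tumor_af_min, normal_af_max = normal_af_max,
    tn_fisher_alpha = tn_fisher_alpha,
    tn_fisher_alternative = .check_alternative(tn_fisher_alternative),
    hq_base_quality = hq_base_quality, hq_coverage_min = hq_coverage_min,
    error_rate_f = error_rate_f, screen_alpha = screen_alpha,
    end_window = end_window
  ), class = "snv_params")
}

.hq <- function(reads, params) {
  reads[reads$base_quality > params$hq_base_quality, , drop = FALSE]
}

#' Select the candidate alternate allele at a tumor site
#'
#' The most frequent non-reference base among high-quality tumor reads;
#' ties break to the lexicographically smallest base. Returns `NA` when no
#' high-quality non-reference base is observed.
#'
#' @param tumor Read-observation data frame at one site.
#' @param ref Reference base.
#' @param params An [snv_params()].
#' @export
select_alt_allele <- function(tumor, ref, params = snv_params()) {
  hq <- .hq(tumor, params)
  nonref <- hq$base[hq$base != ref]
  if (!length(nonref)) return(NA_character_)
  counts <- table(nonref)
  top <- names(counts)[counts == max(counts)]
  sort(top)[1]
}

#' Apply the seven-stage somatic filter cascade at one paired site
#'
#' All stages are evaluated and recorded even after a failure. Counts and
#' allele fractions use high-quality reads only. When a screen's contingency
#' table is degenerate (e.g. no reference reads for the Wilcoxon), the
#' screen passes with p = 1: absence of evidence of an artifact.
#'
#' @param site A paired-site record: list with `pair_id`, `chrom`, `pos`,
#'   `ref`, `tumor`, `normal` (see [pair_sites()]).
#' @param params An [snv_params()].
#' @return An `snv_call`: locus, counts, per-stage `test_result`s and
#'   verdicts, `pass`, and `filter_status` ("PASS" or semicolon-joined
#'   failing stage names). Sites with no alt allele return an `snv_nocall`.
#' @export
apply_cascade <- function(site, params = snv_params()) {
  t_hq <- .hq(site$tumor, params)
  n_hq <- .hq(site$normal, params)
  alt <- select_alt_allele(site$tumor, site$ref, params)
  if (is.na(alt)) {
    return(structure(list(pair_id = site$pair_id, chrom = site$chrom,
                          pos = site$pos, ref = site$ref),
                     class = "snv_nocall"))
  }
  t_alt <- sum(t_hq$base == alt)
  t_dep <- nrow(t_hq)
  t_ref <- t_dep - t_alt
  n_alt <- sum(n_hq$base == alt)
  n_dep <- nrow(n_hq)
  n_ref <- n_dep - n_alt

  tests <- list()
  verdicts <- logical(0)

  t_af <- if (t_dep > 0) t_alt / t_dep else 0
  n_af <- if (n_dep > 0) n_alt / n_dep else 0
  verdicts["af_gate"] <- (t_af > params$tumor_af_min) &&
    (n_af <= params$normal_af_max)

  tests$tn_fisher <- fisher_exact(t_alt, n_alt, t_ref, n_ref,
                                  alternative = params$tn_fisher_alternative)
  verdicts["tn_fisher"] <- tests$tn_fisher$p_value < params$tn_fisher_alpha

  verdicts["hq_coverage"] <- (t_dep >= params$hq_coverage_min) &&
    (n_dep >= params$hq_coverage_min)

  tests$seq_error <- binom_cdf_test(t_alt, t_dep, params$error_rate_f)
  verdicts["seq_error"] <- tests$seq_error$p_value > params$screen_alpha

  alt_q <- t_hq$base_quality[t_hq$base == alt]
  ref_q <- t_hq$base_quality[t_hq$base == site$ref]
  if (length(alt_q) && length(ref_q)) {
    tests$baseq_rank <- wilcoxon_rank_sum(alt_q, ref_q, alternative = "less")
    verdicts["baseq_rank"] <- tests$baseq_rank$p_value > params$screen_alpha
  } else {
    tests$baseq_rank <- NULL
    verdicts["baseq_rank"] <- TRUE
  }

  is_alt <- t_hq$base == alt
  is_ref <- t_hq$base == site$ref
  rep_read <- t_hq$repeat_flag == 1L
  tests$repeat_align <- fisher_exact(
    sum(is_alt & rep_read), sum(is_ref & rep_read),
    sum(is_alt & !rep_read), sum(is_ref & !rep_read),
    alternative = "greater"
  )
  verdicts["repeat_align"] <- tests$repeat_align$p_value > params$screen_alpha

  near_end <- pmin(t_hq$dist_5prime, t_hq$dist_3prime) < params$end_window
  tests$end_bias <- fisher_exact(
    sum(is_alt & near_end), sum(is_ref & near_end),
    sum(is_alt & !near_end), sum(is_ref & !near_end),
    alternative = "greater"
  )
  verdicts["end_bias"] <- tests$end_bias$p_value > params$screen_alpha

  verdicts <- verdicts[SNV_STAGES]
  failing <- names(verdicts)[!verdicts]
  structure(list(
    pair_id = site$pair_id, chrom = site$chrom, pos = site$pos,
    ref = site$ref, alt = alt,
    tumor_alt = t_alt, tumor_ref = t_ref, tumor_hq_depth = t_dep,
    normal_alt = n_alt, normal_ref = n_ref, normal_hq_depth = n_dep,
    tests = tests, verdicts = verdicts,
    pass = all(verdicts),
    filter_status = if (all(verdicts)) "PASS" else paste(failing, collapse = ";")
  ), class = "snv_call")
}

#' Run the cascade over a paired pileup and summarize
#'
#' @param pileup Read-observation data frame (must be position-sorted
#'   within each sample).
#' @param manifest Pair manifest (pair_id, tumor, normal).
#' @param params An [snv_params()].
#' @param quiet Suppress the per-stage failure tally message.
#' @return List of `snv_call`s (no-call sites dropped), with attribute
#'   `stage_failures` (named counts of sites failing each stage).
#' @export
call_snvs <- function(pileup, manifest, params = snv_params(), quiet = FALSE) {
  for (s in unique(pileup$sample)) {
    sub <- pileup[pileup$sample == s, ]
    o <- order(sub$chrom, sub$pos)
    if (is.unsorted(o)) {
      stop("ordering error: pileup for sample ", s,
           " is not sorted by (chrom, pos)")
    }
  }
  sites <- pair_sites(pileup, manifest)
  calls <- lapply(sites, apply_cascade, params = params)
  calls <- calls[vapply(calls, inherits, logical(1), "snv_call")]
  tally <- stats::setNames(integer(length(SNV_STAGES)), SNV_STAGES)
  for (cl in calls) {
    f <- names(cl$verdicts)[!cl$verdicts]
    tally[f] <- tally[f] + 1L
  }
  if (!quiet) {
    message(sprintf("call_snvs: %d candidate sites, %d PASS; failures: %s",
                    length(calls), sum(vapply(calls, `[[`, logical(1), "pass")),
                    paste(sprintf("%s=%d", names(tally), tally),
                          collapse = ", ")))
  }
  attr(calls, "stage_failures") <- tally
  calls
}

#' Convert SNV calls to a variant-record data frame (VCF-ready)
#' @param calls List of `snv_call`s.
#' @return Data frame with locus, sample, counts, per-filter p-values and
#'   filter status; zero rows for an empty call set.
#' @export
snv_calls_to_records <- function(calls) {
  if (!length(calls)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), sample = character(),
                      filter = character(), stringsAsFactors = FALSE))
  }
  getp <- function(cl, nm) {
    if (is.null(cl$tests[[nm]])) NA_real_ else cl$tests[[nm]]$p_value
  }
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(
      chrom = cl$chrom, pos = cl$pos, ref = cl$ref, alt = cl$alt,
      sample = cl$pair_id, filter = cl$filter_status,
      tdp = cl$tumor_hq_depth, tad = cl$tumor_alt,
      ndp = cl$normal_hq_depth, nad = cl$normal_alt,
      p_tn = getp(cl, "tn_fisher"), p_err = getp(cl, "seq_error"),
      p_bq = getp(cl, "baseq_rank"), p_rep = getp(cl, "repeat_align"),
      p_end = getp(cl, "end_bias"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write SNV calls to VCF with the cascade's FILTER vocabulary
#' @param calls List of `snv_call`s.
#' @param path Output VCF path.
#' @export
write_snv_vcf <- function(calls, path) {
  write_vcf(snv_calls_to_records(calls), path,
            filter_defs = SNV_FILTER_DESCRIPTIONS)
}
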