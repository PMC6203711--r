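# Tiny in-code fixtures shared across test files.

make_mini_pileup <- function() {
  data.frame(
    sample = rep(c("P1_T", "P1_N"), each = 6),
    chrom = "chr1",
    pos = rep(c(10L, 20L, 30L), 4),
    ref = "A",
    base = c("T", "T", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A"),
    base_quality = 30L, mapping_quality = 60L, repeat_flag = 0L,
    dist_5prime = 50L, dist_3prime = 49L, strand = "+",
    stringsAsFactors = FALSE
  )
}

mini_manifest <- data.frame(pair_id = "P1", tumor = "P1_T", normal = "P1_N",
                            group = "g", stringsAsFactors = FALSE)

# A clean indel candidate that passes every criterion.
clean_indel <- function(id = "ind1", sample = "P1", pos = 5000L) {
  data.frame(
    id = id, sample = sample, chrom = "chr1", pos = pos, ref = "AT", alt = "A",
    total_coverage = 60L, n_support = 12L, avg_mapq_support = 45,
    avg_mismatches_support = 0.5, avg_baseq_support = 32,
    median_end_offset = 25L, frac_forward_support = 0.5,
    frac_reverse_support = 0.5, stringsAsFactors = FALSE
  )
}
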