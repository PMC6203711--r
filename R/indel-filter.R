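# Rule-based somatic indel filtering. Candidates (already predicted
# upstream) are summarized per site; a candidate FAILS a criterion if:
#
#   low_coverage   total coverage at the site < 30X
#   low_mapq       mean mapping quality of indel-supporting reads < 30
#   high_mismatch  mean mismatches per indel-supporting read >= 2
#   low_baseq      mean base quality of indel-supporting reads < 20
#   end_proximal   median indel offset from the nearer read end <= 10 bp
#   strand_bias    forward- or reverse-aligned support fraction < 20%
#                  (min of the two strand fractions)
#   known_site     exact (chrom, pos, ref, alt) in the known-sites list
#                  (a dbSNP-style exclusion)
#
# Boundary semantics are literal: coverage 29 fails and 30 passes,
# 2.0 mismatches fails, offset 10 fails and 11 passes, strand 0.20 passes.

INDEL_CRITERIA <- c("low_coverage", "low_mapq", "high_mismatch", "low_baseq",
                    "end_proximal", "strand_bias", "known_site")

INDEL_FILTER_DESCRIPTIONS <- c(
  low_coverage = "Total coverage at the site < 30X",
  low_mapq = "Average mapping quality of indel-supporting reads < 30",
  high_mismatch = "Average mismatches per indel-supporting read >= 2",
  low_baseq = "Average base quality of indel-supporting reads < 20",
  end_proximal = "Median indel offset within 10 bp of read ends",
  strand_bias = "Forward- or reverse-aligned support fraction < 20%",
  known_site = "Locus present in the known-variant-sites list"
)

#' Parameters of the somatic indel filter
#' @param min_coverage Minimum total coverage (default 30).
#' @param min_mapq Minimum mean mapping quality of supporting reads (30).
#' @param max_mismatches Mean mismatches per supporting read at or above
#'   which the candidate fails (2).
#' @param min_baseq Minimum mean base quality of supporting reads (20).
#' @param max_end_offset Median end offset at or below which the candidate
#'   fails (10 bp).
#' @param min_strand_frac Minimum fraction of supporting reads on the rarer
#'   strand (0.20).
#' @export
indel_params <- function(min_coverage = 30, min_mapq = 30, max_mismatches = 2,
                         min_baseq = 20, max_end_offset = 10,
                         min_strand_frac = 0.20) {
  structure(list(min_coverage = min_coverage, min_mapq = min_mapq,
                 max_mismatches = max_mismatches, min_baseq = min_baseq,
                 max_end_offset = max_end_offset,
                 min_strand_frac = min_strand_frac),
            class = "indel_params")
}

#' Filter one indel candidate
#'
#' @param candidate One-row data frame (or list) with fields: chrom, pos,
#'   ref, alt, sample, total_coverage, n_support, avg_mapq_support,
#'   avg_mismatches_support, avg_baseq_support, median_end_offset,
#'   frac_forward_support, frac_reverse_support.
#' @param params An [indel_params()].
#' @param known A `known_sites` object or NULL.
#' @return An `indel_verdict`: per-criterion verdicts (TRUE = pass),
#'   `pass`, `filter_status`.
#' @export
filter_indel <- function(candidate, params = indel_params(), known = NULL) {
  cd <- as.list(candidate)
  if (is.null(cd$n_support) || cd$n_support == 0) {
    stop("degenerate candidate: no indel-supporting reads")
  }
  if (cd$n_support > 0) {
    s <- cd$frac_forward_support + cd$frac_reverse_support
    if (abs(s - 1) > 1e-9) stop("strand fractions must sum to 1")
  }
  verdicts <- c(
    low_coverage = cd$total_coverage >= params$min_coverage,
    low_mapq = cd$avg_mapq_support >= params$min_mapq,
    high_mismatch = cd$avg_mismatches_support < params$max_mismatches,
    low_baseq = cd$avg_baseq_support >= params$min_baseq,
    end_proximal = cd$median_end_offset > params$max_end_offset,
    strand_bias = min(cd$frac_forward_support, cd$frac_reverse_support) >=
      params$min_strand_frac,
    known_site = !locus_in_known_sites(known, cd$chrom, cd$pos, cd$ref, cd$alt)
  )
  failing <- names(verdicts)[!verdicts]
  structure(list(
    candidate = cd, verdicts = verdicts, pass = all(verdicts),
    filter_status = if (all(verdicts)) "PASS" else paste(failing, collapse = ";")
  ), class = "indel_verdict")
}

#' Filter a batch of indel candidates
#'
#' @param candidates Candidates data frame (one row each; `id` column must
#'   be unique).
#' @param params An [indel_params()].
#' @param known A `known_sites` object or NULL.
#' @param quiet Suppress the per-criterion failure tally message.
#' @return List of `indel_verdict`s sorted by (chrom, pos), with attribute
#'   `criterion_failures`.
#' @export
filter_indels <- function(candidates, params = indel_params(), known = NULL,
                          quiet = FALSE) {
  if (nrow(candidates) && anyDuplicated(candidates$id)) {
    stop("integrity error: duplicate candidate id ",
         candidates$id[duplicated(candidates$id)][1])
  }
  if (nrow(candidates)) {
    candidates <- candidates[order(candidates$chrom, candidates$pos,
                                   candidates$sample), , drop = FALSE]
  }
  verdicts <- lapply(seq_len(nrow(candidates)), function(i) {
    filter_indel(candidates[i, ], params, known)
  })
  tally <- stats::setNames(integer(length(INDEL_CRITERIA)), INDEL_CRITERIA)
  for (v in verdicts) {
    f <- names(v$verdicts)[!v$verdicts]
    tally[f] <- tally[f] + 1L
  }
  if (!quiet) {
    message(sprintf("filter_indels: %d candidates, %d PASS; failures: %s",
                    length(verdicts),
                    sum(vapply(verdicts, `[[`, logical(1), "pass")),
                    paste(sprintf("%s=%d", names(tally), tally),
                          collapse = ", ")))
  }
  attr(verdicts, "criterion_failures") <- tally
  verdicts
}

#' Convert indel verdicts to a VCF-ready record data frame
#' @param verdicts List of `indel_verdict`s.
#' @export
indel_verdicts_to_records <- function(verdicts) {
  if (!length(verdicts)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), sample = character(),
                      filter = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(verdicts, function(v) {
    cd <- v$candidate
    data.frame(chrom = cd$chrom, pos = cd$pos, ref = cd$ref, alt = cd$alt,
               sample = cd$sample, filter = v$filter_status,
               dp = as.integer(cd$total_coverage),
               sup = as.integer(cd$n_support),
               stringsAsFactors = FALSE)
  }))
}

#' Write indel verdicts to VCF
#' @param verdicts List of `indel_verdict`s.
#' @param path Output path.
#' @export
write_indel_vcf <- function(verdicts, path) {
  write_vcf(indel_verdicts_to_records(verdicts), path,
            filter_defs = INDEL_FILTER_DESCRIPTIONS)
}
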