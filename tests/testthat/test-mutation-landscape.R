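# Consequence classification on a hand-built two-gene genome, recurrence,
# frequencies, burden and cohort comparisons.

# chr1 layout (1-based):
#   1-10   padding
#   11-22  plus-strand gene GP: CDS = ATG CTT TAC TAA
#   23-30  padding
#   31-39  minus-strand gene GM: coding CDS = ATG GAT TAA,
#          genomic (plus strand) = TTAATCCAT
#   40-50  padding
hand_genome <- function() {
  seq1 <- paste0("GGGGGGGGGG", "ATGCTTTACTAA", "GGGGGGGG", "TTAATCCAT",
                 "GGGGGGGGGGG")
  models <- data.frame(
    gene_id = c("GP", "GM"), chrom = "chr1",
    start = c(11L, 31L), end = c(22L, 39L),
    strand = c("+", "-"),
    cds_blocks = c("11-22", "31-39"),
    stringsAsFactors = FALSE
  )
  list(seqs = c(chr1 = seq1), models = models)
}

test_that("consequence classification follows the genetic code", {
  g <- hand_genome()
  expect_equal(extract_cds(g$seqs, g$models[1, ]), "ATGCTTTACTAA")
  expect_equal(extract_cds(g$seqs, g$models[2, ]), "ATGGATTAA")

  # CTT -> CTC (Leu -> Leu)
  r <- classify_consequence("chr1", 16, "T", "C", g$models, g$seqs)
  expect_equal(r, list(gene = "GP", consequence = "synonymous"))
  # TAC -> TAA (Tyr -> stop)
  r <- classify_consequence("chr1", 19, "C", "A", g$models, g$seqs)
  expect_equal(r$consequence, "stopgain")
  # TAA -> CAA (stop lost)
  r <- classify_consequence("chr1", 20, "T", "C", g$models, g$seqs)
  expect_equal(r$consequence, "stoploss")
  # CTT -> CAT (Leu -> His)
  r <- classify_consequence("chr1", 15, "T", "A", g$models, g$seqs)
  expect_equal(r$consequence, "missense")
  # outside any gene
  r <- classify_consequence("chr1", 5, "G", "A", g$models, g$seqs)
  expect_equal(r, list(gene = NA_character_, consequence = "noncoding"))

  # minus strand: plus-strand A>G at chr1:34 changes coding GAT -> GAC
  r <- classify_consequence("chr1", 34, "A", "G", g$models, g$seqs)
  expect_equal(r, list(gene = "GM", consequence = "synonymous"))
  # minus strand missense: coding GAT -> GTT (Asp -> Val), plus strand T>A at 35
  r <- classify_consequence("chr1", 35, "T", "A", g$models, g$seqs)
  expect_equal(r$consequence, "missense")

  expect_error(classify_consequence("chr1", 9999, "A", "T", g$models, g$seqs),
               "coordinate error")
})

test_that("classifier agrees with the translate-whole-CDS oracle everywhere", {
  g <- hand_genome()
  for (gi in 1:2) {
    m <- g$models[gi, ]
    cds <- extract_cds(g$seqs, m)
    cds_pos <- if (m$strand == "-") {
      rev(seq(m$start, m$end))
    } else {
      seq(m$start, m$end)
    }
    for (i in seq_len(nchar(cds))) {
      genomic_pos <- cds_pos[i]
      ref_plus <- substring(g$seqs[["chr1"]], genomic_pos, genomic_pos)
      for (alt_plus in setdiff(c("A", "C", "G", "T"), ref_plus)) {
        alt_coding <- if (m$strand == "-") chartr("ACGT", "TGCA", alt_plus)
                      else alt_plus
        expected <- oracle_consequence(cds, i, alt_coding)
        got <- classify_consequence("chr1", genomic_pos, ref_plus, alt_plus,
                                    g$models, g$seqs)$consequence
        expect_equal(got, expected,
                     info = sprintf("gene %s, cds offset %d, alt %s",
                                    m$gene_id, i, alt_plus))
      }
    }
  }
})

test_that("recurrence matrix is a binary indicator over non-synonymous records", {
  records <- data.frame(
    sample = c("s1", "s2", "s2", "s3", "s1", "s1"),
    gene = c("Ryr1", "Ryr1", "Ryr1", "Mtor", "Sdk1", "Ttn"),
    consequence = c("missense", "stopgain", "missense", "missense",
                    "synonymous", "noncoding"),
    stringsAsFactors = FALSE
  )
  rec <- build_recurrence(records, samples = c("s1", "s2", "s3"))
  expect_equal(sort(rownames(rec$matrix)), c("Mtor", "Ryr1"))
  expect_equal(unname(rec$matrix["Ryr1", ]), c(1L, 1L, 0L))  # duplicates -> 1
  expect_equal(recurrent_genes(rec, 2L), "Ryr1")
  # one-sample gene is not recurrent
  expect_false("Mtor" %in% recurrent_genes(rec, 2L))
  # the permissive flag admits synonymous records too
  rec_all <- build_recurrence(records, samples = c("s1", "s2", "s3"),
                              nonsyn_only = FALSE)
  expect_true("Sdk1" %in% rownames(rec_all$matrix))
})

test_that("mutation frequencies reproduce the printed cohort percentages", {
  m <- matrix(0L, 1, 42, dimnames = list("RYR1", paste0("s", 1:42)))
  groups <- stats::setNames(rep(c("mouse", "human"), c(5, 37)),
                            colnames(m))
  m["RYR1", 1:4] <- 1L      # 4 of 5 mice
  m["RYR1", 6:10] <- 1L     # 5 of 37 humans
  rec <- structure(list(matrix = m, groups = groups),
                   class = "recurrence_matrix")
  fm <- mutation_frequency("RYR1", rec, group = "mouse")
  expect_equal(fm$percent, 80)
  expect_equal(fm$fraction, 4 / 5)
  fh <- mutation_frequency("RYR1", rec, group = "human")
  expect_equal(fh$percent, 13.5)
  expect_equal(fh$count, 5L)
  f0 <- mutation_frequency("RYR1", rec)
  expect_equal(f0$n, 42L)
  expect_error(mutation_frequency("NOPE", rec), "lookup error")
})

test_that("burden comparison: printed summaries give fold 7.8 and p < 0.05", {
  b <- burden_compare(summary1 = c(335, 84, 5), summary2 = c(43, 13, 3))
  expect_equal(b$fold, 7.8)
  expect_lt(b$test$p_value, 0.05)

  counts <- c(5, 6, 7, 5, 6, 7)
  groups <- rep(c("a", "b"), each = 3)
  b0 <- burden_compare(counts, groups)
  expect_equal(b0$fold, 1.0)
  expect_equal(b0$test$p_value, 1)

  # invariant to sample ordering
  withr::with_seed(4, {
    counts <- c(rpois(5, 300), rpois(3, 40))
    groups <- rep(c("hfhc", "hf"), c(5, 3))
    b1 <- burden_compare(counts, groups)
    perm <- sample(8)
    b2 <- burden_compare(counts[perm], groups[perm])
    expect_equal(b1$fold, b2$fold)
    expect_equal(abs(b1$test$statistic), abs(b2$test$statistic),
                 tolerance = 1e-12)
  })
})

test_that("overlap and ortholog mapping follow the documented rules", {
  expect_equal(overlap_count(c("A", "B", "C"), c("B", "C", "D")), 2L)
  expect_equal(map_orthologs(c("x"), stats::setNames(character(0),
                                                     character(0))),
               character(0))
  map <- c(Gm1 = "HUM1", Gm2 = "HUM1", Gm3 = "HUM3")
  expect_equal(map_orthologs(c("Gm1", "Gm2", "Gm3"), map), c("HUM1", "HUM3"))
})

test_that("cohort frequency comparison is a symmetric chi-square", {
  expect_equal(frequency_compare(5, 10, 5, 10)$p_value, 1)
  r <- frequency_compare(9, 10, 1, 10)
  n <- 20; a <- 9; b <- 1; c <- 1; d <- 9
  closed <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(r$statistic, closed, tolerance = 1e-10)
  expect_lt(r$p_value, 0.05)
  expect_equal(frequency_compare(9, 10, 1, 10)$p_value,
               frequency_compare(1, 10, 9, 10)$p_value, tolerance = 1e-12)
})
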