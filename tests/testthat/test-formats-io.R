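# Readers/writers: round-trips, validation errors, VCF serialization
# cross-checked with an independent VCF parser.

test_that("pileup TSV round-trips and groups into paired sites", {
  pu <- make_mini_pileup()
  path <- tempfile(fileext = ".tsv")
  write_pileups(pu, path)
  back <- read_pileups(path, manifest = mini_manifest)
  expect_equal(back[, names(pu)], pu)
  sites <- pair_sites(back, mini_manifest)
  expect_length(sites, 3L)
  expect_true(all(vapply(sites, function(s) nrow(s$tumor) == 2, logical(1))))
})

test_that("pileup validation reports bad rows with line numbers", {
  pu <- make_mini_pileup()
  pu$base[3] <- "N"
  path <- tempfile(fileext = ".tsv")
  write_pileups(pu, path)
  expect_error(read_pileups(path), "line 4")

  pu <- make_mini_pileup()
  pu$base_quality[5] <- -2L
  write_pileups(pu, path)
  expect_error(read_pileups(path), "line 6")

  pu <- make_mini_pileup()
  pu$sample[7:12] <- "P2_N"  # mate missing from the data
  write_pileups(pu, path)
  mani2 <- rbind(mini_manifest,
                 data.frame(pair_id = "P2", tumor = "P2_T", normal = "P2_N",
                            group = "g"))
  expect_error(read_pileups(path, manifest = mani2), "pairing error")
})

test_that("simulated pileups round-trip through disk exactly", {
  cfg <- test_config(n_samples_per_group = c(NASH = 2L),
                     n_somatic_per_sample = 5L, n_germline = 5L,
                     n_background = 10L)
  g <- make_genome(cfg)
  sim <- simulate_paired_pileups(g, cfg)
  path <- tempfile(fileext = ".tsv")
  write_pileups(sim$pileup, path)
  back <- read_pileups(path, manifest = sim$manifest)
  attr(back, "manifest") <- NULL
  expect_equal(back, sim$pileup)
})

test_that("write_vcf emits valid v4.2 with the filter contract", {
  path <- tempfile(fileext = ".vcf")
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), filter = character())
  write_vcf(empty, path, filter_defs = c(end_bias = "x"))
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_false(any(!startsWith(lines, "#")))
  expect_silent(validate_vcf(path))

  recs <- data.frame(
    chrom = c("chr1", "chr1"), pos = c(100L, 50L), ref = c("A", "C"),
    alt = c("T", "G"), sample = c("s1", "s1"),
    filter = c("PASS", "end_bias;repeat_align"),
    tad = c(12L, 3L), p_tn = c(0.000123456, 0.2),
    stringsAsFactors = FALSE
  )
  write_vcf(recs, path, filter_defs = c(end_bias = "end", repeat_align = "rep"))
  expect_silent(validate_vcf(path))
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  # sorted by position; FILTER column carries the exact strings
  expect_match(body[1], "^chr1\t50\t")
  expect_match(body[1], "\tend_bias;repeat_align\t")
  expect_match(body[2], "\tPASS\t")

  dup <- rbind(recs, recs[1, ])
  expect_error(write_vcf(dup, path, filter_defs = c(end_bias = "e",
                                                    repeat_align = "r")),
               "integrity error")
})

test_that("written VCF is readable by an independent parser", {
  recs <- data.frame(
    chrom = "chr2", pos = 77L, ref = "G", alt = "A", sample = "s9",
    filter = "PASS", tad = 9L, p_tn = 0.0042, stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".vcf")
  write_vcf(recs, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  expect_equal(unname(fix[1, "CHROM"]), "chr2")
  expect_equal(as.integer(fix[1, "POS"]), 77L)
  expect_equal(unname(fix[1, "REF"]), "G")
  expect_equal(unname(fix[1, "ALT"]), "A")
  expect_equal(unname(fix[1, "FILTER"]), "PASS")
  expect_match(fix[1, "INFO"], "TAD=9")
})

test_that("GMT round-trips and rejects duplicate ids", {
  sets <- list(S1 = c("a", "b", "c"), S2 = c("b", "d"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  writeLines(c("S1\tna\ta\tb", "S1\tna\tc"), path)
  expect_error(read_gmt(path), "duplicate set id")
  write_gmt(sets, path)
  expect_equal(fgsea::gmtPathways(path), sets)
})

test_that("matrix reader reports bad cells with coordinates", {
  m <- matrix(1:6 / 2, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path)
  expect_equal(read_matrix(path), m)
  lines <- readLines(path)
  lines[3] <- sub("\t1\t", "\tNaX\t", lines[3])
  writeLines(lines, path)
  expect_error(read_matrix(path), "gene 'g2', sample 's1'")
})

test_that("ortholog map and known sites behave as specified", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "Ryr1\tRYR1", "Mtor\tMTOR", "Gm123\tRYR1"), path)
  map <- read_ortholog_map(path)
  expect_equal(map[["Ryr1"]], "RYR1")
  expect_equal(map_orthologs(c("Ryr1", "Gm123", "Unknown"), map), "RYR1")
  expect_equal(map_orthologs(character(0), map), character(0))
  writeLines(c("from\tto", "Ryr1\tRYR1", "Ryr1\tRYR2"), path)
  expect_error(read_ortholog_map(path), "integrity error")

  ks_path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t500\tAT\tA"), ks_path)
  ks <- read_known_sites(ks_path)
  expect_true(locus_in_known_sites(ks, "chr1", 500, "AT", "A"))
  expect_false(locus_in_known_sites(ks, "chr1", 500, "AT", "AG"))
  expect_false(locus_in_known_sites(known_sites(), "chr1", 500, "AT", "A"))
})
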