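#!/usr/bin/env Rscript
# Stage 2: somatic variant calling. Runs the seven-stage SNV filter cascade
# on the paired pileups and the six-criterion indel filter (with known-sites
# exclusion) on the candidate summaries, then scores both against the
# planted truth.

suppressPackageStartupMessages(library(nashhcc))

sim_dir <- "results/simulation"
out <- "results/variants"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifest <- read.delim(file.path(sim_dir, "pairs.tsv"))
pileup <- read_pileups(file.path(sim_dir, "pileups.tsv"), manifest = manifest)

calls <- call_snvs(pileup, manifest, quiet = FALSE)
write_snv_vcf(calls, file.path(out, "somatic_snvs.vcf"))
validate_vcf(file.path(out, "somatic_snvs.vcf"))
recs <- snv_calls_to_records(calls)
write.table(recs, file.path(out, "snv_records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pass <- recs[recs$filter == "PASS", ]
pass_key <- paste(pass$sample, pass$chrom, pass$pos, pass$alt)
som <- read.delim(file.path(sim_dir, "truth_somatic.tsv"))
germ <- read.delim(file.path(sim_dir, "truth_germline.tsv"))
sens <- mean(paste(som$sample, som$chrom, som$pos, som$alt) %in% pass_key)
leak <- sum(paste(germ$sample, germ$chrom, germ$pos, germ$alt) %in% pass_key)

art <- read.delim(file.path(sim_dir, "truth_artifacts.tsv"))
stage_of <- c(end_biased = "end_bias", repeat_biased = "repeat_align",
              low_quality_alt = "baseq_rank")
rec_key <- paste(recs$sample, recs$chrom, recs$pos)
rej <- vapply(names(stage_of), function(cls) {
  sub <- art[art$class == cls, ]
  mean(vapply(seq_len(nrow(sub)), function(i) {
    j <- match(paste(sub$sample[i], sub$chrom[i], sub$pos[i]), rec_key)
    !is.na(j) && recs$filter[j] != "PASS" &&
      stage_of[[cls]] %in% strsplit(recs$filter[j], ";")[[1]]
  }, logical(1)))
}, numeric(1))

cat(sprintf(
  "SNV cascade: %d candidate sites, %d PASS.\nSensitivity on planted somatic events: %.3f; germline leakage: %d of %d;\nartifact rejection with the matching flag: end %.2f, repeat %.2f, base-quality %.2f.\n",
  nrow(recs), nrow(pass), sens, leak, nrow(germ),
  rej["end_biased"], rej["repeat_biased"], rej["low_quality_alt"]))

candidates <- read.delim(file.path(sim_dir, "indel_candidates.tsv"))
known <- read_known_sites(file.path(sim_dir, "known_sites.tsv"))
verdicts <- filter_indels(candidates, known = known, quiet = FALSE)
write_indel_vcf(verdicts, file.path(out, "somatic_indels.vcf"))
validate_vcf(file.path(out, "somatic_indels.vcf"))

truth_ind <- read.delim(file.path(sim_dir, "truth_indels.tsv"))
got <- vapply(verdicts, `[[`, character(1), "filter_status")
names(got) <- vapply(verdicts, function(v) v$candidate$id, character(1))
agree <- mean(got[truth_ind$id] == truth_ind$expected)
cat(sprintf("Indel filter: %d candidates, %d PASS; verdicts match planted expectations for %.1f%%.\n",
            length(verdicts), sum(vapply(verdicts, `[[`, logical(1), "pass")),
            100 * agree))
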