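# Paired tumor/normal read-observation simulator. Plants somatic SNVs
# (tumor-only alt reads at Binomial(depth, VAF)), germline heterozygous
# variants (both samples near VAF 0.5), three artifact classes matched to
# the cascade's screens (read-end clustering, repeat alignment, low alt
# base quality) and background loci carrying only sequencing error. Depth
# is Poisson per sample per site; truth loci are resampled if a zero depth
# is drawn so no truth pileup is empty.

.DEFAULT_BQ_MEAN <- 35
.DEFAULT_BQ_SD <- 4
.LOWQ_BQ_MEAN <- 15
.LOWQ_BQ_SD <- 1.5
.REPEAT_RATE <- 0.05
.END_WINDOW <- 10L

.draw_depth <- function(n, mean, force_positive = FALSE) {
  d <- stats::rpois(n, mean)
  if (force_positive) {
    while (any(d == 0L)) d[d == 0L] <- stats::rpois(sum(d == 0L), mean)
  }
  d
}

.default_quals <- function(n) {
  pmin(pmax(round(stats::rnorm(n, .DEFAULT_BQ_MEAN, .DEFAULT_BQ_SD)), 12L), 41L)
}

.lowq_quals <- function(n) {
  pmin(pmax(round(stats::rnorm(n, .LOWQ_BQ_MEAN, .LOWQ_BQ_SD)), 11L), 19L)
}

# expand site-level counts into per-read observation rows for one sample
.emit_reads <- function(sites, sample_id, read_length) {
  n_tot <- sites$n_alt + sites$n_ref
  keep <- n_tot > 0L
  sites <- sites[keep, , drop = FALSE]
  n_tot <- n_tot[keep]
  if (!nrow(sites)) return(NULL)
  idx <- rep(seq_len(nrow(sites)), n_tot)
  rank <- sequence(n_tot)
  is_alt <- rank <= sites$n_alt[idx]
  n <- length(idx)
  cls <- sites$class[idx]

  bq <- .default_quals(n)
  lowq <- cls == "low_quality_alt" & is_alt
  if (any(lowq)) bq[lowq] <- .lowq_quals(sum(lowq))

  rep_flag <- stats::rbinom(n, 1L, .REPEAT_RATE)
  rep_flag[cls == "repeat_biased" & is_alt] <- 1L

  d5 <- sample.int(read_length, n, replace = TRUE) - 1L
  endb <- cls == "end_biased" & is_alt
  if (any(endb)) {
    k <- sum(endb)
    offset <- sample.int(.END_WINDOW, k, replace = TRUE) - 1L
    at_5p <- stats::runif(k) < 0.5
    d5[endb] <- ifelse(at_5p, offset, read_length - 1L - offset)
  }

  data.frame(
    sample = sample_id,
    chrom = sites$chrom[idx],
    pos = sites$pos[idx],
    ref = sites$ref[idx],
    base = ifelse(is_alt, sites$alt[idx], sites$ref[idx]),
    base_quality = bq,
    mapping_quality = 60L,
    repeat_flag = rep_flag,
    dist_5prime = d5,
    dist_3prime = read_length - 1L - d5,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate paired tumor/normal pileups with known ground truth
#'
#' For every tumor/normal pair, read observations are emitted at all truth
#' loci (somatic, germline, artifact) plus background loci. Somatic loci
#' carry alt reads at `Binomial(depth, somatic_vaf)` in the tumor and at
#' `somatic_vaf * normal_contamination` in the normal; germline loci carry
#' alt in both samples near VAF 0.5; artifact loci imitate the failure mode
#' their class names (alt reads within 10 bases of a read end, repeat-
#' aligned alt reads, or low alt base qualities); background loci carry
#' sequencing error at `base_error_rate`. Somatic events are planted inside
#' CDS so gene and consequence are defined.
#'
#' @param genome A `toy_genome` from [make_genome()].
#' @param config A [sim_config()].
#' @return List: `pileup` (read-observation data frame, sorted by sample,
#'   chrom, pos), `manifest` (pair_id, tumor, normal, group), and `truth`
#'   (lists `somatic`, `germline`, `artifacts` keyed by pair_id).
#' @export
simulate_paired_pileups <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  models <- genome$models
  seqs <- genome$seqs

  withr::with_seed(.sim_seed(config, "pileup"), {
    # CDS locus pool (for somatic events) and whole-genome pool
    cds_pool <- do.call(rbind, lapply(seq_len(nrow(models)), function(i) {
      m <- models[i, ]
      blocks <- parse_cds_blocks(m$cds_blocks)
      pos <- unlist(apply(blocks, 1, function(b) seq(b[1], b[2]),
                          simplify = FALSE))
      data.frame(chrom = m$chrom, pos = pos, gene = m$gene_id,
                 stringsAsFactors = FALSE)
    }))

    groups <- names(config$n_samples_per_group)
    manifest <- do.call(rbind, lapply(groups, function(g) {
      k <- config$n_samples_per_group[[g]]
      if (k == 0L) return(NULL)
      pair_id <- sprintf("%s_%d", g, seq_len(k))
      data.frame(pair_id = pair_id, tumor = paste0(pair_id, "_T"),
                 normal = paste0(pair_id, "_N"), group = g,
                 stringsAsFactors = FALSE)
    }))

    truth_somatic <- list(); truth_germline <- list(); truth_artifact <- list()
    pileups <- list()

    for (i in seq_len(nrow(manifest))) {
      pair <- manifest$pair_id[i]
      grp <- manifest$group[i]
      n_som <- config$n_somatic_per_sample[[grp]]
      n_art <- config$artifact_counts
      n_bg <- config$n_background

      som_idx <- sample.int(nrow(cds_pool), n_som)
      som <- cds_pool[som_idx, , drop = FALSE]

      # remaining loci drawn genome-wide, unique within the pair
      n_other <- config$n_germline + sum(n_art) + n_bg
      other <- data.frame(
        chrom = sample(names(seqs), n_other * 2L, replace = TRUE),
        pos = sample.int(config$chrom_length, n_other * 2L, replace = TRUE)
      )
      other <- other[!duplicated(paste(other$chrom, other$pos)), ]
      used <- paste(som$chrom, som$pos)
      other <- other[!(paste(other$chrom, other$pos) %in% used), ]
      if (nrow(other) < n_other) stop("locus pool exhausted; enlarge genome")
      other <- other[seq_len(n_other), ]

      cut1 <- config$n_germline
      germ <- other[seq_len(cut1), , drop = FALSE]
      art <- other[cut1 + seq_len(sum(n_art)), , drop = FALSE]
      bg <- other[cut1 + sum(n_art) + seq_len(n_bg), , drop = FALSE]
      art$class <- rep(names(n_art), times = n_art)

      ref_at <- function(df) {
        vapply(seq_len(nrow(df)), function(j) {
          substring(seqs[[df$chrom[j]]], df$pos[j], df$pos[j])
        }, character(1))
      }
      alt_for <- function(ref) {
        vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), character(1),
               USE.NAMES = FALSE)
      }

      som$ref <- ref_at(som); som$alt <- alt_for(som$ref)
      germ$ref <- ref_at(germ); germ$alt <- alt_for(germ$ref)
      art$ref <- ref_at(art); art$alt <- alt_for(art$ref)
      bg$ref <- ref_at(bg); bg$alt <- alt_for(bg$ref)

      som$consequence <- vapply(seq_len(nrow(som)), function(j) {
        classify_consequence(som$chrom[j], som$pos[j], som$ref[j], som$alt[j],
                             models, seqs)$consequence
      }, character(1))

      vaf <- config$somatic_vaf
      site_block <- function(df, vaf, class) {
        data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                   alt = df$alt, vaf = rep_len(vaf, nrow(df)),
                   class = rep_len(class, nrow(df)),
                   stringsAsFactors = FALSE)
      }
      # tumor side
      t_sites <- rbind(
        site_block(som, vaf, "somatic"),
        site_block(germ, 0.5, "germline"),
        site_block(art, vaf, if (nrow(art)) art$class else character(0)),
        site_block(bg, config$base_error_rate, "background")
      )
      n_sites <- nrow(t_sites)
      truth_site <- t_sites$class != "background"
      t_depth <- .draw_depth(n_sites, config$depth_mean)
      t_depth[truth_site] <- .draw_depth(sum(truth_site), config$depth_mean,
                                         force_positive = TRUE)
      t_sites$n_alt <- stats::rbinom(n_sites, t_depth, t_sites$vaf)
      t_sites$n_ref <- t_depth - t_sites$n_alt

      # matched normal: germline keeps VAF 0.5; somatic leaks at the
      # contamination rate; artifacts are tumor-only; background errors
      n_vaf <- ifelse(t_sites$class == "germline", 0.5,
               ifelse(t_sites$class == "somatic",
                      vaf * config$normal_contamination,
               ifelse(t_sites$class == "background",
                      config$base_error_rate, 0)))
      n_depth <- .draw_depth(n_sites, config$depth_mean)
      n_depth[truth_site] <- .draw_depth(sum(truth_site), config$depth_mean,
                                         force_positive = TRUE)
      n_sites_df <- t_sites
      n_sites_df$class <- "none"  # artifact read features are tumor-only
      n_sites_df$n_alt <- stats::rbinom(n_sites, n_depth, n_vaf)
      n_sites_df$n_ref <- n_depth - n_sites_df$n_alt

      pileups[[length(pileups) + 1L]] <-
        .emit_reads(t_sites, manifest$tumor[i], config$read_length)
      pileups[[length(pileups) + 1L]] <-
        .emit_reads(n_sites_df, manifest$normal[i], config$read_length)

      truth_somatic[[pair]] <- data.frame(
        sample = rep_len(pair, nrow(som)), chrom = som$chrom, pos = som$pos,
        ref = som$ref, alt = som$alt, vaf = rep_len(vaf, nrow(som)),
        gene = som$gene, consequence = som$consequence,
        stringsAsFactors = FALSE
      )
      truth_germline[[pair]] <- data.frame(
        sample = rep_len(pair, nrow(germ)), chrom = germ$chrom,
        pos = germ$pos, ref = germ$ref, alt = germ$alt,
        vaf = rep_len(0.5, nrow(germ)), stringsAsFactors = FALSE
      )
      truth_artifact[[pair]] <- data.frame(
        sample = rep_len(pair, nrow(art)), chrom = art$chrom, pos = art$pos,
        ref = art$ref, alt = art$alt, class = art$class,
        stringsAsFactors = FALSE
      )
    }

    pileup <- do.call(rbind, pileups)
    pileup <- pileup[order(pileup$sample, pileup$chrom, pileup$pos), ]
    rownames(pileup) <- NULL

    truth <- list(
      somatic = do.call(rbind, c(truth_somatic, list(make.row.names = FALSE))),
      germline = do.call(rbind, c(truth_germline, list(make.row.names = FALSE))),
      artifacts = do.call(rbind, c(truth_artifact, list(make.row.names = FALSE)))
    )
    list(pileup = pileup, manifest = manifest, truth = truth)
  })
}

#' Simulate somatic indel candidate summaries with planted filter failures
#'
#' Emits, per tumor/normal pair, `n_clean` candidates that satisfy every
#' filter criterion plus one candidate engineered to fail each named
#' criterion and one clean candidate placed at a known variant site.
#'
#' @param config A [sim_config()].
#' @param n_clean Clean candidates per pair.
#' @return List: `candidates` data frame, `known` a `known_sites` object,
#'   `truth` (candidate id -> expected failing criterion or "PASS").
#' @export
simulate_indel_candidates <- function(config, n_clean = 5L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(.sim_seed(config, "indels"), {
    groups <- names(config$n_samples_per_group)
    pairs <- unlist(lapply(groups, function(g) {
      sprintf("%s_%d", g, seq_len(config$n_samples_per_group[[g]]))
    }))
    fail_classes <- c("low_coverage", "low_mapq", "high_mismatch",
                      "low_baseq", "end_proximal", "strand_bias",
                      "known_site")
    rows <- list(); truth <- list(); known_rows <- list()
    counter <- 0L
    clean_row <- function(pair, id) {
      data.frame(
        id = id, sample = pair, chrom = "chr1",
        pos = sample.int(config$chrom_length - 100L, 1L),
        ref = "AT", alt = "A",
        total_coverage = sample(40:120, 1L),
        n_support = sample(8:25, 1L),
        avg_mapq_support = round(stats::runif(1, 40, 60), 1),
        avg_mismatches_support = round(stats::runif(1, 0, 1.5), 2),
        avg_baseq_support = round(stats::runif(1, 25, 40), 1),
        median_end_offset = sample(15:40, 1L),
        frac_forward_support = round(stats::runif(1, 0.3, 0.7), 3),
        stringsAsFactors = FALSE
      )
    }
    for (pair in pairs) {
      for (j in seq_len(n_clean)) {
        counter <- counter + 1L
        id <- sprintf("ind%04d", counter)
        rows[[id]] <- clean_row(pair, id)
        truth[[id]] <- "PASS"
      }
      for (cls in fail_classes) {
        counter <- counter + 1L
        id <- sprintf("ind%04d", counter)
        r <- clean_row(pair, id)
        if (cls == "low_coverage") r$total_coverage <- sample(5:29, 1L)
        if (cls == "low_mapq") r$avg_mapq_support <- round(stats::runif(1, 5, 29), 1)
        if (cls == "high_mismatch") r$avg_mismatches_support <- round(stats::runif(1, 2, 6), 2)
        if (cls == "low_baseq") r$avg_baseq_support <- round(stats::runif(1, 5, 19), 1)
        if (cls == "end_proximal") r$median_end_offset <- sample(0:10, 1L)
        if (cls == "strand_bias") r$frac_forward_support <- round(stats::runif(1, 0, 0.19), 3)
        if (cls == "known_site") {
          known_rows[[id]] <- data.frame(chrom = r$chrom, pos = r$pos,
                                         ref = r$ref, alt = r$alt,
                                         stringsAsFactors = FALSE)
        }
        rows[[id]] <- r
        truth[[id]] <- cls
      }
    }
    candidates <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    candidates$frac_reverse_support <- round(1 - candidates$frac_forward_support, 3)
    known <- known_sites(if (length(known_rows)) {
      do.call(rbind, c(known_rows, list(make.row.names = FALSE)))
    } else NULL)
    list(candidates = candidates, known = known,
         truth = unlist(truth))
  })
}
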