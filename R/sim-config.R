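# Configuration for the synthetic-data module. The defaults mirror the
# study design the pipeline emulates: whole-exome sequencing of 5 NASH-HCC
# and 3 steatosis-HCC tumor/normal pairs at high depth, with a heavier
# somatic burden in the NASH group, plus two-color log2-ratio expression
# profiling of the same animals.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators and validates them.
#' Identical `seed` + configuration reproduces every output exactly.
#'
#' @param seed Integer seed; every generator draws from a stream derived
#'   from it.
#' @param n_chromosomes,chrom_length Toy genome shape (chromosome count,
#'   length in bases; `chrom_length >= 1000`).
#' @param n_genes Number of non-overlapping gene models to place.
#' @param n_samples_per_group Named integer vector: tumor/normal pairs per
#'   group label, e.g. `c(NASH = 5, steatosis = 3)`.
#' @param depth_mean Mean sequencing depth (Poisson, drawn independently per
#'   sample per site; tumor and normal alike).
#' @param base_error_rate Per-base sequencing error probability at
#'   background loci.
#' @param somatic_vaf Variant allele fraction of planted somatic events, in
#'   (0, 1]; must exceed `base_error_rate`.
#' @param n_somatic_per_sample Somatic SNVs planted per tumor; scalar or one
#'   value per group (recycled over `n_samples_per_group`).
#' @param n_germline Germline heterozygous variants planted per pair
#'   (present in tumor and normal near VAF 0.5).
#' @param artifact_counts Named counts of planted artifact sites per tumor:
#'   `end_biased`, `repeat_biased`, `low_quality_alt`.
#' @param normal_contamination Fraction of the tumor VAF leaking into the
#'   matched normal at somatic loci.
#' @param n_background Background (truth-free) loci emitted per sample so
#'   specificity is measurable.
#' @param read_length Read length in bases (fixed geometry; end distances
#'   uniform for non-artifact reads).
#' @param expression List: `n_genes` (expression gene universe; the array
#'   probes many more genes than the toy genome carries), `n_de_genes`,
#'   `log2_effect_size`, `noise_sd`.
#' @param pathways List: `n_sets`, `set_size`, `planted_enriched`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       chrom_length = 60000L,
                       n_genes = 300L,
                       n_samples_per_group = c(NASH = 5L, steatosis = 3L),
                       depth_mean = 80,
                       base_error_rate = 0.001,
                       somatic_vaf = 0.3,
                       n_somatic_per_sample = c(NASH = 20L, steatosis = 3L),
                       n_germline = 20L,
                       artifact_counts = c(end_biased = 6L, repeat_biased = 6L,
                                           low_quality_alt = 6L),
                       normal_contamination = 0,
                       n_background = 500L,
                       read_length = 100L,
                       expression = list(n_genes = 1000L,
                                         n_de_genes = 50L,
                                         log2_effect_size = log2(2.5),
                                         noise_sd = 0.25),
                       pathways = list(n_sets = 15L, set_size = 20L,
                                       planted_enriched = 3L)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  if (is.null(names(n_samples_per_group))) {
    names(n_samples_per_group) <- paste0("group", seq_along(n_samples_per_group))
  }
  counts <- c(n_chromosomes, chrom_length, n_genes, n_samples_per_group,
              n_somatic_per_sample, n_germline, artifact_counts,
              n_background, read_length)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all counts must be non-negative")
  }
  probs <- c(base_error_rate, normal_contamination)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (somatic_vaf <= 0 || somatic_vaf > 1) stop("somatic_vaf must lie in (0, 1]")
  if (somatic_vaf <= base_error_rate) {
    stop("somatic_vaf must exceed base_error_rate")
  }
  if (chrom_length < 1000) stop("chrom_length must be >= 1000")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (!is.null(expression$noise_sd) && expression$noise_sd <= 0) {
    stop("expression noise_sd must be positive")
  }
  required_artifacts <- c("end_biased", "repeat_biased", "low_quality_alt")
  if (!all(required_artifacts %in% names(artifact_counts))) {
    stop("artifact_counts must name: ", paste(required_artifacts, collapse = ", "))
  }
  # recycle per-group somatic counts against the group vector
  n_somatic_per_sample <- rep_len(as.integer(n_somatic_per_sample),
                                  length(n_samples_per_group))
  names(n_somatic_per_sample) <- names(n_samples_per_group)

  structure(list(
    seed = seed,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group) |>
      stats::setNames(names(n_samples_per_group)),
    depth_mean = depth_mean,
    base_error_rate = base_error_rate,
    somatic_vaf = somatic_vaf,
    n_somatic_per_sample = n_somatic_per_sample,
    n_germline = as.integer(n_germline),
    artifact_counts = as.integer(artifact_counts) |>
      stats::setNames(names(artifact_counts)),
    normal_contamination = normal_contamination,
    n_background = as.integer(n_background),
    read_length = as.integer(read_length),
    expression = expression,
    pathways = pathways
  ), class = "sim_config")
}

# Sub-seeds for the independent generator streams; kept below 2^31.
.sim_seed <- function(config, stream) {
  offsets <- c(genome = 11L, pileup = 23L, expression = 37L,
               genesets = 53L, indels = 71L)
  (config$seed %% 2000000000L) + offsets[[stream]]
}
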