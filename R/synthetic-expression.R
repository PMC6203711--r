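# Group-structured expression matrices with planted fold changes, and GMT
# gene-set collections with planted enrichment. Values are on the log2
# scale throughout (two-color log2 ratios, or log2-transformed abundances
# for the paired design), so a fold change is an additive shift.

#' Simulate a gene x sample expression matrix with planted DE genes
#'
#' Each value is gene baseline + group effect + Normal(0, noise_sd) noise.
#' The first group label is the case group (e.g. NASH); planted DE genes
#' receive `direction * log2_effect_size` there. With `paired = TRUE`
#' a tumor/adjacent-normal design is generated instead: `n_pairs` pairs
#' share a per-pair baseline shift and tumors of planted genes carry the
#' effect.
#'
#' @param config A [sim_config()]; `config$expression` supplies
#'   `n_de_genes`, `log2_effect_size`, `noise_sd`.
#' @param genes Gene ids (default `E0001 ...` up to
#'   `config$expression$n_genes`, a probe universe distinct from the toy
#'   genome's gene models).
#' @param paired Generate a paired tumor/normal design.
#' @param n_pairs Number of pairs for the paired design.
#' @param pair_sd SD of the per-pair baseline shift.
#' @return List: `matrix` (genes x samples), `groups` (named group labels,
#'   or tumor/normal for paired), `pairing` (named pair ids, paired only),
#'   `truth` data frame (gene, direction, log2fc).
#' @export
simulate_expression <- function(config, genes = NULL, paired = FALSE,
                                n_pairs = 17L, pair_sd = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  if (ex$noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(genes)) {
    n_univ <- config$expression$n_genes %||% config$n_genes
    genes <- sprintf("E%04d", seq_len(n_univ))
  }
  n_genes <- length(genes)
  n_de <- min(ex$n_de_genes, n_genes)

  withr::with_seed(.sim_seed(config, "expression"), {
    de_genes <- sample(genes, n_de)
    direction <- sample(c(1, -1), n_de, replace = TRUE)
    effect <- stats::setNames(rep(0, n_genes), genes)
    effect[de_genes] <- direction * ex$log2_effect_size
    baseline <- stats::setNames(stats::rnorm(n_genes, 0, 0.5), genes)

    if (paired) {
      if (n_pairs < 2) stop("paired design requires >= 2 pairs")
      pair_ids <- sprintf("P%02d", seq_len(n_pairs))
      samples <- c(paste0(pair_ids, "_T"), paste0(pair_ids, "_N"))
      groups <- stats::setNames(rep(c("tumor", "normal"), each = n_pairs),
                                samples)
      pairing <- stats::setNames(rep(pair_ids, 2L), samples)
      shift <- stats::rnorm(n_pairs, 0, pair_sd)
      m <- matrix(baseline, n_genes, 2L * n_pairs) +
        matrix(rep(shift, 2L), n_genes, 2L * n_pairs, byrow = TRUE) +
        stats::rnorm(n_genes * 2L * n_pairs, 0, ex$noise_sd)
      m[, seq_len(n_pairs)] <- m[, seq_len(n_pairs)] + effect
      dimnames(m) <- list(genes, samples)
      return(list(matrix = m, groups = groups, pairing = pairing,
                  truth = data.frame(gene = de_genes, direction = direction,
                                     log2fc = direction * ex$log2_effect_size,
                                     stringsAsFactors = FALSE)))
    }

    grp <- config$n_samples_per_group
    if (any(grp < 2)) stop("each group needs >= 2 samples")
    labels <- rep(names(grp), times = grp)
    samples <- unlist(lapply(names(grp), function(g) {
      sprintf("%s_%d", g, seq_len(grp[[g]]))
    }))
    groups <- stats::setNames(labels, samples)
    case <- names(grp)[1]  # first label (e.g. NASH) carries the planted effects
    is_case <- labels == case
    m <- matrix(baseline, n_genes, length(samples)) +
      outer(effect, as.numeric(is_case)) +
      stats::rnorm(n_genes * length(samples), 0, ex$noise_sd)
    dimnames(m) <- list(genes, samples)
    list(matrix = m, groups = groups, pairing = NULL, case_group = case,
         truth = data.frame(gene = de_genes, direction = direction,
                            log2fc = direction * ex$log2_effect_size,
                            stringsAsFactors = FALSE))
  })
}

#' Build a gene-set collection with planted enrichment
#'
#' The first `planted_enriched` sets draw about 70% of their members from
#' `special_genes` (e.g. the planted DE genes, or genes scheduled for
#' somatic mutation) and the rest from the other genes; remaining sets are
#' uniform draws from the whole universe.
#'
#' @param config A [sim_config()]; `config$pathways` supplies `n_sets`,
#'   `set_size`, `planted_enriched`.
#' @param genes Gene universe (character vector).
#' @param special_genes Genes to load the planted sets with.
#' @return List: `sets` (named list, GMT-serializable), `planted` (ids of
#'   the enriched sets).
#' @export
make_gene_sets <- function(config, genes, special_genes) {
  stopifnot(inherits(config, "sim_config"))
  pw <- config$pathways
  if (pw$set_size > length(genes)) stop("set_size exceeds the gene universe")
  special_genes <- intersect(special_genes, genes)
  withr::with_seed(.sim_seed(config, "genesets"), {
    ids <- sprintf("PW%03d", seq_len(pw$n_sets))
    planted <- ids[seq_len(min(pw$planted_enriched, pw$n_sets))]
    other <- setdiff(genes, special_genes)
    sets <- lapply(ids, function(id) {
      if (id %in% planted) {
        k <- min(ceiling(0.7 * pw$set_size), length(special_genes),
                 pw$set_size)
        filler <- if (length(other) >= pw$set_size - k) other else genes
        chosen <- sample(special_genes, k)
        c(chosen, sample(setdiff(filler, chosen), pw$set_size - k))
      } else {
        sample(genes, pw$set_size)
      }
    })
    names(sets) <- ids
    list(sets = sets, planted = planted)
  })
}
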