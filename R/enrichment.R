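# Hypergeometric over-representation analysis of gene lists against a
# gene-set collection, with BH adjustment across all tested sets and the
# minimum-overlap significance gates (>= 4 genes for expression queries,
# >= 3 for mutation queries), plus the multi-sample aggregation rule for
# per-sample mutation queries.

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' Every set is intersected with the universe before testing; query genes
#' outside the universe are dropped with a warning. BH adjustment spans all
#' sets in the collection (zero-overlap sets included in the family).
#' A set is significant iff adjusted p < `alpha` AND overlap >= `min_genes`.
#'
#' @param query Query gene ids.
#' @param collection Named list of gene sets.
#' @param universe Reference gene universe (e.g. all genes in the gene
#'   models).
#' @param min_genes Minimum overlap for significance (4 for expression
#'   queries, 3 for mutation queries).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Data frame: set id, overlap, set_size, query_size, universe_size,
#'   p, adj_p, significant, overlap_genes (comma-joined).
#' @export
enrich <- function(query, collection, universe, min_genes = 4L, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(id) {
    set <- intersect(unique(collection[[id]]), universe)
    ov <- intersect(set, query)
    p <- hypergeom_overrep(length(ov), length(set), n, N)$p_value
    data.frame(set = id, overlap = length(ov), set_size = length(set),
               query_size = n, universe_size = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$set), , drop = FALSE]  # independent of set iteration order
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha & out$overlap >= min_genes
  rownames(out) <- NULL
  out[, c("set", "overlap", "set_size", "query_size", "universe_size",
          "p", "adj_p", "significant", "overlap_genes")]
}

#' Aggregate per-sample mutation enrichment across a cohort
#'
#' Runs [enrich()] per sample with the mutation gate (`min_genes = 3`) and
#' reports pathways significant in at least `min_samples` samples.
#'
#' @param sample_gene_lists Named list: sample id -> mutated gene ids.
#' @param collection Named list of gene sets.
#' @param universe Gene universe.
#' @param min_genes Per-sample overlap gate (default 3).
#' @param alpha Adjusted-p threshold per sample (default 0.05).
#' @param min_samples Minimum number of samples in which a pathway must be
#'   significant (default 3).
#' @return List: `report` (data frame: set, n_significant, reported) and
#'   `per_sample` (sets x samples logical matrix of significance flags).
#' @export
per_sample_mutation_enrichment <- function(sample_gene_lists, collection,
                                           universe, min_genes = 3L,
                                           alpha = 0.05, min_samples = 3L) {
  sets <- names(collection)
  if (!length(sample_gene_lists)) {
    return(list(report = data.frame(set = character(),
                                    n_significant = integer(),
                                    reported = logical()),
                per_sample = matrix(FALSE, 0, 0)))
  }
  flags <- vapply(sample_gene_lists, function(genes) {
    res <- enrich(genes, collection, universe, min_genes = min_genes,
                  alpha = alpha)
    res$significant[match(sets, res$set)]
  }, logical(length(sets)))
  flags <- matrix(flags, nrow = length(sets),
                  dimnames = list(sets, names(sample_gene_lists)))
  n_sig <- rowSums(flags)
  report <- data.frame(set = sets, n_significant = as.integer(n_sig),
                       reported = n_sig >= min_samples,
                       stringsAsFactors = FALSE)
  list(report = report, per_sample = flags)
}
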