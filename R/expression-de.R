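# Differential expression on log2-scale matrices: gene-mean centering for
# display, two-group Welch testing with a fold-change gate, paired testing
# with BH false-discovery control, and correlation-based hierarchical
# clustering of samples.

#' Center each gene at its cross-sample mean
#'
#' Values are assumed to be on the log scale already; subtracting the gene
#' mean leaves per-sample deviations, the usual heat-map normalization.
#'
#' @param mat Gene x sample numeric matrix (>= 2 samples).
#' @return Matrix with all row means zero.
#' @export
normalize_to_gene_mean <- function(mat) {
  if (ncol(mat) < 2) stop("need >= 2 samples to center on the gene mean")
  sweep(mat, 1, rowMeans(mat))
}

#' Two-group differential expression with a fold-change gate
#'
#' Per-gene Welch t-test between the case and reference groups on log2
#' values. A gene is up if its mean log2 difference (case - reference) is
#' `>= log2(fold_min)` with `p < alpha`, down if `<= -log2(fold_min)` with
#' `p < alpha`; the fold bound is inclusive.
#'
#' @param mat Gene x sample log2 matrix.
#' @param groups Named group labels for the columns (two levels).
#' @param case Case group label (default: first label encountered).
#' @param fold_min Minimum fold change (default 2, i.e. |delta log2| >= 1).
#' @param alpha Raw p-value threshold (default 0.05).
#' @return List: `up`, `down` (gene ids) and `table` (gene, log2fc, p).
#' @export
de_genes <- function(mat, groups, case = NULL, fold_min = 2, alpha = 0.05) {
  groups <- groups[colnames(mat)]
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required")
  if (is.null(case)) case <- lv[1]
  ref <- setdiff(lv, case)
  ci <- which(groups == case)
  ri <- which(groups == ref)
  if (length(ci) < 2 || length(ri) < 2) stop("each group needs >= 2 samples")

  log2fc <- rowMeans(mat[, ci, drop = FALSE]) -
    rowMeans(mat[, ri, drop = FALSE])
  pvals <- vapply(seq_len(nrow(mat)), function(i) {
    t_test(mat[i, ci], mat[i, ri], welch = TRUE)$p_value
  }, numeric(1))
  tab <- data.frame(gene = rownames(mat), log2fc = log2fc, p = pvals,
                    row.names = NULL, stringsAsFactors = FALSE)
  cut <- log2(fold_min)
  list(
    up = tab$gene[tab$log2fc >= cut & tab$p < alpha],
    down = tab$gene[tab$log2fc <= -cut & tab$p < alpha],
    table = tab, case = case, reference = ref,
    method = "Welch t-test on log2 values"
  )
}

#' Paired tumor/normal differential expression with FDR control
#'
#' Per-gene paired t-test on tumor minus normal differences, BH adjustment
#' across genes; reported genes satisfy raw `p < alpha` and adjusted
#' `p <= fdr_max`.
#'
#' @param mat Gene x sample log2 matrix.
#' @param pairing Named pair ids per sample (a perfect tumor/normal
#'   matching).
#' @param groups Named labels per sample; `tumor_label` marks the tumor arm.
#' @param tumor_label Label of the tumor samples (default "tumor").
#' @param alpha Raw p threshold (default 0.05).
#' @param fdr_max Maximum BH-adjusted p (default 0.15).
#' @return List: `genes` (reported ids) and `table` (gene, mean_diff, p,
#'   fdr).
#' @export
paired_de <- function(mat, pairing, groups, tumor_label = "tumor",
                      alpha = 0.05, fdr_max = 0.15) {
  pairing <- pairing[colnames(mat)]
  groups <- groups[colnames(mat)]
  tum <- colnames(mat)[groups == tumor_label]
  nor <- colnames(mat)[groups != tumor_label]
  if (length(tum) != length(nor)) stop("integrity error: unbalanced pairing")
  if (length(tum) < 2) stop("need >= 2 pairs")
  nor <- nor[match(pairing[tum], pairing[nor])]
  if (anyNA(nor) || anyDuplicated(pairing[tum])) {
    stop("integrity error: pairing is not a perfect matching")
  }
  d <- mat[, tum, drop = FALSE] - mat[, nor, drop = FALSE]
  mean_diff <- rowMeans(d)
  pvals <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]
    if (stats::sd(x) == 0) {
      if (mean(x) == 0) 1 else 0
    } else {
      stats::t.test(x)$p.value
    }
  }, numeric(1))
  fdr <- bh_adjust(pvals)
  tab <- data.frame(gene = rownames(mat), mean_diff = mean_diff, p = pvals,
                    fdr = fdr, row.names = NULL, stringsAsFactors = FALSE)
  list(genes = tab$gene[tab$p < alpha & tab$fdr <= fdr_max], table = tab)
}

#' Unsupervised hierarchical clustering of samples
#'
#' Distance is 1 - Pearson correlation between sample profiles; average
#' linkage. Samples are ordered by id before clustering so the tree is
#' invariant to input column order (documented tie-break).
#'
#' @param mat Gene x sample matrix (>= 2 samples, no zero-variance sample).
#' @return List: `hclust` object and `leaf_order` (sample ids).
#' @export
hierarchical_cluster <- function(mat) {
  if (ncol(mat) < 2) stop("need >= 2 samples")
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate input: zero-variance sample ",
         colnames(mat)[which(sds == 0)[1]])
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, leaf_order = hc$labels[hc$order])
}
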