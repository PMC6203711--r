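# From PASS variants to annotated mutation records, recurrence matrices
# and cohort statistics: per-sample burden with group comparison, mutation
# frequencies, gene-list overlap, ortholog mapping and cohort frequency
# comparison.

.round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Classify the coding consequence of a SNV on the toy genome
#'
#' Finds the containing gene; SNVs inside a CDS block have their reference
#' and mutated codon translated on the coding strand (reverse-complemented
#' for minus-strand genes) and are classified as synonymous, missense,
#' stopgain or stoploss. Loci outside every CDS interval are noncoding.
#'
#' @param chrom,pos,ref,alt Variant locus and alleles (plus-strand bases).
#' @param models Gene-model data frame.
#' @param seqs Named chromosome-sequence vector (or `toy_genome$seqs`).
#' @return List: `gene` (or NA) and `consequence`.
#' @export
classify_consequence <- function(chrom, pos, ref, alt, models, seqs) {
  if (!chrom %in% names(seqs)) stop("unknown chromosome: ", chrom)
  if (pos < 1 || pos > nchar(seqs[[chrom]])) {
    stop("coordinate error: position ", pos, " beyond ", chrom)
  }
  hit <- models[models$chrom == chrom & models$start <= pos &
                  models$end >= pos, , drop = FALSE]
  if (!nrow(hit)) return(list(gene = NA_character_, consequence = "noncoding"))
  m <- hit[1, ]
  blocks <- parse_cds_blocks(m$cds_blocks)
  in_cds <- any(blocks[, "start"] <= pos & blocks[, "end"] >= pos)
  if (!in_cds) return(list(gene = m$gene_id, consequence = "noncoding"))

  cds_pos <- .cds_positions(m)
  offset <- match(pos, cds_pos)  # 1-based index in coding order
  codon_start <- offset - ((offset - 1L) %% 3L)
  codon_idx <- codon_start:(codon_start + 2L)
  codon_genomic <- cds_pos[codon_idx]
  ref_codon <- paste(.coding_base(seqs, chrom, codon_genomic, m$strand),
                     collapse = "")
  alt_coding <- if (m$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  within <- which(codon_genomic == pos)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_coding

  ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  consequence <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stopgain"
  else if (ref_aa == "*") "stoploss"
  else "missense"
  list(gene = m$gene_id, consequence = consequence)
}

#' Annotate PASS variant records with gene and consequence
#'
#' @param records Variant-record data frame (chrom, pos, ref, alt, sample).
#' @param genome A `toy_genome` (or list with `seqs` and `models`).
#' @return `records` with `gene` and `consequence` columns appended.
#' @export
annotate_variants <- function(records, genome) {
  seqs <- genome$seqs
  models <- genome$models
  if (!nrow(records)) {
    records$gene <- character(0)
    records$consequence <- character(0)
    return(records)
  }
  ann <- lapply(seq_len(nrow(records)), function(i) {
    classify_consequence(records$chrom[i], records$pos[i], records$ref[i],
                         records$alt[i], models, seqs)
  })
  records$gene <- vapply(ann, function(a) a$gene %||% NA_character_, character(1))
  records$consequence <- vapply(ann, `[[`, character(1), "consequence")
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

NONSYNONYMOUS <- c("missense", "stopgain", "stoploss")

#' Build a gene x sample binary recurrence matrix
#'
#' An entry is 1 iff at least one qualifying record exists for that
#' (gene, sample); by default only non-synonymous records qualify.
#'
#' @param records Annotated mutation records (sample, gene, consequence).
#' @param samples Sample universe for the columns (default: samples seen).
#' @param groups Optional named group labels per sample.
#' @param nonsyn_only Restrict to missense/stopgain/stoploss records.
#' @return A `recurrence_matrix`: `matrix` (0/1), `groups`.
#' @export
build_recurrence <- function(records, samples = NULL, groups = NULL,
                             nonsyn_only = TRUE) {
  if (nonsyn_only) {
    records <- records[records$consequence %in% NONSYNONYMOUS, , drop = FALSE]
  }
  records <- records[!is.na(records$gene), , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(records$sample))
  genes <- sort(unique(records$gene))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(records)) {
    m[cbind(match(records$gene, genes), match(records$sample, samples))] <- 1L
  }
  structure(list(matrix = m, groups = groups), class = "recurrence_matrix")
}

#' Recurrently mutated genes (mutated in >= min_samples samples)
#'
#' @param rec A `recurrence_matrix`.
#' @param min_samples Recurrence threshold (default 2).
#' @param group Restrict to samples of one group label.
#' @return Character vector of recurrent gene ids.
#' @export
recurrent_genes <- function(rec, min_samples = 2L, group = NULL) {
  m <- rec$matrix
  if (!is.null(group)) {
    if (is.null(rec$groups)) stop("recurrence matrix has no group labels")
    m <- m[, names(rec$groups)[rec$groups == group], drop = FALSE]
  }
  rownames(m)[rowSums(m) >= min_samples]
}

#' Mutation frequency of a gene within a cohort
#'
#' @param gene Gene id (must be a matrix row).
#' @param rec A `recurrence_matrix`.
#' @param group Optional group restriction.
#' @return List: `count`, `n`, `fraction`, `percent` (half-up, one decimal).
#' @export
mutation_frequency <- function(gene, rec, group = NULL) {
  m <- rec$matrix
  if (!gene %in% rownames(m)) stop("lookup error: unknown gene ", gene)
  if (!is.null(group)) {
    if (is.null(rec$groups)) stop("recurrence matrix has no group labels")
    m <- m[, names(rec$groups)[rec$groups == group], drop = FALSE]
  }
  k <- sum(m[gene, ])
  n <- ncol(m)
  list(count = k, n = n, fraction = k / n,
       percent = .round_half_up(100 * k / n, 1))
}

#' Compare per-sample mutation burden between two groups
#'
#' Reports per-group mean and SD, the fold ratio of the larger over the
#' smaller mean (one decimal, half-up), and a Welch t-test. Supply either
#' per-sample counts + group labels, or two `c(mean, sd, n)` summaries.
#'
#' @param counts Per-sample burden counts (e.g. mutated gene numbers).
#' @param groups Group label per count (exactly two levels).
#' @param summary1,summary2 Alternative `c(mean, sd, n)` summaries.
#' @param welch Welch t-test (default) or pooled.
#' @return List: `means`, `sds`, `ns`, `fold`, `test` (a `test_result`).
#' @export
burden_compare <- function(counts = NULL, groups = NULL,
                           summary1 = NULL, summary2 = NULL, welch = TRUE) {
  if (!is.null(summary1)) {
    test <- t_test(summary1 = summary1, summary2 = summary2, welch = welch)
    means <- c(summary1[1], summary2[1])
    sds <- c(summary1[2], summary2[2])
    ns <- c(summary1[3], summary2[3])
  } else {
    lv <- unique(groups)
    if (length(lv) != 2) stop("exactly two groups are required")
    x <- counts[groups == lv[1]]
    y <- counts[groups == lv[2]]
    if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 samples")
    means <- c(mean(x), mean(y))
    sds <- c(stats::sd(x), stats::sd(y))
    ns <- c(length(x), length(y))
    names(means) <- names(sds) <- names(ns) <- lv
    test <- t_test(x, y, welch = welch)
  }
  fold <- .round_half_up(max(means) / min(means), 1)
  list(means = means, sds = sds, ns = ns, fold = fold, test = test)
}

#' Overlap between two gene lists
#' @param list1,list2 Character vectors of gene symbols.
#' @return Size of the set intersection.
#' @export
overlap_count <- function(list1, list2) {
  length(intersect(unique(list1), unique(list2)))
}

#' Map gene symbols through a many-to-one ortholog map
#'
#' Preserves input order, drops unmapped symbols and deduplicates targets
#' (two source genes mapping to one ortholog yield a single entry).
#'
#' @param genes Source symbols.
#' @param map Named vector from [read_ortholog_map()].
#' @return Mapped target symbols.
#' @export
map_orthologs <- function(genes, map) {
  mapped <- map[genes]
  unique(unname(mapped[!is.na(mapped)]))
}

#' Compare mutation frequencies between two cohorts (chi-square)
#'
#' @param k1,n1 Mutated / total in cohort 1.
#' @param k2,n2 Mutated / total in cohort 2.
#' @param continuity Yates correction.
#' @return A `test_result` from [chi_square_2x2()].
#' @export
frequency_compare <- function(k1, n1, k2, n2, continuity = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop("cohort sizes must be positive")
  if (k1 > n1 || k2 > n2) stop("mutated count cannot exceed cohort size")
  chi_square_2x2(k1, k2, n1 - k1, n2 - k2, continuity = continuity)
}
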