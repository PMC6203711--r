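# Toy genome and gene models. Chromosomes are uniform random A/C/G/T;
# gene models are non-overlapping, stranded, with CDS blocks whose
# concatenation (coding strand) starts with ATG, contains no internal stop
# codon, and ends with a stop codon -- so consequence classification is
# well defined at every coding position.

.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) {
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

.all_codons <- function() {
  g <- expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE)
  paste0(g[[1]], g[[2]], g[[3]])
}

# random coding sequence of n_codons codons incl. leading ATG and final stop
.random_cds <- function(n_codons) {
  sense <- setdiff(.all_codons(), .STOP_CODONS)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(.STOP_CODONS, 1L)), collapse = "")
}

#' Generate a toy genome with non-overlapping gene models
#'
#' Each gene has one or two CDS blocks (a short intron separates two
#' blocks); CDS total length is a multiple of 3, begins with ATG on the
#' coding strand, carries no internal stop codon and ends with a stop.
#' Genes are assigned round-robin to chromosomes and placed left to right
#' with random spacing. Identical seed and configuration reproduce the
#' genome byte for byte.
#'
#' @param config A [sim_config()].
#' @return A `toy_genome`: `seqs` (named chromosome sequences) and `models`
#'   (data frame: gene_id, chrom, start, end, strand, cds_blocks).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(.sim_seed(config, "genome"), {
    seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
      paste(sample(.BASES, config$chrom_length, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))

    n <- config$n_genes
    gene_ids <- sprintf("G%04d", seq_len(n))
    chrom_of <- rep(names(seqs), length.out = n)
    models <- vector("list", n)
    cursor <- stats::setNames(rep(1L, length(seqs)), names(seqs))

    for (i in seq_len(n)) {
      chrom <- chrom_of[i]
      n_codons <- sample(40:80, 1L)
      cds <- .random_cds(n_codons)
      cds_len <- nchar(cds)
      strand <- sample(c("+", "-"), 1L)
      two_blocks <- stats::runif(1) < 0.5
      intron <- if (two_blocks) sample(20:80, 1L) else 0L
      footprint <- cds_len + intron
      gap <- sample(60:200, 1L)
      start <- cursor[[chrom]] + gap
      end <- start + footprint - 1L
      if (end > config$chrom_length - 50L) {
        stop("sizing error: gene models do not fit in the genome; ",
             "increase chrom_length or n_chromosomes, or reduce n_genes")
      }
      genomic <- if (strand == "+") cds else .revcomp(cds)
      if (two_blocks) {
        # split the coding sequence; genomic layout keeps coding order on
        # the coding strand (for '-', the later coding part sits leftmost)
        split_at <- sample(seq(3L, cds_len - 3L), 1L)
        c1 <- substr(cds, 1L, split_at)
        c2 <- substr(cds, split_at + 1L, cds_len)
        if (strand == "+") {
          left <- c1; right <- c2
        } else {
          left <- .revcomp(c2); right <- .revcomp(c1)
        }
        w1 <- nchar(left)
        intron_seq <- paste(sample(.BASES, intron, replace = TRUE),
                            collapse = "")
        genomic <- paste0(left, intron_seq, right)
        b1 <- c(start, start + w1 - 1L)
        b2 <- c(start + w1 + intron, end)
        blocks <- sprintf("%d-%d,%d-%d", b1[1], b1[2], b2[1], b2[2])
      } else {
        blocks <- sprintf("%d-%d", start, end)
      }
      substr(seqs[[chrom]], start, end) <- genomic
      cursor[[chrom]] <- end + 1L
      models[[i]] <- data.frame(
        gene_id = gene_ids[i], chrom = chrom, start = start, end = end,
        strand = strand, cds_blocks = blocks, stringsAsFactors = FALSE
      )
    }
    models <- do.call(rbind, models)
    structure(list(seqs = seqs, models = models), class = "toy_genome")
  })
}

#' Parse a cds_blocks string into a start/end matrix (genomic order)
#' @param blocks `"s1-e1,s2-e2"` string.
#' @return Integer matrix with columns start, end.
#' @export
parse_cds_blocks <- function(blocks) {
  parts <- strsplit(strsplit(blocks, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  colnames(m) <- c("start", "end")
  m
}

#' Extract the coding-strand CDS sequence of one gene model
#' @param genome A `toy_genome` or named chromosome-sequence vector.
#' @param model One-row gene-model data frame.
#' @return Character CDS sequence (5'->3' on the coding strand).
#' @export
extract_cds <- function(genome, model) {
  seqs <- if (inherits(genome, "toy_genome")) genome$seqs else genome
  blocks <- parse_cds_blocks(model$cds_blocks)
  pieces <- apply(blocks, 1, function(b) substr(seqs[[model$chrom]], b[1], b[2]))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") .revcomp(s) else s
}

#' Translate a coding sequence with the standard genetic code
#' @param cds Character DNA sequence (length a multiple of 3).
#' @return Amino-acid string (stop = `*`).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# genomic positions of a gene's CDS in coding order (5'->3' on coding strand)
.cds_positions <- function(model) {
  blocks <- parse_cds_blocks(model$cds_blocks)
  pos <- unlist(lapply(seq_len(nrow(blocks)),
                       function(i) seq(blocks[i, 1], blocks[i, 2])))
  if (model$strand == "-") rev(pos) else pos
}

# base at genomic positions, as coding-strand bases for the given strand
.coding_base <- function(seqs, chrom, pos, strand) {
  b <- substring(seqs[[chrom]], pos, pos)
  if (strand == "-") chartr("ACGT", "TGCA", b) else b
}
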