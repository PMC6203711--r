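# On-disk formats: genome FASTA, BED-like gene-model TSV, read-observation
# pileup TSV, VCF v4.2, GMT gene sets, numeric matrix TSV, ortholog map and
# known-sites TSV. Readers validate strictly and report offending lines;
# writers and readers round-trip.

PILEUP_COLUMNS <- c("sample", "chrom", "pos", "ref", "base", "base_quality",
                    "mapping_quality", "repeat_flag", "dist_5prime",
                    "dist_3prime", "strand")

#' Write a genome to FASTA
#'
#' @param genome A `toy_genome` (see [make_genome()]) or a named character
#'   vector of chromosome sequences.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "toy_genome")) genome$seqs else genome
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write/read gene models (BED-like TSV, 1-based inclusive)
#'
#' Columns: chrom, start, end, strand, gene_id, cds_blocks
#' (comma-separated `start-end` pairs in genomic order).
#' @param models Gene-model data frame.
#' @param path TSV path.
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(
    models[, c("chrom", "start", "end", "strand", "gene_id", "cds_blocks")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "strand", "gene_id", "cds_blocks")
  if (!all(needed %in% names(df))) {
    stop("gene-model file lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene-model file")
  df
}

#' Write read observations to a pileup TSV
#' @param pileup Data frame with the pileup columns (one row per read
#'   observation at a site).
#' @param path TSV path.
#' @export
write_pileups <- function(pileup, path) {
  stopifnot(all(PILEUP_COLUMNS %in% names(pileup)))
  utils::write.table(pileup[, PILEUP_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a pileup TSV
#'
#' One row per read observation: sample, chrom, pos (1-based), ref, base,
#' base_quality, mapping_quality, repeat_flag, dist_5prime, dist_3prime,
#' strand. Rows with bases outside A/C/G/T or negative qualities are
#' rejected with their line number. When a sample-pair `manifest` is given
#' (columns pair_id, tumor, normal), every sample must appear in it.
#'
#' @param path Pileup TSV path.
#' @param manifest Optional pair manifest data frame.
#' @return The validated data frame (attribute `manifest` attached if given).
#' @export
read_pileups <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(PILEUP_COLUMNS, names(df))
  if (length(missing)) {
    stop("pileup file lacks columns: ", paste(missing, collapse = ", "))
  }
  bad_base <- which(!(df$base %in% c("A", "C", "G", "T")) |
                      !(df$ref %in% c("A", "C", "G", "T")))
  if (length(bad_base)) {
    stop(sprintf("invalid base at line %d of %s (header is line 1): '%s'",
                 bad_base[1] + 1L, path, df$base[bad_base[1]]))
  }
  bad_q <- which(df$base_quality < 0 | df$mapping_quality < 0 |
                   df$dist_5prime < 0 | df$dist_3prime < 0)
  if (length(bad_q)) {
    stop(sprintf("negative quality or distance at line %d of %s",
                 bad_q[1] + 1L, path))
  }
  if (any(df$pos < 1)) stop("positions must be >= 1")
  if (!is.null(manifest)) {
    known <- c(manifest$tumor, manifest$normal)
    orphan <- setdiff(unique(df$sample), known)
    if (length(orphan)) {
      stop("pairing error: sample(s) not in manifest: ",
           paste(orphan, collapse = ", "))
    }
    mates <- stats::setNames(c(manifest$normal, manifest$tumor),
                             c(manifest$tumor, manifest$normal))
    present <- unique(df$sample)
    unmated <- present[!(mates[present] %in% present)]
    if (length(unmated)) {
      stop("pairing error: missing mate for sample(s): ",
           paste(unmated, collapse = ", "))
    }
    attr(df, "manifest") <- manifest
  }
  df
}

#' Group a pileup into paired tumor/normal site records
#'
#' @param pileup Pileup data frame.
#' @param manifest Pair manifest (pair_id, tumor, normal).
#' @return List of site records: `pair_id`, `chrom`, `pos`, `ref`, and the
#'   `tumor` / `normal` read-observation frames.
#' @export
pair_sites <- function(pileup, manifest) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    t_id <- manifest$tumor[i]
    n_id <- manifest$normal[i]
    sub <- pileup[pileup$sample %in% c(t_id, n_id), , drop = FALSE]
    if (!nrow(sub)) next
    key <- factor(paste(sub$chrom, sub$pos, sep = ":"),
                  levels = unique(paste(sub$chrom, sub$pos, sep = ":")))
    chunks <- split(sub, key)
    pair_id <- manifest$pair_id[i]
    out <- c(out, lapply(chunks, function(rows) {
      list(
        pair_id = pair_id,
        chrom = rows$chrom[1],
        pos = rows$pos[1],
        ref = rows$ref[1],
        tumor = rows[rows$sample == t_id, , drop = FALSE],
        normal = rows[rows$sample == n_id, , drop = FALSE]
      )
    }))
  }
  out
}

# ---- VCF ----------------------------------------------------------------

.vcf_info_type <- function(x) {
  if (is.integer(x)) "Integer" else if (is.numeric(x)) "Float" else "String"
}

#' Write variant records to a VCF v4.2 file
#'
#' `records` must carry chrom, pos, ref, alt, filter; every other column
#' becomes an INFO key (numeric columns as Float with 4 significant digits,
#' integer as Integer, character as String). FILTER definitions for every
#' named filter are emitted in the header. Records are sorted by
#' (chrom, pos); duplicate (chrom, pos, sample, alt) rows are an error.
#'
#' @param records Data frame of variant records (may have zero rows).
#' @param path Output path.
#' @param filter_defs Named character vector: filter id -> description.
#'   Defaults to ids found in the `filter` column.
#' @return The path, invisibly.
#' @export
write_vcf <- function(records, path, filter_defs = NULL) {
  required <- c("chrom", "pos", "ref", "alt", "filter")
  if (!all(required %in% names(records))) {
    stop("records must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(records)) {
    if (any(!nzchar(records$filter))) stop("empty filter status")
    key_cols <- intersect(c("chrom", "pos", "sample", "alt"), names(records))
    key <- do.call(paste, c(records[key_cols], sep = "\r"))
    if (anyDuplicated(key)) {
      stop("integrity error: duplicate (chrom, pos, sample, alt) record")
    }
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
  }
  used_filters <- setdiff(unique(unlist(strsplit(records$filter, ";"))), "PASS")
  if (is.null(filter_defs)) {
    filter_defs <- stats::setNames(rep("cascade filter", length(used_filters)),
                                   used_filters)
  } else {
    missing <- setdiff(used_filters, names(filter_defs))
    if (length(missing)) {
      stop("filter ids used but not defined: ", paste(missing, collapse = ", "))
    }
  }
  info_cols <- setdiff(names(records), c(required, "id", "qual"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nashhcc",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">",
            names(filter_defs), unname(filter_defs)),
    vapply(info_cols, function(col) {
      sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
              toupper(col), .vcf_info_type(records[[col]]), col)
    }, character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- header
  if (nrow(records)) {
    info <- vapply(seq_len(nrow(records)), function(i) {
      parts <- vapply(info_cols, function(col) {
        v <- records[[col]][i]
        if (is.na(v)) return(NA_character_)
        val <- if (is.double(v)) signif(v, 4) else v
        paste0(toupper(col), "=", format(val, scientific = FALSE, trim = TRUE))
      }, character(1))
      parts <- parts[!is.na(parts)]
      if (length(parts)) paste(parts, collapse = ";") else "."
    }, character(1))
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
      records$chrom, as.integer(records$pos), records$ref, records$alt,
      records$filter, info
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Syntactic validation of a VCF written by this package
#'
#' Checks the fileformat line, that every FILTER id and INFO key used in the
#' body is defined in the header, and that data lines have 8 columns.
#'
#' @param path VCF path.
#' @return TRUE invisibly, or an error describing the violation.
#' @export
validate_vcf <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "##fileformat=VCF")) stop("missing fileformat line")
  header <- lines[startsWith(lines, "##")]
  filt_def <- sub("^##FILTER=<ID=([^,]+),.*$", "\\1",
                  header[startsWith(header, "##FILTER=")])
  info_def <- sub("^##INFO=<ID=([^,]+),.*$", "\\1",
                  header[startsWith(header, "##INFO=")])
  body <- lines[!startsWith(lines, "#")]
  for (ln in body) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 8) stop("data line does not have 8 columns: ", ln)
    filters <- setdiff(strsplit(fields[7], ";")[[1]], c("PASS", "."))
    undef <- setdiff(filters, filt_def)
    if (length(undef)) stop("undefined FILTER id: ", paste(undef, collapse = ", "))
    if (fields[8] != ".") {
      keys <- sub("=.*$", "", strsplit(fields[8], ";")[[1]])
      undef <- setdiff(keys, info_def)
      if (length(undef)) stop("undefined INFO key: ", paste(undef, collapse = ", "))
    }
  }
  invisible(TRUE)
}

# ---- Gene sets, matrices, maps ------------------------------------------

#' Write a gene-set collection to GMT
#' @param sets Named list of character vectors (gene ids).
#' @param path GMT path.
#' @param descriptions Optional named descriptions (default "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#' @param path GMT path.
#' @return Named list of character vectors; duplicate set ids are an error.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) stop("GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("integrity error: duplicate set id ", ids[duplicated(ids)][1])
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  sets
}

#' Read a numeric gene x sample matrix from TSV
#'
#' First column = gene ids (unique), header = sample ids. Any non-numeric
#' cell is reported with its (gene, sample) coordinates.
#' @param path TSV path.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("integrity error: duplicate gene row ",
                                 genes[duplicated(genes)][1])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) & !is.na(vals[[j]]))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                   genes[bad[1]], names(vals)[j], vals[[j]][bad[1]]))
    }
    if (anyNA(col)) {
      stop(sprintf("missing value at gene '%s', sample '%s'",
                   genes[which(is.na(col))[1]], names(vals)[j]))
    }
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' Write a numeric matrix to TSV (gene ids in the first column)
#' @param mat Numeric matrix with row and column names.
#' @param path TSV path.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column ortholog map (many-to-one, e.g. mouse -> human)
#'
#' Duplicate source symbols mapping to conflicting targets are an integrity
#' error; exact duplicate rows are collapsed.
#' @param path TSV with columns `from`, `to` (header required).
#' @return Named character vector: from -> to.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  names(df)[1:2] <- c("from", "to")
  df <- unique(df[, 1:2])
  if (anyDuplicated(df$from)) {
    stop("integrity error: conflicting mapping for ",
         df$from[duplicated(df$from)][1])
  }
  stats::setNames(df$to, df$from)
}

#' Read a known-variant-sites list (chrom, pos, ref, alt)
#' @param path TSV path with header.
#' @return A `known_sites` object supporting [locus_in_known_sites()].
#' @export
read_known_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(df))) {
    stop("known-sites file lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  keys <- paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  structure(list(keys = unique(keys), table = df), class = "known_sites")
}

#' Exact-locus membership in a known-sites set
#' @param known A `known_sites` object (or NULL for an empty set).
#' @param chrom,pos,ref,alt Locus to test.
#' @export
locus_in_known_sites <- function(known, chrom, pos, ref, alt) {
  if (is.null(known)) return(rep(FALSE, length(pos)))
  paste(chrom, pos, ref, alt, sep = "\r") %in% known$keys
}

#' Build an empty or in-memory known-sites set
#' @param df Data frame with chrom, pos, ref, alt (default empty).
#' @export
known_sites <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(chrom = character(), pos = integer(),
                     ref = character(), alt = character())
  }
  structure(list(keys = unique(paste(df$chrom, df$pos, df$ref, df$alt,
                                     sep = "\r")),
                 table = df),
            class = "known_sites")
}
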