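# Readers and writers for every external format the pipeline touches.
# All identifiers are whitespace-stripped but case-sensitive.  Readers never
# silently drop rows: every filter lives in a named downstream operation.

# Sample table ---------------------------------------------------------------

#' Read a sample table
#'
#' A sample table maps sequencing samples to tissues.  Expected TSV columns:
#' \code{sample_id}, \code{tissue}, \code{replicate}.
#'
#' @param path Path to a tab-separated file.
#' @return A \code{data.frame} with columns \code{sample_id}, \code{tissue},
#'   \code{replicate}; sample ids are unique and every tissue has at least one
#'   sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "tissue", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("sample table %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  df$sample_id <- .strip(df$sample_id)
  df$tissue <- .strip(df$tissue)
  df$replicate <- as.integer(df$replicate)
  validate_sample_table(df[need])
}

#' Validate a sample table
#'
#' @param df A data.frame with \code{sample_id}, \code{tissue},
#'   \code{replicate}.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_sample_table <- function(df) {
  if (anyDuplicated(df$sample_id))
    .stopf("duplicated sample_id(s): %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]),
                 collapse = ", "))
  if (any(is.na(df$replicate)) || any(df$replicate < 1))
    .stopf("replicate must be a positive integer")
  if (any(!nzchar(df$tissue)))
    .stopf("empty tissue label in sample table")
  df
}

#' Write a sample table
#' @param df Sample table data.frame.
#' @param path Output TSV path.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Gene annotation ------------------------------------------------------------

#' Read a gene annotation table
#'
#' Expected TSV columns: \code{gene_id}, \code{gene_name}, \code{biotype}
#' (e.g. \code{protein_coding}, \code{lncRNA}).
#'
#' @param path Path to a tab-separated file.
#' @return data.frame with unique \code{gene_id}.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "gene_name", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("gene annotation %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  df$gene_id <- .strip(df$gene_id)
  df$gene_name <- .strip(df$gene_name)
  df$biotype <- .strip(df$biotype)
  if (anyDuplicated(df$gene_id))
    .stopf("duplicated gene_id(s) in annotation: %s",
           paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df[need]
}

# Feature annotation ---------------------------------------------------------

#' Read a gene to protein-feature annotation table
#'
#' Long-format TSV with columns \code{gene_id} and \code{feature} (one row
#' per gene/feature pair); a gene may carry zero features (absent from the
#' table).
#'
#' @param path Path to a tab-separated file.
#' @param vocabulary Optional character vector; when given, any feature tag
#'   outside it is a fatal error (controlled vocabulary).
#' @return data.frame with columns \code{gene_id}, \code{feature}.
#' @export
read_feature_table <- function(path, vocabulary = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "feature")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("feature table %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  df$gene_id <- .strip(df$gene_id)
  df$feature <- .strip(df$feature)
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(df$feature), vocabulary)
    if (length(bad))
      .stopf("feature tag(s) outside controlled vocabulary: %s",
             paste(bad, collapse = ", "))
  }
  unique(df[need])
}

#' Write a feature annotation table
#' @param df data.frame with \code{gene_id}, \code{feature}.
#' @param path Output TSV path.
#' @export
write_feature_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Expression matrix ----------------------------------------------------------

#' Construct an ExpressionMatrix
#'
#' The substrate of the bulk pipeline: a genes x samples matrix of
#' non-negative FPKM values, a sample table mapping samples to tissues and an
#' optional gene annotation.
#'
#' @param values Numeric matrix, rows = genes, columns = samples, with
#'   dimnames set.
#' @param sample_table Sample table data.frame (see
#'   \code{\link{read_sample_table}}).
#' @param annotation Optional gene annotation data.frame.
#' @return An object of class \code{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, sample_table, annotation = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("values must carry gene and sample dimnames")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicated gene_id(s): %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]),
                 collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    .stopf("negative or non-finite value at gene '%s', sample '%s'",
           rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  sample_table <- validate_sample_table(sample_table)
  extra <- setdiff(colnames(values), sample_table$sample_id)
  if (length(extra))
    .stopf("sample(s) absent from sample table: %s",
           paste(extra, collapse = ", "))
  missing_s <- setdiff(sample_table$sample_id, colnames(values))
  if (length(missing_s))
    .stopf("sample(s) in sample table missing from matrix: %s",
           paste(missing_s, collapse = ", "))
  # order sample_table to match the matrix columns
  sample_table <- sample_table[match(colnames(values),
                                     sample_table$sample_id), , drop = FALSE]
  rownames(sample_table) <- NULL
  if (!is.null(annotation)) {
    miss_a <- setdiff(rownames(values), annotation$gene_id)
    if (length(miss_a))
      .stopf("gene(s) missing from annotation: %s",
             paste(utils::head(miss_a, 5), collapse = ", "))
    annotation <- annotation[match(rownames(values), annotation$gene_id), ,
                             drop = FALSE]
    rownames(annotation) <- NULL
  }
  structure(list(values = values, sample_table = sample_table,
                 annotation = annotation),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tissues)%s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_table$tissue)),
              if (is.null(x$annotation)) "" else ", annotated"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene and/or sample
#' @param x ExpressionMatrix.
#' @param genes,samples Character vectors (or indices) to keep; \code{NULL}
#'   keeps all.
#' @return ExpressionMatrix.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  ann <- x$annotation
  if (!is.null(genes)) {
    v <- v[genes, , drop = FALSE]
    if (!is.null(ann))
      ann <- ann[match(rownames(v), ann$gene_id), , drop = FALSE]
  }
  st <- x$sample_table
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    st <- st[match(colnames(v), st$sample_id), , drop = FALSE]
  }
  ExpressionMatrix(v, st, ann)
}

#' Read an expression matrix from TSV
#'
#' The TSV carries a header row of sample ids and a first column
#' \code{gene_id}; body values are numeric FPKM.
#'
#' @param path Path to the TSV.
#' @param sample_table Sample table data.frame; every matrix column must be
#'   declared here and vice versa.
#' @param annotation Optional gene annotation data.frame.
#' @return ExpressionMatrix.
#' @export
read_expression_matrix <- function(path, sample_table, annotation = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    .stopf("first column of %s must be 'gene_id', found '%s'",
           path, names(df)[1])
  gene_id <- .strip(df$gene_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    .stopf("non-numeric expression values in %s", path)
  rownames(m) <- gene_id
  colnames(m) <- .strip(colnames(m))
  ExpressionMatrix(m, sample_table, annotation)
}

#' Write an expression matrix to TSV
#' @param x ExpressionMatrix (or plain matrix with dimnames).
#' @param path Output TSV path.
#' @export
write_expression_matrix <- function(x, path) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# FASTA ----------------------------------------------------------------------

#' Read protein FASTA
#'
#' Sequences are uppercased and validated against the 20 standard amino
#' acids plus \code{X} and the gap character \code{-}.  The \code{.} gap
#' dialect is deliberately rejected rather than auto-converted.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- .strip(vapply(strsplit(names(set), "\\s+"), `[`, "", 1))
  .check_aa(seqs, what = "sequence")
  seqs
}

#' Read an aligned protein FASTA
#'
#' @param path FASTA path; all records must have equal length.
#' @return A \code{ProteinAlignment}.
#' @export
read_aligned_fasta <- function(path) {
  seqs <- read_fasta(path)
  ProteinAlignment(seqs)
}

#' Construct a ProteinAlignment
#'
#' Equal-length gapped protein sequences, the substrate for pairwise
#' identity and column conservation.
#'
#' @param seqs Named character vector of equal-length gapped sequences.
#' @return Object of class \code{ProteinAlignment} with fields \code{ids},
#'   \code{seqs}, \code{width}.
#' @export
ProteinAlignment <- function(seqs) {
  if (!length(seqs)) .stopf("empty alignment")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    .stopf("aligned sequences have unequal lengths: %s",
           paste(sort(w), collapse = ", "))
  .check_aa(seqs, what = "aligned sequence")
  structure(list(ids = names(seqs), seqs = unname(seqs), width = w),
            class = "ProteinAlignment")
}

#' @export
print.ProteinAlignment <- function(x, ...) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns\n",
              length(x$seqs), x$width))
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, cols = columns)
#' @param x ProteinAlignment.
#' @param ... Unused.
#' @return Character matrix.
#' @export
as.matrix.ProteinAlignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Write sequences to FASTA
#' @param seqs Named character vector or ProteinAlignment.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "ProteinAlignment"))
    seqs <- stats::setNames(seqs$seqs, seqs$ids)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Ortholog table -------------------------------------------------------------

#' Read an orthologue table
#'
#' Compara/BioMart-style TSV with columns \code{source_gene},
#' \code{species}, \code{target_gene}, \code{orthology_type},
#' \code{percent_identity}.  Rows with a blank \code{target_gene} are
#' retained and flagged \code{detected = FALSE} ("no orthologue detected");
#' their identity is missing.
#'
#' @param path Path to the TSV.
#' @return data.frame with an added logical column \code{detected}.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  need <- c("source_gene", "species", "target_gene", "orthology_type",
            "percent_identity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("ortholog table %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  df$source_gene <- .strip(df$source_gene)
  df$species <- .strip(df$species)
  df$target_gene <- ifelse(is.na(df$target_gene), NA_character_,
                           .strip(df$target_gene))
  df$target_gene[!is.na(df$target_gene) & !nzchar(df$target_gene)] <-
    NA_character_
  df$percent_identity <- as.numeric(df$percent_identity)
  df$detected <- !is.na(df$target_gene)
  bad <- which(df$detected & (is.na(df$percent_identity) |
                              df$percent_identity < 0 |
                              df$percent_identity > 100))
  if (length(bad))
    .stopf("percent_identity outside [0,100] at row %d (gene %s)",
           bad[1], df$source_gene[bad[1]])
  df$percent_identity[!df$detected] <- NA_real_
  df[c(need, "detected")]
}

# Cell matrix ----------------------------------------------------------------

#' Construct a CellMatrix
#'
#' Cells x genes integer counts with per-cell metadata (cell type label,
#' detected-feature count, percent mitochondrial content) and an optional
#' stage tag.
#'
#' @param counts Matrix-like (dense or \code{Matrix} sparse), rows = cells,
#'   columns = genes; non-negative integers.
#' @param cell_data data.frame with columns \code{cell_id},
#'   \code{cell_type}, \code{n_features}, \code{percent_mito}.
#' @param gene_ids Character vector of gene ids (defaults to
#'   \code{colnames(counts)}).
#' @param stage Optional stage tag (e.g. \code{"P14"}, \code{"adult"}).
#' @return Object of class \code{CellMatrix}.
#' @export
CellMatrix <- function(counts, cell_data, gene_ids = colnames(counts),
                       stage = NULL) {
  if (is.null(gene_ids)) .stopf("gene ids are required")
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else counts
  if (any(vals < 0)) .stopf("negative count")
  if (any(vals != round(vals))) .stopf("non-integer count")
  need <- c("cell_id", "cell_type", "n_features", "percent_mito")
  miss <- setdiff(need, names(cell_data))
  if (length(miss))
    .stopf("cell data lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(cell_data) != nrow(counts))
    .stopf("cell metadata rows (%d) do not match matrix rows (%d)",
           nrow(cell_data), nrow(counts))
  if (length(gene_ids) != ncol(counts))
    .stopf("gene ids (%d) do not match matrix columns (%d)",
           length(gene_ids), ncol(counts))
  if (any(!nzchar(cell_data$cell_type) | is.na(cell_data$cell_type)))
    .stopf("empty cell_type label")
  rownames(counts) <- cell_data$cell_id
  colnames(counts) <- gene_ids
  rownames(cell_data) <- NULL
  structure(list(counts = counts, cell_data = cell_data[need],
                 gene_ids = gene_ids, stage = stage),
            class = "CellMatrix")
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d cells x %d genes, %d cell types%s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_data$cell_type)),
              if (is.null(x$stage)) "" else paste0(", stage ", x$stage)))
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' Read a single-cell count matrix
#'
#' Accepts a MatrixMarket coordinate triplet (\code{.mtx}) or a dense TSV
#' (auto-detected by extension), with sidecar TSVs for genes and cells.
#' The cell file must carry \code{cell_id}, \code{cell_type},
#' \code{n_features}, \code{percent_mito}; the gene file a \code{gene_id}
#' column.  For MTX the stored orientation is cells x genes.
#'
#' @param path_matrix Path to \code{.mtx} or dense \code{.tsv} counts
#'   (dense: rows = cells, columns = genes, first column \code{cell_id}).
#' @param path_genes Path to gene sidecar TSV.
#' @param path_cells Path to cell sidecar TSV.
#' @param stage Optional stage tag.
#' @return CellMatrix.
#' @export
read_cell_matrix <- function(path_matrix, path_genes, path_cells,
                             stage = NULL) {
  genes <- utils::read.delim(path_genes, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes))
    .stopf("gene sidecar %s lacks a gene_id column", path_genes)
  cells <- utils::read.delim(path_cells, stringsAsFactors = FALSE)
  ext <- tolower(tools::file_ext(path_matrix))
  if (ext == "mtx") {
    counts <- as(Matrix::readMM(path_matrix), "CsparseMatrix")
    if (nrow(counts) != nrow(cells) || ncol(counts) != nrow(genes))
      .stopf("MTX dimensions (%d x %d) do not match sidecars (%d cells, %d genes)",
             nrow(counts), ncol(counts), nrow(cells), nrow(genes))
  } else {
    df <- utils::read.delim(path_matrix, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (names(df)[1] != "cell_id")
      .stopf("dense cell matrix %s must start with a cell_id column",
             path_matrix)
    counts <- as.matrix(df[, -1, drop = FALSE])
    if (!identical(.strip(df$cell_id), .strip(cells$cell_id)))
      .stopf("cell ids in dense matrix do not match cell sidecar")
    if (ncol(counts) != nrow(genes))
      .stopf("dense matrix genes (%d) do not match gene sidecar (%d)",
             ncol(counts), nrow(genes))
  }
  CellMatrix(counts, cells, gene_ids = .strip(genes$gene_id), stage = stage)
}

#' Write a CellMatrix as MTX triplet plus sidecars
#' @param x CellMatrix.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix, default \code{"counts"}.
#' @return Named character vector of the three paths written.
#' @export
write_cell_matrix <- function(x, dir, prefix = "counts") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pm <- file.path(dir, paste0(prefix, ".mtx"))
  pg <- file.path(dir, paste0(prefix, "_genes.tsv"))
  pc <- file.path(dir, paste0(prefix, "_cells.tsv"))
  m <- x$counts
  if (!methods::is(m, "sparseMatrix"))
    m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(methods::as(m * 1, "CsparseMatrix"), pm)
  utils::write.table(data.frame(gene_id = x$gene_ids), pg, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$cell_data, pc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(matrix = pm, genes = pg, cells = pc)
}
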