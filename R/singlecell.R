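# Cell-type-resolved expression, entropy specificity, gene-set aggregation
# and protein-feature x cell-type enrichment.

#' Quality-control filter on cells
#'
#' Keeps cells with \code{min_features <= n_features <= max_features}
#' (bounds inclusive) and \code{percent_mito < max_mito} (strictly less).
#' The number of removed cells is reported as a message and attached as the
#' attribute \code{"removed"}.
#'
#' @param x CellMatrix.
#' @param min_features,max_features Detected-feature bounds, defaults 200
#'   and 6000 (inclusive).
#' @param max_mito Mitochondrial-content ceiling in percent, default 10
#'   (strict).
#' @return Filtered CellMatrix.
#' @export
qc_filter <- function(x, min_features = 200, max_features = 6000,
                      max_mito = 10) {
  cd <- x$cell_data
  keep <- cd$n_features >= min_features & cd$n_features <= max_features &
    cd$percent_mito < max_mito
  removed <- sum(!keep)
  message(sprintf("qc_filter: removed %d of %d cells", removed, nrow(cd)))
  out <- CellMatrix(x$counts[keep, , drop = FALSE],
                    cd[keep, , drop = FALSE],
                    gene_ids = x$gene_ids, stage = x$stage)
  attr(out, "removed") <- removed
  out
}

#' Log-normalize single-cell counts
#'
#' Scales each cell to a fixed total (\code{scale}, default 10,000) and
#' applies \code{log(1 + x)} (natural log):
#' \code{value = ln(1 + count / cell_total * scale)}.  Doubling all counts
#' in a cell leaves its normalized values unchanged.
#'
#' @param x CellMatrix (or a cells x genes count matrix).
#' @param scale Scale factor, default 1e4.
#' @return Normalized cells x genes matrix (sparse when the input counts
#'   are sparse).
#' @export
lognormalize <- function(x, scale = 1e4) {
  counts <- if (inherits(x, "CellMatrix")) x$counts else x
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0)) .stopf("cell with zero total counts")
  if (methods::is(counts, "sparseMatrix")) {
    norm <- methods::as(counts, "CsparseMatrix")
    # CSC: column j spans p[j]:(p[j+1]-1); rows give the owning cell
    cell_of <- norm@i + 1L
    norm@x <- log1p(norm@x / totals[cell_of] * scale)
    norm
  } else {
    log1p(counts / totals * scale)
  }
}

#' Mean expression per cell type
#'
#' Averages each gene's normalized expression over the cells of each type.
#' Types with fewer than \code{min_cells} cells are excluded and listed in
#' the \code{excluded} field (scarce populations do not support robust
#' means).
#'
#' @param norm Normalized cells x genes matrix
#'   (\code{\link{lognormalize}}).
#' @param labels Character vector of cell-type labels, one per cell.
#' @param min_cells Minimum cells per retained type, default 50.
#' @return Object of class \code{CellTypeProfile}: list with \code{means}
#'   (genes x types), \code{gene_ids}, \code{cell_types}, \code{n_cells}
#'   (named), \code{excluded} (named integer vector of dropped types).
#' @export
celltype_means <- function(norm, labels, min_cells = 50) {
  if (length(labels) != nrow(norm))
    .stopf("one label per cell required (%d labels, %d cells)",
           length(labels), nrow(norm))
  counts <- table(labels)
  keep_types <- names(counts)[counts >= min_cells]
  excluded <- counts[counts < min_cells]
  if (!length(keep_types)) .stopf("no cell type reaches min_cells = %d",
                                  min_cells)
  means <- vapply(keep_types, function(ct) {
    Matrix::colMeans(norm[labels == ct, , drop = FALSE])
  }, numeric(ncol(norm)))
  rownames(means) <- colnames(norm)
  structure(list(means = means, gene_ids = colnames(norm),
                 cell_types = keep_types,
                 n_cells = stats::setNames(as.integer(counts[keep_types]),
                                           keep_types),
                 excluded = stats::setNames(as.integer(excluded),
                                            names(excluded))),
            class = "CellTypeProfile")
}

#' @export
print.CellTypeProfile <- function(x, ...) {
  cat(sprintf("CellTypeProfile: %d genes x %d cell types%s\n",
              nrow(x$means), ncol(x$means),
              if (length(x$excluded))
                paste0(" (excluded: ",
                       paste(names(x$excluded), collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Entropy-based cell-type specificity
#'
#' For each gene, normalize its cell-type means to a distribution
#' \code{p_c = m_c / sum(m)}, compute the Shannon entropy
#' \code{H = -sum p_c ln p_c} (with \code{0 ln 0 := 0}) and the specificity
#' \code{S = 1 - H / ln(T)} over T types.  S is 1 for expression confined
#' to one type, 0 for perfectly uniform expression; lower entropy means
#' expression concentrated in fewer cell types.  Genes with all-zero means
#' are undefined (NA).  The ln(T) normalisation makes stages with different
#' numbers of retained types comparable.
#'
#' @param profile CellTypeProfile.
#' @return data.frame with \code{gene_id}, \code{entropy}, \code{score},
#'   \code{n_types}.
#' @export
entropy_specificity <- function(profile) {
  m <- profile$means
  T <- ncol(m)
  if (T < 2L) .stopf("specificity requires at least two cell types")
  tot <- rowSums(m)
  p <- m / tot
  plogp <- ifelse(p > 0, p * log(p), 0)
  H <- -rowSums(plogp)
  S <- 1 - H / log(T)
  H[tot == 0] <- NA_real_
  S[tot == 0] <- NA_real_
  data.frame(gene_id = rownames(m), entropy = unname(H),
             score = unname(S), n_types = T, stringsAsFactors = FALSE)
}

#' Aggregate a gene set across cell types
#'
#' Cumulative (summed) normalized mean expression of a gene set per cell
#' type; the peak type is attached as attribute \code{"argmax"}.
#'
#' @param profile CellTypeProfile.
#' @param gene_set Non-empty character vector of gene ids.
#' @return Named numeric vector over cell types.
#' @export
aggregate_gene_set <- function(profile, gene_set) {
  if (!length(gene_set)) .stopf("gene set is empty")
  miss <- setdiff(gene_set, profile$gene_ids)
  if (length(miss))
    .stopf("gene(s) not in profile: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  s <- colSums(profile$means[gene_set, , drop = FALSE])
  attr(s, "argmax") <- names(s)[which.max(s)]
  s
}

#' Protein-feature x cell-type enrichment
#'
#' For each gene the cell-type mean profile is Z-scored across cell types
#' (within-gene; zero-variance profiles map to zeros); for each feature tag
#' the enrichment row is the mean Z over the genes carrying that tag.
#' Features with no gene detected in the profile are omitted with a
#' warning.
#'
#' @param profile CellTypeProfile.
#' @param features Feature annotation data.frame (\code{gene_id},
#'   \code{feature}).
#' @return List with \code{enrichment} (features x cell types matrix) and
#'   \code{n_genes} (named integer, contributing genes per feature).
#' @export
feature_celltype_enrichment <- function(profile, features) {
  z <- zscore_rows(profile$means)
  tags <- unique(features$feature)
  rows <- list(); ngenes <- integer(0)
  for (f in tags) {
    g <- intersect(features$gene_id[features$feature == f],
                   profile$gene_ids)
    if (!length(g)) {
      .warnf("feature '%s' has no detected gene; omitted", f)
      next
    }
    rows[[f]] <- colMeans(z[g, , drop = FALSE])
    ngenes[f] <- length(g)
  }
  if (!length(rows)) .stopf("no feature has any detected gene")
  enr <- do.call(rbind, rows)
  list(enrichment = enr, n_genes = ngenes)
}

#' Compare gene ranks between two stages
#'
#' Spearman rank correlation (ties mid-ranked) of two named score vectors
#' over the genes present in both, plus a per-gene rank-shift table.
#'
#' @param scores_stage1,scores_stage2 Named numeric vectors (e.g.
#'   specificity scores at two developmental stages).
#' @return List with \code{rho}, \code{n}, and \code{shifts}: data.frame
#'   \code{gene_id}, \code{rank1}, \code{rank2}, \code{delta}
#'   (\code{rank2 - rank1}).
#' @export
stage_rank_comparison <- function(scores_stage1, scores_stage2) {
  common <- intersect(names(scores_stage1), names(scores_stage2))
  if (length(common) < 2L) .stopf("need at least two shared genes")
  s1 <- scores_stage1[common]; s2 <- scores_stage2[common]
  ok <- !is.na(s1) & !is.na(s2)
  s1 <- s1[ok]; s2 <- s2[ok]
  r1 <- rank(s1); r2 <- rank(s2)
  rho <- stats::cor(s1, s2, method = "spearman")
  list(rho = unname(rho), n = length(s1),
       shifts = data.frame(gene_id = names(s1), rank1 = unname(r1),
                           rank2 = unname(r2),
                           delta = unname(r2 - r1),
                           stringsAsFactors = FALSE))
}
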