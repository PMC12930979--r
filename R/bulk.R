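# Bulk one-vs-rest enrichment: identify genes selectively expressed in a
# target tissue from a multi-tissue FPKM matrix, and score their specificity.

#' Retain provisional-identifier protein-coding genes
#'
#' Keeps genes whose name matches the configured identifier pattern (by
#' default names ending in \code{"Rik"}, the provisional RIKEN cDNA
#' convention) and whose biotype is \code{protein_coding}.  Non-coding
#' provisional genes (lncRNA, pseudogene, ...) are dropped.  Row order is
#' preserved.
#'
#' @param x ExpressionMatrix with annotation.
#' @param pattern Regular expression applied to \code{gene_name}; default
#'   \code{"Rik$"}.
#' @param biotype Required biotype; default \code{"protein_coding"}.
#' @return ExpressionMatrix restricted to matching genes; a warning is
#'   emitted (and an empty matrix returned) when nothing survives.
#' @export
select_rik_protein_coding <- function(x, pattern = "Rik$",
                                      biotype = "protein_coding") {
  if (is.null(x$annotation))
    .stopf("annotation is required to select genes by name/biotype")
  keep <- grepl(pattern, x$annotation$gene_name) &
    x$annotation$biotype == biotype
  if (!any(keep)) {
    .warnf("no genes match pattern '%s' with biotype '%s'", pattern, biotype)
  }
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out$annotation <- x$annotation[keep, , drop = FALSE]
  rownames(out$annotation) <- NULL
  out
}

#' Per-tissue mean expression
#'
#' Arithmetic mean of FPKM over each tissue's replicates.
#'
#' @param x ExpressionMatrix.
#' @return Numeric matrix, genes x tissues (tissue order = first appearance
#'   in the sample table).
#' @export
tissue_means <- function(x) {
  st <- x$sample_table
  tissues <- unique(st$tissue)
  out <- vapply(tissues, function(t) {
    cols <- st$sample_id[st$tissue == t]
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  if (nrow(x$values) == 1L) out <- matrix(out, nrow = 1,
                                          dimnames = list(rownames(x$values),
                                                          tissues))
  out
}

#' One-vs-rest log2 fold change
#'
#' \code{log2((mean_target + eps) / (mean_of_other_tissue_means + eps))}.
#' "Rest" is the unweighted mean of the other tissues' per-tissue means,
#' i.e. the contrast is at tissue granularity, not pooled samples.
#'
#' @param means Genes x tissues matrix from \code{\link{tissue_means}}.
#' @param target Target tissue name.
#' @param pseudocount Positive stabiliser added to both means; default 0.01
#'   (below the conventional 0.1 FPKM expression floor).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2fc_one_vs_rest <- function(means, target, pseudocount = 0.01) {
  if (!target %in% colnames(means))
    .stopf("target tissue '%s' not present", target)
  if (ncol(means) < 2L)
    .stopf("one-vs-rest requires at least two tissues")
  if (pseudocount <= 0) .stopf("pseudocount must be > 0")
  tgt <- means[, target]
  rest <- rowMeans(means[, setdiff(colnames(means), target), drop = FALSE])
  log2((tgt + pseudocount) / (rest + pseudocount))
}

#' One-vs-rest enrichment test
#'
#' Per-gene two-sided test of the target tissue's replicates against all
#' other samples pooled, on \code{log2(FPKM + 1)} values.  Three tests are
#' available:
#' \describe{
#'   \item{\code{"moderated"}}{limma trend-moderated t (default).  With the
#'     typical two replicates per tissue a per-gene variance estimate has
#'     almost no information; sharing variance across genes along the
#'     mean-variance trend is what makes small-replicate designs testable,
#'     and mirrors the information sharing of count-model DE tools.}
#'   \item{\code{"pooled"}}{Student t with pooled variance,
#'     df = n1 + n2 - 2.}
#'   \item{\code{"welch"}}{Welch t with Satterthwaite df.  Note that with
#'     two target replicates the Welch df collapses towards 1 and power is
#'     very poor; provided for completeness.}
#' }
#' Genes with zero variance in both groups and equal means get p = 1.
#'
#' @param x ExpressionMatrix.
#' @param target Target tissue name.
#' @param method One of \code{"moderated"}, \code{"pooled"}, \code{"welch"}.
#' @return Named numeric vector of p-values in [0,1].
#' @export
enrichment_test <- function(x, target,
                            method = c("moderated", "pooled", "welch")) {
  method <- match.arg(method)
  st <- x$sample_table
  if (!target %in% st$tissue)
    .stopf("target tissue '%s' not in sample table", target)
  grp1 <- st$sample_id[st$tissue == target]
  grp2 <- st$sample_id[st$tissue != target]
  if (length(grp1) < 2L || length(grp2) < 2L)
    .stopf("need at least two samples in each group (target %d, rest %d)",
           length(grp1), length(grp2))
  lv <- log2(x$values + 1)
  g1 <- lv[, grp1, drop = FALSE]
  g2 <- lv[, grp2, drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- .row_vars(g1); v2 <- .row_vars(g2)

  if (method == "moderated") {
    design <- cbind(Intercept = 1,
                    target = as.numeric(st$tissue == target))
    fit <- limma::eBayes(limma::lmFit(lv, design), trend = TRUE)
    p <- fit$p.value[, "target"]
  } else if (method == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    tt <- (m1 - m2) / sqrt(se2)
    p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  } else {
    a <- v1 / n1; b <- v2 / n2
    se2 <- a + b
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df = df)
  }
  # degenerate genes: no variance anywhere and equal means -> no evidence
  degen <- (v1 == 0 & v2 == 0 & m1 == m2)
  p[degen] <- 1
  p[is.na(p)] <- 1
  p <- pmin(pmax(p, 0), 1)
  stats::setNames(p, rownames(lv))
}

.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment: sort p ascending, take
#' \code{padj_(i) = min_{j >= i} p_(j) * m / j} capped at 1, and restore the
#' original order.
#'
#' @param p Numeric vector of p-values in [0,1] (NAs propagate and do not
#'   count towards m).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  pv <- p[ok]
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out[ok[o]] <- adj
  names(out) <- names(p)
  out
}

#' Tissue-specificity index tau
#'
#' Yanai-style index computed on transformed per-tissue means
#' \code{y_t}: \code{tau = sum_t (1 - y_t / max_t y) / (N - 1)}.
#' 0 means uniform expression, 1 means expression confined to a single
#' tissue.  Genes whose transformed maximum is 0 are undefined (NA).
#'
#' @param means Genes x tissues matrix of mean FPKM.
#' @param transform \code{"log2"} (default, \code{y = log2(mean + 1)}) or
#'   \code{"none"} (raw means).
#' @return Named numeric vector of tau in [0,1] (NA where undefined).
#' @export
compute_tau <- function(means, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  if (ncol(means) < 2L) .stopf("tau requires at least two tissues")
  y <- if (transform == "log2") log2(means + 1) else means
  if (any(y < 0)) .stopf("tau requires non-negative transformed values")
  mx <- apply(y, 1, max)
  n <- ncol(y)
  tau <- rowSums(1 - y / mx) / (n - 1)
  tau[mx == 0] <- NA_real_
  stats::setNames(tau, rownames(means))
}

#' Assemble per-gene enrichment records
#'
#' Runs the one-vs-rest contrast end to end and returns one row per gene:
#' log2 fold change, p-value, BH-adjusted p, mean target-tissue FPKM, tau,
#' and the triple-filter pass flag.
#'
#' @param x ExpressionMatrix.
#' @param target Target tissue.
#' @param pseudocount Pseudocount for the fold change (default 0.01).
#' @param method Test passed to \code{\link{enrichment_test}}.
#' @param log2fc_min,padj_max,min_fpkm Triple-filter thresholds, strict
#'   inequalities: \code{log2fc > log2fc_min}, \code{padj < padj_max},
#'   \code{mean_target_fpkm > min_fpkm}.  Defaults 0.58, 0.05, 0.1.
#' @param tau_transform Transform for \code{\link{compute_tau}}.
#' @return data.frame with columns \code{gene_id}, \code{log2fc},
#'   \code{pvalue}, \code{padj}, \code{mean_target_fpkm}, \code{tau},
#'   \code{enriched}.
#' @export
enrichment_records <- function(x, target, pseudocount = 0.01,
                               method = "moderated",
                               log2fc_min = 0.58, padj_max = 0.05,
                               min_fpkm = 0.1, tau_transform = "log2") {
  means <- tissue_means(x)
  lfc <- log2fc_one_vs_rest(means, target, pseudocount)
  p <- enrichment_test(x, target, method = method)
  padj <- bh_adjust(p)
  tau <- compute_tau(means, transform = tau_transform)
  rec <- data.frame(gene_id = rownames(x$values),
                    log2fc = unname(lfc),
                    pvalue = unname(p),
                    padj = unname(padj),
                    mean_target_fpkm = unname(means[, target]),
                    tau = unname(tau),
                    stringsAsFactors = FALSE)
  rec$enriched <- rec$log2fc > log2fc_min & rec$padj < padj_max &
    rec$mean_target_fpkm > min_fpkm
  rec
}

#' Apply the triple enrichment filter
#'
#' A gene is enriched iff all three strict inequalities hold:
#' \code{log2fc > log2fc_min}, \code{padj < padj_max} and
#' \code{mean_target_fpkm > min_fpkm}.
#'
#' @param records data.frame from \code{\link{enrichment_records}} (columns
#'   \code{gene_id}, \code{log2fc}, \code{padj}, \code{mean_target_fpkm}).
#' @param log2fc_min,padj_max,min_fpkm Thresholds; defaults 0.58, 0.05, 0.1.
#' @return Character vector of enriched gene ids.
#' @export
filter_enriched <- function(records, log2fc_min = 0.58, padj_max = 0.05,
                            min_fpkm = 0.1) {
  need <- c("gene_id", "log2fc", "padj", "mean_target_fpkm")
  miss <- setdiff(need, names(records))
  if (length(miss))
    .stopf("records lack column(s): %s", paste(miss, collapse = ", "))
  pass <- records$log2fc > log2fc_min & records$padj < padj_max &
    records$mean_target_fpkm > min_fpkm
  pass[is.na(pass)] <- FALSE
  records$gene_id[pass]
}

#' Row-standardise a matrix (Z-score each row)
#'
#' Subtracts the row mean and divides by the row sample standard deviation.
#' Zero-variance rows map to all zeros so that downstream heatmaps and
#' gene-set scores stay defined.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(.row_vars(m))
  z <- (m - mu) / s
  z[s == 0 | !is.finite(s), ] <- 0
  z
}

#' Gene-set enrichment score profile across tissues
#'
#' For each tissue, the mean over the gene set of the row-Z-scored
#' \code{log2(mean FPKM + 1)} profile.  Because each row Z sums to zero,
#' the profile of any set sums to ~0 across tissues; a set of genes all
#' maximal in one tissue peaks there.
#'
#' @param means Genes x tissues matrix of mean FPKM.
#' @param gene_set Character vector of gene ids (subset of rownames).
#' @return Named numeric vector, one score per tissue.
#' @export
gene_set_score <- function(means, gene_set) {
  if (!length(gene_set)) .stopf("gene set is empty")
  miss <- setdiff(gene_set, rownames(means))
  if (length(miss))
    .stopf("gene(s) not in matrix: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  z <- zscore_rows(log2(means + 1))
  colMeans(z[gene_set, , drop = FALSE])
}

#' PCA embedding of samples or tissues
#'
#' Centred SVD of the observations (matrix columns).  Deterministic up to
#' the fixed sign convention that each component's largest-magnitude gene
#' loading is positive.
#'
#' @param m Numeric matrix, rows = genes (variables), columns =
#'   observations (samples or tissues).
#' @param n_components Number of components to keep (default 2).
#' @return List with \code{coordinates} (observations x components),
#'   \code{explained_variance} (fractions, non-increasing) and
#'   \code{loadings}.
#' @export
pca_embed <- function(m, n_components = 2) {
  x <- t(m)                      # observations in rows
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  if (n_components < 1L) .stopf("need at least two observations for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  coord <- pc$x[, k, drop = FALSE]
  # sign convention: largest-|loading| positive
  for (j in k) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      coord[, j] <- -coord[, j]
    }
  }
  list(coordinates = coord, explained_variance = ev[k], loadings = rot)
}

#' Top genes by enrichment effect size
#'
#' Ranks by decreasing \code{log2fc} with a deterministic lexicographic
#' tie-break on \code{gene_id}.
#'
#' @param records Enrichment records data.frame.
#' @param n Number of genes to keep; when \code{n} is at least the number
#'   of records all genes are returned (still in rank order).
#' @return Character vector of gene ids.
#' @export
select_top_genes <- function(records, n) {
  o <- order(-records$log2fc, records$gene_id)
  utils::head(records$gene_id[o], n)
}
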