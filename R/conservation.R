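# Orthologue conservation breadth, alignment identity, column conservation
# and protein composition.

#' Deduplicate orthologue mappings
#'
#' For each (source_gene, species) pair with multiple mappings the entry
#' with the highest percent identity is retained; ties break to the
#' lexicographically smallest target gene.  Rows with no detected
#' orthologue never outrank a detected one and survive only when a pair has
#' no detected mapping at all.
#'
#' @param records data.frame from \code{\link{read_ortholog_table}}.
#' @return data.frame with one row per (source_gene, species).
#' @export
dedup_orthologs <- function(records) {
  key <- paste(records$source_gene, records$species, sep = "\r")
  # order: detected first, then identity descending, then target ascending
  o <- order(key, !records$detected, -ifelse(is.na(records$percent_identity),
                                             -Inf, records$percent_identity),
             records$target_gene, method = "radix")
  r <- records[o, , drop = FALSE]
  keep <- !duplicated(paste(r$source_gene, r$species, sep = "\r"))
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conservation breadth per source gene
#'
#' Counts, for each source gene, the number of species in
#' \code{species_list} with a detected orthologue after deduplication.
#' Genes with no orthologue anywhere get breadth 0 (lineage-restricted).
#'
#' @param records Deduplicated orthologue records
#'   (\code{\link{dedup_orthologs}}).
#' @param species_list Character vector of species to count over.
#' @return data.frame with \code{source_gene}, \code{breadth}, and one
#'   \code{identity_<species>} column per species (best percent identity,
#'   NA where undetected).
#' @export
conservation_breadth <- function(records, species_list) {
  genes <- unique(records$source_gene)
  r <- records[records$species %in% species_list, , drop = FALSE]
  out <- data.frame(source_gene = genes, stringsAsFactors = FALSE)
  det <- matrix(FALSE, length(genes), length(species_list),
                dimnames = list(genes, species_list))
  idm <- matrix(NA_real_, length(genes), length(species_list),
                dimnames = list(genes, species_list))
  hit <- r$detected
  det[cbind(match(r$source_gene[hit], genes),
            match(r$species[hit], species_list))] <- TRUE
  idm[cbind(match(r$source_gene[hit], genes),
            match(r$species[hit], species_list))] <-
    r$percent_identity[hit]
  out$breadth <- as.integer(rowSums(det))
  for (s in species_list) out[[paste0("identity_", s)]] <- idm[, s]
  out
}

#' Pairwise identity between two aligned sequences
#'
#' Fraction of identical residues over the columns where \emph{both}
#' sequences are non-gap.  When no such column exists the identity is
#' undefined (NA).
#'
#' @param alignment ProteinAlignment.
#' @param i,j Row indices or sequence ids.
#' @return Identity in [0,1], or NA.
#' @export
pairwise_identity <- function(alignment, i, j) {
  m <- as.matrix(alignment)
  i <- .aln_row(alignment, i); j <- .aln_row(alignment, j)
  a <- m[i, ]; b <- m[j, ]
  both <- a != "-" & b != "-"
  if (!any(both)) return(NA_real_)
  sum(a[both] == b[both]) / sum(both)
}

.aln_row <- function(alignment, i) {
  if (is.character(i)) {
    k <- match(i, alignment$ids)
    if (is.na(k)) .stopf("no sequence '%s' in alignment", i)
    return(k)
  }
  if (i < 1 || i > length(alignment$ids)) .stopf("row %s out of range", i)
  i
}

#' Pairwise identity matrix
#'
#' Symmetric matrix of \code{\link{pairwise_identity}} over all sequence
#' pairs; the diagonal is 1.
#'
#' @param alignment ProteinAlignment.
#' @return Numeric matrix with sequence ids as dimnames.
#' @export
identity_matrix <- function(alignment) {
  n <- length(alignment$ids)
  m <- as.matrix(alignment)
  nongap <- m != "-"
  out <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        both <- nongap[i, ] & nongap[j, ]
        out[i, j] <- out[j, i] <-
          if (any(both)) sum(m[i, both] == m[j, both]) / sum(both)
          else NA_real_
      }
    }
  }
  dimnames(out) <- list(alignment$ids, alignment$ids)
  out
}

#' Per-column conservation track
#'
#' For each alignment column, the maximum residue frequency among non-gap
#' residues (a one-sequence alignment is therefore 1 at every non-gap
#' column).  All-gap columns are flagged missing.
#'
#' @param alignment ProteinAlignment.
#' @return data.frame with columns \code{column}, \code{score} (NA for
#'   all-gap columns) and \code{n_nongap}.
#' @export
column_conservation <- function(alignment) {
  m <- as.matrix(alignment)
  score <- numeric(ncol(m))
  nng <- integer(ncol(m))
  for (k in seq_len(ncol(m))) {
    col <- m[, k]
    res <- col[col != "-"]
    nng[k] <- length(res)
    score[k] <- if (length(res)) max(tabulate(factor(res))) / length(res)
                else NA_real_
  }
  data.frame(column = seq_len(ncol(m)), score = score, n_nongap = nng)
}

# Composition ----------------------------------------------------------------

#' Default physicochemical class map
#'
#' Five classes: hydrophobic \{A,V,L,I,M,F,W\}, polar \{S,T,N,Q,Y,C,H\},
#' positive \{K,R\}, negative \{D,E\}, special (proline/glycine) \{P,G\}.
#' Histidine is placed with the polar class (a single assignment is
#' required; pass your own map to change it).
#'
#' @return Named character vector mapping residue -> class.
#' @export
aa_class_map <- function() {
  map <- c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
           I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
           W = "hydrophobic",
           S = "polar", T = "polar", N = "polar", Q = "polar",
           Y = "polar", C = "polar", H = "polar",
           K = "positive", R = "positive",
           D = "negative", E = "negative",
           P = "special", G = "special")
  map
}

#' Amino-acid composition profile
#'
#' Fraction of residues in each of five physicochemical classes.  \code{X}
#' and gaps are excluded from the denominator; a sequence with no standard
#' residue is an error.
#'
#' @param sequence Protein sequence (string).
#' @param class_map Residue -> class map; default \code{\link{aa_class_map}}.
#' @return Named numeric vector over
#'   \code{c("hydrophobic","polar","positive","negative","special")},
#'   summing to 1.
#' @export
composition_profile <- function(sequence, class_map = aa_class_map()) {
  if (!nzchar(sequence)) .stopf("empty sequence")
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  ch <- ch[!ch %in% c("-", "X")]
  if (!length(ch)) .stopf("sequence contains no standard residue")
  .check_aa(list(paste(ch, collapse = "")), what = "sequence")
  classes <- c("hydrophobic", "polar", "positive", "negative", "special")
  cl <- class_map[ch]
  tab <- table(factor(cl, levels = classes))
  as.vector(tab) / length(ch) -> fr
  stats::setNames(fr, classes)
}

#' Sequence lengths by group
#'
#' Emits per-group amino-acid lengths for downstream comparison (the
#' significance test itself is a standard rank-sum call, e.g.
#' \code{wilcox.test}).  Gaps are stripped first so aligned input gives the
#' same lengths as unaligned input.
#'
#' @param groups Named list of character vectors of sequences.
#' @return Named list of integer vectors of lengths; empty groups yield an
#'   empty vector with a warning.
#' @export
length_table <- function(groups) {
  out <- lapply(names(groups), function(g) {
    seqs <- groups[[g]]
    if (!length(seqs)) {
      .warnf("group '%s' is empty", g)
      return(integer(0))
    }
    nchar(gsub("-", "", seqs, fixed = TRUE))
  })
  stats::setNames(out, names(groups))
}
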