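# Global pairwise protein alignment (Needleman-Wunsch with affine gaps).
# Built-in fallback for externally produced multiple alignments.

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix as shipped with Biostrings, restricted to
#' the 20 standard residues plus X.
#'
#' @return Integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c(AA20, "X")
  m[keep, keep]
}

#' Global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment.  A gap run of length L costs
#' \code{gap_open + (L - 1) * gap_extend} (the first gapped position pays
#' the opening penalty).  Traceback is deterministic with tie preference
#' diagonal > up (gap in \code{b}) > left (gap in \code{a}), so the same
#' inputs always give the same alignment, and the returned score is the
#' global optimum.
#'
#' @param a,b Protein sequences (non-empty strings).
#' @param substitution_matrix Scoring matrix with residue dimnames; default
#'   \code{\link{blosum62}}.
#' @param gap_open Cost of the first position of a gap (positive number,
#'   default 10).
#' @param gap_extend Cost of each further gapped position (default 1).
#' @return List with \code{alignment} (a two-sequence
#'   \code{ProteinAlignment}), \code{score}, and \code{identity} (pairwise
#'   identity of the aligned pair).
#' @export
nw_align <- function(a, b, substitution_matrix = blosum62(),
                     gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) .stopf("empty sequence")
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  .check_aa(list(a = paste(A, collapse = ""), b = paste(B, collapse = "")),
            allow_gap = FALSE)
  S <- substitution_matrix
  n <- length(A); m <- length(B)
  NEG <- -1e9
  # state matrices: M match/mismatch, X gap in b (consumes a, "up"),
  # Y gap in a (consumes b, "left")
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  # traceback: which predecessor state fed each cell (1=M, 2=X, 3=Y)
  tbM <- matrix(0L, n + 1, m + 1)
  tbX <- matrix(0L, n + 1, m + 1)
  tbY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- -gap_open - (i - 1) * gap_extend
    tbX[i + 1, 1] <- if (i == 1) 1L else 2L
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- -gap_open - (j - 1) * gap_extend
    tbY[1, j + 1] <- if (j == 1) 1L else 3L
  }
  for (i in seq_len(n)) {
    si <- S[A[i], ]
    for (j in seq_len(m)) {
      s <- si[B[j]]
      # M: best predecessor at (i-1, j-1); tie order M > X > Y
      cand <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(cand)
      M[i + 1, j + 1] <- cand[k] + s
      tbM[i + 1, j + 1] <- k
      # X (gap in b): from (i-1, j); opening from M or Y, extending from X
      cand <- c(M[i, j + 1] - gap_open,
                X[i, j + 1] - gap_extend,
                Y[i, j + 1] - gap_open)
      k <- which.max(cand)
      X[i + 1, j + 1] <- cand[k]
      tbX[i + 1, j + 1] <- k
      # Y (gap in a): from (i, j-1)
      cand <- c(M[i + 1, j] - gap_open,
                X[i + 1, j] - gap_open,
                Y[i + 1, j] - gap_extend)
      k <- which.max(cand)
      Y[i + 1, j + 1] <- cand[k]
      tbY[i + 1, j + 1] <- k
    }
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(finals)       # tie order M > X > Y
  score <- finals[state]
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == 1L) {
      prev <- tbM[i + 1, j + 1]
      ra <- c(A[i], ra); rb <- c(B[j], rb)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      prev <- tbX[i + 1, j + 1]
      ra <- c(A[i], ra); rb <- c("-", rb)
      i <- i - 1
    } else {
      prev <- tbY[i + 1, j + 1]
      ra <- c("-", ra); rb <- c(B[j], rb)
      j <- j - 1
    }
    state <- prev
  }
  aln <- ProteinAlignment(c(a = paste(ra, collapse = ""),
                            b = paste(rb, collapse = "")))
  list(alignment = aln, score = unname(score),
       identity = pairwise_identity(aln, 1, 2))
}
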