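# Independent brute-force oracles.  Each is deliberately written the dumb,
# literal way (loops, enumeration) so it shares no code path with the
# implementation it checks.

# literal step-up BH: for each i in sort order, min over j >= i of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, p[o[j]] * m / j)
    out[o[i]] <- min(c(vals, 1))
  }
  out
}

# direct tau on an already-transformed profile
oracle_tau <- function(y) {
  mx <- max(y)
  if (mx == 0) return(NA_real_)
  s <- 0
  for (v in y) s <- s + (1 - v / mx)
  s / (length(y) - 1)
}

# pairwise identity by a literal per-column loop
oracle_identity <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  num <- 0; den <- 0
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      den <- den + 1
      if (a[k] == b[k]) num <- num + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

# column conservation by literal counting
oracle_column_conservation <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  sapply(seq_len(ncol(m)), function(k) {
    res <- m[, k][m[, k] != "-"]
    if (!length(res)) return(NA_real_)
    max(table(res)) / length(res)
  })
}

# affine gap score of an explicit alignment (pair of gapped strings)
score_alignment <- function(ca, cb, S, gap_open, gap_extend) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  sc <- 0; in_a <- FALSE; in_b <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      sc <- sc - if (in_a) gap_extend else gap_open
      in_a <- TRUE; in_b <- FALSE
    } else if (b[k] == "-") {
      sc <- sc - if (in_b) gap_extend else gap_open
      in_b <- TRUE; in_a <- FALSE
    } else {
      sc <- sc + S[a[k], b[k]]
      in_a <- FALSE; in_b <- FALSE
    }
  }
  sc
}

# optimal global score by exhaustive enumeration of all alignments
oracle_nw_score <- function(sa, sb, S, gap_open, gap_extend) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score_alignment(paste(ca, collapse = ""),
                                         paste(cb, collapse = ""),
                                         S, gap_open, gap_extend))
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, c(ca, a[i]), c(cb, b[j]))
    if (i <= length(a)) rec(i + 1, j, c(ca, a[i]), c(cb, "-"))
    if (j <= length(b)) rec(i, j + 1, c(ca, "-"), c(cb, b[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# Spearman by rank-then-Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sd(rx) * sd(ry)) *
    length(x) / (length(x) - 1)
}

# random gapped alignment, n sequences x w columns
random_alignment <- function(n, w, gap_frac = 0.15) {
  seqs <- replicate(n, {
    ch <- sample(rikatlas:::AA20, w, replace = TRUE)
    gaps <- runif(w) < gap_frac
    ch[gaps] <- "-"
    paste(ch, collapse = "")
  })
  names(seqs) <- paste0("s", seq_len(n))
  ProteinAlignment(seqs)
}

random_protein <- function(len) {
  paste(sample(rikatlas:::AA20, len, replace = TRUE), collapse = "")
}
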