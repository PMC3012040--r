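# Shared fixtures and independent oracles. Oracles are deliberately written
# as separate, naive implementations of the quantities they check.

toy_positions <- c(7L, 32L, 48L, 55L, 73L)

toy_pattern <- function() {
  rbind(c(1, 1, 0, 0, 0),
        c(1, 1, 0, 0, 0),
        c(0, 0, 1, 1, 0),
        c(0, 0, 1, 1, 1))
}

toy_dataset <- function() {
  meth_set(toy_pattern(), toy_positions)
}

toy_config <- function(seed = 42L, ...) {
  sim_config(ref_length = 100L, cpg_positions = toy_positions,
             methylation_pattern = toy_pattern(), n_noncpg_c = 10L,
             conversion_failure_p = 0, seq_error_p = 0, seed = seed, ...)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent affine-gap global alignment score (plain-R Gotoh, ACGT only)
r_nw_score <- function(ref, clone, scheme = subst_scheme()) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(clone, "")[[1]]
  n <- length(a); m <- length(b)
  s <- function(x, y) {
    if (x == y) scheme$match
    else if (x == "C" && y == "T") scheme$bisulfite_TC
    else scheme$mismatch
  }
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)   # gap in clone (ref consumed)
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in ref (clone consumed)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- scheme$gap_open + (i - 2) * scheme$gap_extend
  for (j in seq_len(m) + 1) Y[1, j] <- scheme$gap_open + (j - 2) * scheme$gap_extend
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        s(a[i - 1], b[j - 1])
      X[i, j] <- max(M[i - 1, j] + scheme$gap_open,
                     X[i - 1, j] + scheme$gap_extend,
                     Y[i - 1, j] + scheme$gap_open)
      Y[i, j] <- max(M[i, j - 1] + scheme$gap_open,
                     Y[i, j - 1] + scheme$gap_extend,
                     X[i, j - 1] + scheme$gap_open)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins (point probabilities via binomial coefficients)
fisher_oracle_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); N <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  pobs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(N, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# two-sided exact Mann-Whitney p by full enumeration of group assignments,
# with U computed by direct pair comparison (not ranks)
mw_oracle_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  ufun <- function(xi, yi) {
    sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  }
  centre <- m * n / 2
  obs <- abs(ufun(x, y) - centre)
  cmb <- combn(m + n, m)
  hits <- 0L
  for (k in seq_len(ncol(cmb))) {
    xi <- pooled[cmb[, k]]
    yi <- pooled[-cmb[, k]]
    if (abs(ufun(xi, yi) - centre) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(cmb)
}

# chi-square statistic over grand total, from first principles
chi2_over_n <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E) / sum(m)
}

# a random count matrix with no all-zero row or column
random_count_matrix <- function(nr, nc) {
  repeat {
    m <- matrix(stats::rpois(nr * nc, 1.5), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

write_lines_tmp <- function(lines, ext = ".fasta") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
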