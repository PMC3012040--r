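#' Per-site methylation summary
#'
#' @param ds A `meth_set`.
#' @return A tibble, one row per CpG site: `position`, `n_methylated`,
#'   `n_unmethylated`, `n_missing`, `percent_methylated` (missing calls are
#'   excluded from the denominator; an all-missing site yields NA).
#' @examples
#' ds <- meth_set(rbind(c(1, 0), c(1, NA)), c(7, 32))
#' methylation_summary(ds)
#' @export
methylation_summary <- function(ds) {
  stopifnot(inherits(ds, "meth_set"))
  m <- ds$calls
  n1 <- unname(colSums(m == 1, na.rm = TRUE))
  n0 <- unname(colSums(m == 0, na.rm = TRUE))
  nm <- unname(colSums(is.na(m)))
  tibble(
    position = ds$cpg_positions,
    n_methylated = as.integer(n1),
    n_unmethylated = as.integer(n0),
    n_missing = as.integer(nm),
    percent_methylated = ifelse(n1 + n0 > 0, 100 * n1 / (n1 + n0), NA_real_)
  )
}

phi_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2L) return(list(value = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(list(value = NA_real_, n = n))
  list(value = sum((x - mean(x)) * (y - mean(y))) /
         ((n - 1) * sd(x) * sd(y)), n = n)
}

shared_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 1L) return(list(value = NA_real_, n = n))
  list(value = mean(x[ok] == y[ok]), n = n)
}

#' Co-occurrence of methylation between CpG sites
#'
#' Pairwise agreement of methylation state across clones, for neighbouring
#' and distant site pairs. Two readings are available: `correlation`, the
#' Pearson correlation of the two binary columns over pairwise-complete
#' clones (the phi coefficient), and `shared_fraction`, the fraction of
#' pairwise-complete clones with identical state at both sites (one minus
#' the normalized Hamming distance between the columns). Pairs with fewer
#' than two complete clones, or zero variance in correlation mode, are
#' missing-flagged (NA), never NaN.
#'
#' @param ds A `meth_set` with at least two sites.
#' @param mode `"correlation"` (default) or `"shared_fraction"`.
#' @param neighbours_only If TRUE only adjacent site pairs (and the
#'   diagonal) are computed; distant entries stay NA.
#' @return A `meth_cooc` object: `positions`, `mode`, `values` (symmetric
#'   matrix, unit diagonal wherever a site has any complete observation),
#'   `n_pairs`, `neighbours_only`.
#' @export
cooccurrence <- function(ds, mode = c("correlation", "shared_fraction"),
                         neighbours_only = FALSE) {
  stopifnot(inherits(ds, "meth_set"))
  mode <- match.arg(mode)
  k <- length(ds$cpg_positions)
  if (k < 2L) {
    abort("co-occurrence needs at least two CpG sites",
          class = "methclones_input_error")
  }
  vals <- matrix(NA_real_, k, k, dimnames = list(ds$cpg_positions, ds$cpg_positions))
  np <- matrix(0L, k, k, dimnames = dimnames(vals))
  pairfun <- if (mode == "correlation") phi_pair else shared_pair
  for (i in seq_len(k)) {
    ni <- sum(!is.na(ds$calls[, i]))
    np[i, i] <- ni
    vals[i, i] <- if (ni > 0L) 1 else NA_real_
    if (i < k) {
      jj <- if (neighbours_only) i + 1L else seq(i + 1L, k)
      for (j in jj) {
        p <- pairfun(ds$calls[, i], ds$calls[, j])
        vals[i, j] <- vals[j, i] <- p$value
        np[i, j] <- np[j, i] <- p$n
      }
    }
  }
  structure(list(positions = ds$cpg_positions, mode = mode, values = vals,
                 n_pairs = np, neighbours_only = neighbours_only),
            class = "meth_cooc")
}

#' @export
print.meth_cooc <- function(x, ...) {
  cat("<meth_cooc> mode=", x$mode,
      if (x$neighbours_only) " (neighbours only)", "\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
tidy.meth_cooc <- function(x, ...) {
  k <- length(x$positions)
  idx <- which(upper.tri(x$values, diag = FALSE), arr.ind = TRUE)
  tibble(
    from = x$positions[idx[, 1L]],
    to = x$positions[idx[, 2L]],
    neighbouring = idx[, 2L] == idx[, 1L] + 1L,
    value = x$values[idx],
    n_pairs = x$n_pairs[idx]
  )
}

#' Neighbouring co-occurrence values
#'
#' Convenience accessor for adjacent site pairs, e.g. for the connecting
#' lines of the lollipop summary row.
#'
#' @param x A `meth_cooc` from [cooccurrence()].
#' @return Tibble with `from`, `to`, `value`, `n_pairs` for adjacent pairs.
#' @export
neighbour_values <- function(x) {
  stopifnot(inherits(x, "meth_cooc"))
  dplyr::filter(tidy(x), .data$neighbouring)[
    c("from", "to", "value", "n_pairs")]
}

normalize_groups <- function(ds, groups) {
  if (is.data.frame(groups)) {
    g <- setNames(as.character(groups$group), as.character(groups$clone_id))
  } else {
    g <- setNames(as.character(groups), names(groups) %||% ds$clone_ids)
  }
  g <- g[ds$clone_ids]
  if (anyNA(g)) {
    abort("every clone needs a group label", class = "methclones_input_error")
  }
  lev <- unique(g)
  if (length(lev) != 2L) {
    abort("exactly two groups are required", class = "methclones_input_error")
  }
  factor(g, levels = lev)
}

#' Per-site Fisher exact test between two clone groups
#'
#' For each CpG site, clones with a defined call are cross-tabulated as
#' group x methylation state and tested for independence with the two-sided
#' Fisher exact test (two-sidedness by summing hypergeometric point
#' probabilities at or below that of the observed table). A degenerate
#' table - any zero margin after missing-exclusion - is reported with p = 1
#' and flagged rather than tested.
#'
#' @param ds A `meth_set`.
#' @param groups Two-level labelling of clones: a tibble with `clone_id` and
#'   `group` columns, or a (named) vector in clone order.
#' @param positions CpG positions to test (default: all).
#' @param adjust `"none"` (default; the raw per-site p-values) or `"BH"` for
#'   Benjamini-Hochberg adjusted values in an extra column.
#' @return A tibble, one row per tested site: `position`, the 2x2 counts
#'   (`a` = group1/methylated, `b` = group1/unmethylated, `c`, `d` likewise
#'   for group2), `p_value`, `degenerate`, and `p_adjusted` when requested.
#' @export
fisher_site_test <- function(ds, groups, positions = NULL,
                             adjust = c("none", "BH")) {
  stopifnot(inherits(ds, "meth_set"))
  adjust <- match.arg(adjust)
  g <- normalize_groups(ds, groups)
  positions <- positions %||% ds$cpg_positions
  rows <- purrr::map(positions, function(pos) {
    j <- match(pos, ds$cpg_positions)
    if (is.na(j)) {
      abort(paste0("position ", pos, " is not a CpG site of this dataset"),
            class = "methclones_input_error")
    }
    call <- ds$calls[, j]
    ok <- !is.na(call)
    tab <- matrix(c(
      sum(ok & g == levels(g)[1L] & call == 1),
      sum(ok & g == levels(g)[1L] & call == 0),
      sum(ok & g == levels(g)[2L] & call == 1),
      sum(ok & g == levels(g)[2L] & call == 0)
    ), nrow = 2L, byrow = TRUE)
    ft <- fisher_p_2x2(tab)
    tibble(position = as.integer(pos), a = tab[1L, 1L], b = tab[1L, 2L],
           c = tab[2L, 1L], d = tab[2L, 2L], p_value = ft$p,
           degenerate = ft$degenerate)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

# two-sided exact p for a 2x2 table; a zero margin is degenerate (only one
# table is possible) and reported as p = 1 without testing
fisher_p_2x2 <- function(tab) {
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  list(p = if (degenerate) 1 else fisher.test(tab)$p.value,
       degenerate = degenerate)
}

mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mw_exact_two_sided <- function(x, y) {
  # permutation enumeration of the U statistic under exchangeability,
  # valid with ties; two-sided by distance of U from its null mean
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  centre <- m * n / 2
  obs <- abs(mw_u_stat(x, y) - centre)
  idx <- combn(m + n, m)
  r <- rank(pooled)
  us <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
  mean(abs(us - centre) >= obs - 1e-9)
}

mw_normal_two_sided <- function(x, y) {
  m <- length(x); n <- length(y)
  u <- mw_u_stat(x, y)
  N <- m + n
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * (N + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - m * n / 2) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Mann-Whitney U test on per-site methylation between two clone sets
#'
#' Summarises each dataset to its per-site percent methylation and compares
#' the two percentage vectors across sites with the Mann-Whitney U test.
#' For a combined sample of at most 20 sites the p-value is exact, by full
#' enumeration of group assignments (valid under ties); above that a normal
#' approximation with tie correction is used. Sites whose percentage is
#' undefined (all calls missing) are dropped from the affected vector.
#'
#' @param ds_a,ds_b Two `meth_set` objects over the same CpG positions.
#' @param unit `"site"` (default; the per-site percentages are the sampling
#'   unit) or `"clone"` (per-clone percent across sites).
#' @return A one-row tibble: `statistic` (U for the first dataset),
#'   `p_value`, `n_a`, `n_b`, `exact`, `method`.
#' @export
mannwhitney_set_test <- function(ds_a, ds_b, unit = c("site", "clone")) {
  stopifnot(inherits(ds_a, "meth_set"), inherits(ds_b, "meth_set"))
  unit <- match.arg(unit)
  if (unit == "site" &&
      !identical(ds_a$cpg_positions, ds_b$cpg_positions)) {
    abort("the two datasets must share the same CpG positions",
          class = "methclones_input_error")
  }
  vec <- function(ds) {
    if (unit == "site") {
      methylation_summary(ds)$percent_methylated
    } else {
      r1 <- rowSums(ds$calls == 1, na.rm = TRUE)
      r0 <- rowSums(ds$calls == 0, na.rm = TRUE)
      ifelse(r1 + r0 > 0, 100 * r1 / (r1 + r0), NA_real_)
    }
  }
  x <- vec(ds_a); x <- x[!is.na(x)]
  y <- vec(ds_b); y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("need at least two informative units per group",
          class = "methclones_input_error")
  }
  exact <- length(x) + length(y) <= 20L
  p <- if (exact) mw_exact_two_sided(x, y) else mw_normal_two_sided(x, y)
  tibble(
    statistic = mw_u_stat(x, y),
    p_value = p,
    n_a = length(x),
    n_b = length(y),
    exact = exact,
    method = if (exact) "exact permutation enumeration"
             else "normal approximation with tie correction"
  )
}

#' Pairwise Hamming distances between binary patterns
#'
#' Distance between two rows (or columns) is the number of pairwise-complete
#' positions at which they disagree, divided by the number compared. A pair
#' with no comparable position is NA.
#'
#' @param mat Numeric matrix of 0/1/NA; distances are between rows.
#' @return A symmetric matrix of normalized distances with an `n_compared`
#'   attribute (matrix of comparison counts).
#' @export
hamming_distances <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  nc <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    nc[i, i] <- sum(!is.na(mat[i, ]))
    if (i < n) for (j in seq(i + 1L, n)) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      nc[i, j] <- nc[j, i] <- sum(ok)
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else NA_real_
    }
  }
  attr(d, "n_compared") <- nc
  d
}

#' Hierarchical biclustering of the methylation matrix
#'
#' Agglomerative clustering of clones and, independently, of CpG sites,
#' using the normalized Hamming distance appropriate for binary methylation
#' patterns. Clustering is refused when any pairwise distance is undefined
#' (no comparable positions). Note the column clustering ignores genomic
#' ordering of the sites.
#'
#' @param ds A `meth_set` with at least two clones and two sites.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"complete"`.
#' @return A `meth_biclust` object: `row_tree`, `col_tree` (hclust),
#'   `row_order` (clone ids, leaf order), `col_order` (positions, leaf
#'   order), `row_dist`, `col_dist`, `linkage`.
#' @export
hamming_bicluster <- function(ds, linkage = "complete") {
  stopifnot(inherits(ds, "meth_set"))
  if (nrow(ds$calls) < 2L || ncol(ds$calls) < 2L) {
    abort("biclustering needs at least two clones and two sites",
          class = "methclones_input_error")
  }
  dr <- hamming_distances(ds$calls)
  dc <- hamming_distances(t(ds$calls))
  if (anyNA(dr[upper.tri(dr)]) || anyNA(dc[upper.tri(dc)])) {
    abort(paste0("distance matrix not fully defined: some pairs share no ",
                 "comparable position"),
          class = "methclones_input_error")
  }
  row_tree <- hclust(as.dist(dr), method = linkage)
  col_tree <- hclust(as.dist(dc), method = linkage)
  structure(
    list(row_tree = row_tree, col_tree = col_tree,
         row_order = ds$clone_ids[row_tree$order],
         col_order = ds$cpg_positions[col_tree$order],
         row_dist = dr, col_dist = dc, linkage = linkage),
    class = "meth_biclust"
  )
}

#' @export
print.meth_biclust <- function(x, ...) {
  cat("<meth_biclust> linkage=", x$linkage, "\n  clone order: ",
      paste(x$row_order, collapse = ", "), "\n  site order:  ",
      paste(x$col_order, collapse = ", "), "\n", sep = "")
  invisible(x)
}
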