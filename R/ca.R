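#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Correspondence analysis of the methylation matrix
#'
#' Decomposes the clone-by-CpG table under the chi-square metric: with
#' `P = X / n` (n the grand total), row masses `r` and column masses `c`,
#' the standardized residuals `S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}` are
#' factored by singular value decomposition. Principal inertias are the
#' squared singular values, summing to the total inertia `chi^2 / n`; row
#' and column principal coordinates are the mass-rescaled singular vectors
#' scaled by the singular values. Sites and clones with similar profiles
#' project in similar directions of the resulting biplot.
#'
#' The matrix is used as the raw 0/1 indicator table; duplicate clones are
#' retained (they carry mass). All-zero rows/columns have no mass and are
#' dropped with a warning. Dimensions with `lambda < 1e-12 * lambda_max`
#' are treated as numerically null and excluded.
#'
#' @param x A `meth_set`, or a non-negative numeric matrix.
#' @param na_action How to handle missing calls when `x` is a `meth_set`:
#'   `"omit_clones"` (default) drops clones with any missing call, with a
#'   warning; `"as_unmethylated"` treats missing as 0.
#' @return A `meth_ca` object: `row_coords`, `col_coords` (principal
#'   coordinates, named rows), `principal_inertias`, `percent_inertia`
#'   (sums to 100), `total_inertia` (chi-square statistic / n), `n_dim`.
#' @examples
#' m <- rbind(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0),
#'            c(0, 0, 1, 1, 0), c(0, 0, 1, 1, 1))
#' ca <- correspondence_analysis(meth_set(m, c(7, 32, 48, 55, 73)))
#' round(ca$percent_inertia, 2)
#' @export
correspondence_analysis <- function(x, na_action = c("omit_clones",
                                                     "as_unmethylated")) {
  na_action <- match.arg(na_action)
  if (inherits(x, "meth_set")) {
    m <- x$calls
    if (anyNA(m)) {
      if (na_action == "omit_clones") {
        drop <- apply(is.na(m), 1L, any)
        warn(paste0("dropping ", sum(drop),
                    " clone(s) with missing calls before CA: ",
                    paste(rownames(m)[drop], collapse = ", ")))
        m <- m[!drop, , drop = FALSE]
      } else {
        m[is.na(m)] <- 0
      }
    }
  } else {
    m <- as.matrix(x)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  if (!is.numeric(m) || any(m < 0)) {
    abort("correspondence analysis needs a non-negative numeric matrix",
          class = "methclones_input_error")
  }
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warn(paste0("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
                " all-zero column(s): they carry no mass"))
    m <- m[!zr, !zc, drop = FALSE]
  }
  n <- sum(m)
  if (n <= 0 || nrow(m) < 2L || ncol(m) < 2L) {
    abort("correspondence analysis needs a matrix with positive total and at least 2x2 support",
          class = "methclones_input_error")
  }
  P <- m / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  dec <- svd(S)
  lam <- dec$d^2
  kmax <- min(nrow(m), ncol(m)) - 1L
  lam <- lam[seq_len(kmax)]
  if (length(lam) == 0L || max(lam) < 1e-12) {
    # independence structure: nothing beyond the trivial dimension
    zero_rows <- matrix(numeric(0), nrow(m), 0, dimnames = list(rownames(m), NULL))
    zero_cols <- matrix(numeric(0), ncol(m), 0, dimnames = list(colnames(m), NULL))
    return(structure(
      list(row_coords = zero_rows, col_coords = zero_cols,
           principal_inertias = numeric(0), percent_inertia = numeric(0),
           total_inertia = 0, n_dim = 0L),
      class = "meth_ca"))
  }
  k <- max(which(lam >= 1e-12 * max(lam)))
  sig <- dec$d[seq_len(k)]
  row_coords <- diag(1 / sqrt(r)) %*% dec$u[, seq_len(k), drop = FALSE] %*%
    diag(sig, k, k)
  col_coords <- diag(1 / sqrt(cm)) %*% dec$v[, seq_len(k), drop = FALSE] %*%
    diag(sig, k, k)
  dimnames(row_coords) <- list(rownames(m), paste0("Dim", seq_len(k)))
  dimnames(col_coords) <- list(colnames(m), paste0("Dim", seq_len(k)))
  lam <- lam[seq_len(k)]
  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         principal_inertias = lam,
         percent_inertia = 100 * lam / sum(lam),
         total_inertia = sum(lam),
         n_dim = k),
    class = "meth_ca"
  )
}

#' @export
print.meth_ca <- function(x, ...) {
  cat("<meth_ca> ", nrow(x$row_coords), " clone(s) x ", nrow(x$col_coords),
      " site(s), ", x$n_dim, " dimension(s)\n", sep = "")
  cat("  total inertia (chi2/n): ", format(x$total_inertia, digits = 6), "\n",
      "  percent inertia: ",
      paste(sprintf("%.2f%%", x$percent_inertia), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn correspondence_analysis One row per clone or site with its
#'   principal coordinates (`type` is `"clone"` or `"site"`).
#' @param ... Unused.
#' @export
tidy.meth_ca <- function(x, ...) {
  coords_tbl <- function(m, type) {
    df <- as_tibble(m)
    df$id <- rownames(m)
    df$type <- type
    df[c("type", "id", setdiff(names(df), c("type", "id")))]
  }
  dplyr::bind_rows(coords_tbl(x$row_coords, "clone"),
                   coords_tbl(x$col_coords, "site"))
}

#' @describeIn correspondence_analysis One-row summary: total inertia,
#'   number of dimensions, percent inertia of the first two components.
#' @export
glance.meth_ca <- function(x, ...) {
  tibble(
    total_inertia = x$total_inertia,
    n_dim = x$n_dim,
    percent_inertia_1 = x$percent_inertia[1L],
    percent_inertia_2 = if (x$n_dim >= 2L) x$percent_inertia[2L] else NA_real_
  )
}

#' Export a correspondence analysis result
#'
#' @param ca A `meth_ca`.
#' @param coords_tsv Optional TSV path for the tidy coordinate table.
#' @param inertia_json Optional JSON path for inertias and percentages.
#' @return `ca`, invisibly.
#' @export
export_ca <- function(ca, coords_tsv = NULL, inertia_json = NULL) {
  if (!is.null(coords_tsv)) write_tsv_plain(tidy(ca), coords_tsv)
  if (!is.null(inertia_json)) {
    jsonlite::write_json(
      list(principal_inertias = ca$principal_inertias,
           percent_inertia = ca$percent_inertia,
           total_inertia = ca$total_inertia),
      inertia_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(ca)
}
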