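#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_tile
#'   geom_text scale_fill_gradient2 scale_fill_manual scale_shape_manual
#'   scale_colour_manual labs theme_minimal theme element_blank element_text
#'   coord_fixed scale_y_continuous scale_x_continuous ggsave
#' @export
ggplot2::autoplot

#' Lollipop layout for a methylation dataset
#'
#' Computes the full glyph-state layout of the lollipop display without
#' rendering it: one row of circles per clone (filled = methylated, empty =
#' unmethylated, absent = not covered), a summary row whose dots are filled
#' in proportion to the percent of methylated clones, and connecting-line
#' weights that grow monotonically with the absolute neighbouring
#' co-occurrence. Rendering ([autoplot()] / [plot_lollipop()]) is a thin
#' final step over this object, so tests can assert the layout exactly.
#'
#' @param ds A `meth_set`.
#' @param summary Optional precomputed [methylation_summary()] (never
#'   recomputed when given).
#' @param neighbour_corr Optional precomputed [cooccurrence()] object used
#'   for the connecting-line weights.
#' @param mode `"genomic"` (x is an affine map of base-pair position) or
#'   `"equidistant"` (equal spacing).
#' @return A `lollipop_layout`: tibbles `glyphs` (clone_id, position, x, y,
#'   state), `summary_row` (position, x, fill_fraction, n_called) and
#'   `segments` (from, to, x, xend, value, weight), plus `mode`.
#' @export
lollipop_layout <- function(ds, summary = NULL, neighbour_corr = NULL,
                            mode = c("genomic", "equidistant")) {
  stopifnot(inherits(ds, "meth_set"))
  mode <- match.arg(mode)
  k <- length(ds$cpg_positions)
  if (k == 0L) {
    abort("cannot lay out a dataset with zero CpG sites",
          class = "methclones_input_error")
  }
  summary <- summary %||% methylation_summary(ds)
  x <- if (mode == "genomic") as.numeric(ds$cpg_positions) else
    as.numeric(seq_len(k))
  n <- length(ds$clone_ids)
  glyphs <- tibble(
    clone_id = rep(ds$clone_ids, each = k),
    position = rep(ds$cpg_positions, times = n),
    x = rep(x, times = n),
    y = rep(rev(seq_len(n)), each = k),
    state = dplyr::case_when(
      is.na(as.vector(t(ds$calls))) ~ "absent",
      as.vector(t(ds$calls)) == 1 ~ "filled",
      TRUE ~ "empty"
    )
  )
  summary_row <- tibble(
    position = ds$cpg_positions,
    x = x,
    fill_fraction = summary$percent_methylated / 100,
    n_called = summary$n_methylated + summary$n_unmethylated
  )
  segments <- NULL
  if (k >= 2L) {
    nb <- if (!is.null(neighbour_corr)) neighbour_values(neighbour_corr) else
      if (n >= 2L) neighbour_values(cooccurrence(ds)) else
        tibble(from = ds$cpg_positions[-k], to = ds$cpg_positions[-1L],
               value = NA_real_, n_pairs = 0L)
    x_from <- x[match(nb$from, ds$cpg_positions)]
    x_to <- x[match(nb$to, ds$cpg_positions)]
    segments <- tibble(
      from = nb$from, to = nb$to,
      x = x_from,
      xend = x_to,
      value = nb$value,
      # any monotone map of |value| qualifies as a line weight
      weight = ifelse(is.na(nb$value), 0.25, 0.25 + 2.25 * abs(nb$value))
    )
  }
  structure(list(glyphs = glyphs, summary_row = summary_row,
                 segments = segments, mode = mode,
                 clone_ids = ds$clone_ids),
            class = "lollipop_layout")
}

#' @export
print.lollipop_layout <- function(x, ...) {
  cat("<lollipop_layout> ", length(x$clone_ids), " clone row(s) x ",
      nrow(x$summary_row), " site(s), mode=", x$mode, "\n", sep = "")
  invisible(x)
}

#' @describeIn lollipop_layout Render the layout with ggplot2.
#' @param object A `lollipop_layout`.
#' @param ... Unused.
#' @export
autoplot.lollipop_layout <- function(object, ...) {
  gl <- object$glyphs[object$glyphs$state != "absent", , drop = FALSE]
  ns <- length(object$clone_ids)
  sumy <- ns + 1.5
  p <- ggplot() +
    geom_segment(
      data = tibble(y = c(rev(seq_len(ns)), sumy),
                    x = min(object$summary_row$x),
                    xend = max(object$summary_row$x)),
      aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$y),
      colour = "grey80", linewidth = 0.3)
  if (!is.null(object$segments)) {
    p <- p + geom_segment(
      data = object$segments,
      aes(x = .data$x, xend = .data$xend, y = sumy, yend = sumy,
          linewidth = .data$weight),
      colour = "grey30", show.legend = FALSE) +
      ggplot2::scale_linewidth_identity()
  }
  p <- p +
    geom_point(data = gl,
               aes(x = .data$x, y = .data$y, fill = .data$state),
               shape = 21, size = 3, colour = "black", show.legend = FALSE) +
    scale_fill_manual(values = c(filled = "black", empty = "white")) +
    geom_point(data = object$summary_row,
               aes(x = .data$x, y = sumy, alpha = .data$fill_fraction),
               shape = 21, size = 5, colour = "black", fill = "black",
               show.legend = FALSE) +
    geom_text(data = tibble(x = object$summary_row$x,
                            lab = object$summary_row$position),
              aes(x = .data$x, y = 0.2, label = .data$lab), size = 2.7) +
    scale_y_continuous(
      breaks = c(rev(seq_len(ns)), sumy),
      labels = c(object$clone_ids, "summary")) +
    labs(x = if (object$mode == "genomic") "reference position (bp)" else
           "CpG site index", y = NULL) +
    theme_minimal() +
    theme(panel.grid = element_blank())
  p
}

#' Lollipop plot of per-clone methylation states
#'
#' @inheritParams lollipop_layout
#' @param file Optional output path (`.png` or `.svg`); when given the plot
#'   is also written to disk.
#' @param width,height Device size in inches for `file` output.
#' @return The ggplot object, invisibly when `file` is written.
#' @export
plot_lollipop <- function(ds, summary = NULL, neighbour_corr = NULL,
                          mode = c("genomic", "equidistant"), file = NULL,
                          width = 7, height = 4) {
  p <- autoplot(lollipop_layout(ds, summary, neighbour_corr, mode))
  save_or_return(p, file, width, height)
}

save_or_return <- function(p, file, width, height) {
  if (!is.null(file)) {
    ggsave(file, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' @describeIn cooccurrence Heatmap of the co-occurrence matrix: colour-coded
#'   values, genomic positions printed on the diagonal, missing-flagged
#'   cells in neutral grey.
#' @param object A `meth_cooc`.
#' @param ... Unused.
#' @export
autoplot.meth_cooc <- function(object, ...) {
  k <- length(object$positions)
  long <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k))
  long$value <- object$values[cbind(long$i, long$j)]
  long$label <- ifelse(long$i == long$j, as.character(object$positions[long$i]), "")
  long$value[long$i == long$j] <- NA_real_   # diagonal carries the position label
  lim <- if (object$mode == "correlation") c(-1, 1) else c(0, 1)
  ggplot(long, aes(x = .data$j, y = .data$i, fill = .data$value)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$label), size = 3) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = if (object$mode == "correlation") 0 else 0.5,
                         limits = lim, na.value = "grey85",
                         name = object$mode) +
    scale_y_continuous(trans = "reverse", breaks = NULL) +
    scale_x_continuous(breaks = NULL) +
    labs(x = NULL, y = NULL) +
    coord_fixed() +
    theme_minimal()
}

#' Co-occurrence matrix display
#'
#' @param m A `meth_cooc` from [cooccurrence()].
#' @inheritParams plot_lollipop
#' @return The ggplot object.
#' @export
plot_cooccurrence_matrix <- function(m, file = NULL, width = 5, height = 4.5) {
  save_or_return(autoplot(m), file, width, height)
}

#' @describeIn correspondence_analysis Biplot of the first two principal
#'   coordinates: red triangles mark CpG sites, black bullets mark clones;
#'   axis labels carry the percent inertia to two decimals.
#' @param object A `meth_ca`.
#' @export
autoplot.meth_ca <- function(object, ...) {
  td <- tidy(object)
  if (!"Dim2" %in% names(td)) td$Dim2 <- 0   # rank-1 input: strip plot
  lab1 <- sprintf("Dim 1 (%.2f%%)", object$percent_inertia[1L])
  lab2 <- if (object$n_dim >= 2L)
    sprintf("Dim 2 (%.2f%%)", object$percent_inertia[2L]) else ""
  ggplot(td, aes(x = .data$Dim1, y = .data$Dim2, shape = .data$type,
                 colour = .data$type)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    geom_point(size = 3) +
    geom_text(aes(label = .data$id), vjust = -1, size = 3,
              show.legend = FALSE) +
    scale_shape_manual(values = c(clone = 16, site = 17)) +
    scale_colour_manual(values = c(clone = "black", site = "red")) +
    labs(x = lab1, y = lab2, shape = NULL, colour = NULL) +
    theme_minimal()
}

#' Correspondence analysis biplot
#'
#' @param ca A `meth_ca` from [correspondence_analysis()].
#' @inheritParams plot_lollipop
#' @return The ggplot object.
#' @export
plot_ca_biplot <- function(ca, file = NULL, width = 5.5, height = 5) {
  save_or_return(autoplot(ca), file, width, height)
}

# (x, y) segment coordinates of an hclust tree, leaves at 1..n in leaf order
dendro_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- match(seq_len(n), hc$order)
  xpos <- numeric(nrow(hc$merge))
  segs <- vector("list", nrow(hc$merge))
  node_x <- function(v) if (v < 0) leaf_x[-v] else xpos[v]
  node_h <- function(v) if (v < 0) 0 else hc$height[v]
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1L]; b <- hc$merge[m, 2L]
    xa <- node_x(a); xb <- node_x(b)
    ha <- node_h(a); hb <- node_h(b)
    h <- hc$height[m]
    xpos[m] <- (xa + xb) / 2
    segs[[m]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(ha, hb, h), yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}

#' Clustered heatmap of the methylation matrix
#'
#' Renders the ternary matrix reordered by the row and column dendrograms of
#' a [hamming_bicluster()] result, with marginal dendrograms and a
#' three-colour scheme (methylated / unmethylated / missing).
#'
#' @param ds The `meth_set` the clustering was computed on.
#' @param bic A `meth_biclust` over the same dataset; NULL (e.g. for a
#'   single clone) renders the matrix unclustered without dendrograms.
#' @inheritParams plot_lollipop
#' @return A ggplot (patchwork-combined when dendrograms are drawn).
#' @export
plot_cluster_heatmap <- function(ds, bic = NULL, file = NULL,
                                 width = 6, height = 5) {
  stopifnot(inherits(ds, "meth_set"))
  if (!is.null(bic)) {
    if (!identical(sort(bic$row_order), sort(ds$clone_ids)) ||
        !identical(sort(bic$col_order), sort(ds$cpg_positions))) {
      abort("clustering result does not match the dataset",
            class = "methclones_input_error")
    }
    mat <- ds$calls[match(bic$row_order, ds$clone_ids),
                    match(bic$col_order, ds$cpg_positions), drop = FALSE]
  } else {
    mat <- ds$calls
  }
  long <- tidyr::expand_grid(i = seq_len(nrow(mat)), j = seq_len(ncol(mat)))
  long$state <- dplyr::case_when(
    is.na(mat[cbind(long$i, long$j)]) ~ "missing",
    mat[cbind(long$i, long$j)] == 1 ~ "methylated",
    TRUE ~ "unmethylated"
  )
  hm <- ggplot(long, aes(x = .data$j, y = .data$i, fill = .data$state)) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = c(methylated = "lightyellow",
                                 unmethylated = "firebrick",
                                 missing = "grey80"), name = NULL) +
    scale_y_continuous(trans = "reverse", breaks = seq_len(nrow(mat)),
                       labels = rownames(mat)) +
    scale_x_continuous(breaks = seq_len(ncol(mat)), labels = colnames(mat)) +
    labs(x = "CpG position", y = NULL) +
    theme_minimal() +
    theme(panel.grid = element_blank(),
          axis.text.x = element_text(angle = 90, vjust = 0.5))
  p <- hm
  if (!is.null(bic) && requireNamespace("patchwork", quietly = TRUE)) {
    coltree <- ggplot(dendro_segments(bic$col_tree)) +
      geom_segment(aes(x = .data$x, xend = .data$xend, y = .data$y,
                       yend = .data$yend)) +
      ggplot2::theme_void()
    rowtree <- ggplot(dendro_segments(bic$row_tree)) +
      geom_segment(aes(x = .data$y, xend = .data$yend, y = .data$x,
                       yend = .data$xend)) +
      scale_y_continuous(trans = "reverse") +
      scale_x_continuous(trans = "reverse") +
      ggplot2::theme_void()
    p <- patchwork::wrap_plots(
      patchwork::plot_spacer(), coltree, rowtree, hm,
      ncol = 2L, widths = c(1, 4), heights = c(1, 4))
  }
  save_or_return(p, file, width, height)
}
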