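# Tables and figures: count tables, pivots, histogram, Venn/pseudo-Venn,
# clustergram, precision-recall scatter.  Every figure writes a PNG plus a
# CSV sibling of its underlying numbers, so figures are never the only
# record of a result.

#' Styling options for figures
#'
#' @param color_by optional metadata column driving marker colors (PR plot)
#'   or label colors (clustergram).
#' @param shape_by optional metadata column driving marker shapes; only
#'   meaningful for PR plots.
#' @param font_size base font size in points.
#' @param colormap heatmap palette name: one of `"viridis"`, `"magma"`,
#'   `"heat"`, `"blue-red"`.
#' @param pseudo_venn use the cyclic pseudo-Venn layout; only valid for 6
#'   sets.
#' @return A `StyleSpec` list.
#' @export
style_spec <- function(color_by = NULL, shape_by = NULL, font_size = 12,
                       colormap = "viridis", pseudo_venn = FALSE) {
  if (!is.numeric(font_size) || font_size <= 0)
    stop("font_size must be a positive number")
  colormap <- match.arg(colormap, c("viridis", "magma", "heat", "blue-red"))
  structure(list(color_by = color_by, shape_by = shape_by,
                 font_size = font_size, colormap = colormap,
                 pseudo_venn = isTRUE(pseudo_venn)),
            class = "StyleSpec")
}

heat_palette <- function(name, n = 100) {
  switch(name,
         viridis = grDevices::hcl.colors(n, "viridis"),
         magma = grDevices::hcl.colors(n, "magma"),
         heat = grDevices::hcl.colors(n, "heat colors", rev = TRUE),
         `blue-red` = grDevices::colorRampPalette(
           c("#2166AC", "#F7F7F7", "#B2182B"))(n))
}

csv_sibling <- function(png_path) {
  paste0(tools::file_path_sans_ext(png_path), ".csv")
}

#' Variant counts per call set or group, descending
#'
#' @param items list of `CallSet`s and/or `VariantGroup`s.
#' @return A data.frame (`name`, `n_variants`) sorted by count, descending;
#'   ties keep input order.
#' @export
count_table <- function(items) {
  nm <- vapply(items, function(x)
    if (inherits(x, "VariantGroup")) x$label else x$name, "")
  n <- vapply(items, function(x)
    if (inherits(x, "VariantGroup")) n_variants(x$pooled)
    else n_variants(x), 0L)
  df <- data.frame(name = nm, n_variants = n, stringsAsFactors = FALSE)
  df[order(-df$n_variants), , drop = FALSE]  # base order() is stable
}

#' Pivot pooled group counts into a two-dimensional table
#'
#' Rows are the distinct value tuples of `row_columns`, columns those of
#' `col_columns`; each cell holds the pooled variant count of the matching
#' group. Combinations with no group are left empty (`NA`).
#'
#' @param groups list of `VariantGroup`s whose group_by columns cover
#'   `row_columns` and `col_columns`.
#' @param row_columns,col_columns disjoint character vectors of metadata
#'   property columns.
#' @return A numeric matrix with labeled dimnames.
#' @export
pivot_counts <- function(groups, row_columns, col_columns) {
  if (length(intersect(row_columns, col_columns)) > 0)
    stop("row_columns and col_columns must be disjoint")
  key_cols <- names(groups[[1]]$key)
  missing <- setdiff(c(row_columns, col_columns), key_cols)
  if (length(missing) > 0)
    stop(sprintf("column(s) not used in grouping: %s",
                 paste(missing, collapse = ", ")))
  rkey <- vapply(groups, function(g) paste(g$key[row_columns],
                                           collapse = " & "), "")
  ckey <- vapply(groups, function(g) paste(g$key[col_columns],
                                           collapse = " & "), "")
  rlev <- withr::with_collate("C", sort(unique(rkey)))
  clev <- withr::with_collate("C", sort(unique(ckey)))
  m <- matrix(NA_real_, length(rlev), length(clev),
              dimnames = list(rlev, clev))
  ri <- match(rkey, rlev); ci <- match(ckey, clev)
  for (i in seq_along(groups)) {
    if (!is.na(m[ri[i], ci[i]]))
      stop(sprintf("pivot cell (%s, %s) matches more than one group",
                   rkey[i], ckey[i]))
    m[ri[i], ci[i]] <- n_variants(groups[[i]]$pooled)
  }
  m
}

#' Render a variant-count histogram
#'
#' Bar chart of per-set variant counts in descending order, with a CSV
#' sibling of the plotted numbers.
#'
#' @param counts a [count_table()] data.frame.
#' @param path output PNG path.
#' @param style a [style_spec()].
#' @return Invisibly, the paths written (`png`, `csv`).
#' @export
render_histogram <- function(counts, path, style = style_spec()) {
  counts$name <- factor(counts$name, levels = counts$name)
  p <- ggplot2::ggplot(counts,
                       ggplot2::aes(x = .data$name, y = .data$n_variants)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = NULL, y = "variants") +
    ggplot2::theme_bw(base_size = style$font_size) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)
  csv <- csv_sibling(path)
  write_table_csv(counts, csv)
  invisible(list(png = path, csv = csv))
}

# ---- Venn rendering ---------------------------------------------------------
#
# Layouts are circles (2-3 sets) and the classic rotated-ellipse arrangements
# (4-5 sets).  For 6 sets a cyclic ring of circles is drawn: a true 6-set
# Venn of convex curves cannot show all 63 regions legibly, so the figure
# labels only the regions the layout realizes while the full tally always
# goes to the CSV sibling.  Region label positions are found numerically: a
# grid over the canvas is classified by membership pattern and each label
# sits at its pattern's centroid.

venn_shapes <- function(k, pseudo = FALSE) {
  ellipse <- function(cx, cy, w, h, ang) {
    list(cx = cx, cy = cy, a = w / 2, b = h / 2, ang = ang * pi / 180)
  }
  if (k == 2) {
    list(ellipse(0.40, 0.5, 0.65, 0.65, 0), ellipse(0.60, 0.5, 0.65, 0.65, 0))
  } else if (k == 3) {
    ang <- c(90, 210, 330) * pi / 180
    lapply(ang, function(a)
      ellipse(0.5 + 0.16 * cos(a), 0.5 + 0.16 * sin(a), 0.62, 0.62, 0))
  } else if (k == 4) {
    list(ellipse(0.350, 0.400, 0.72, 0.45, 140),
         ellipse(0.450, 0.500, 0.72, 0.45, 140),
         ellipse(0.544, 0.500, 0.72, 0.45, 40),
         ellipse(0.644, 0.400, 0.72, 0.45, 40))
  } else if (k == 5) {
    list(ellipse(0.428, 0.449, 0.87, 0.50, 155),
         ellipse(0.469, 0.543, 0.87, 0.50, 82),
         ellipse(0.558, 0.523, 0.87, 0.50, 10),
         ellipse(0.578, 0.432, 0.87, 0.50, 118),
         ellipse(0.489, 0.383, 0.87, 0.50, 46))
  } else {
    # cyclic ring, also used for pseudo-Venn
    ang <- (90 - 60 * (0:5)) * pi / 180
    lapply(ang, function(a)
      ellipse(0.5 + 0.18 * cos(a), 0.5 + 0.18 * sin(a), 0.55, 0.55, 0))
  }
}

in_ellipse <- function(x, y, e) {
  dx <- x - e$cx; dy <- y - e$cy
  u <- dx * cos(-e$ang) - dy * sin(-e$ang)
  v <- dx * sin(-e$ang) + dy * cos(-e$ang)
  (u / e$a)^2 + (v / e$b)^2 <= 1
}

ellipse_outline <- function(e, n = 200) {
  t <- seq(0, 2 * pi, length.out = n)
  u <- e$a * cos(t); v <- e$b * sin(t)
  list(x = e$cx + u * cos(e$ang) - v * sin(e$ang),
       y = e$cy + u * sin(e$ang) + v * cos(e$ang))
}

# centroid of every realized membership pattern on a grid
venn_label_positions <- function(shapes, grid_n = 301) {
  g <- seq(0, 1, length.out = grid_n)
  pts <- expand.grid(x = g, y = g)
  member <- vapply(shapes, function(e) in_ellipse(pts$x, pts$y, e),
                   logical(nrow(pts)))
  mask <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  inside <- mask != paste(rep("0", length(shapes)), collapse = "")
  stats::aggregate(pts[inside, ], by = list(pattern = mask[inside]), mean)
}

#' Render a Venn (or pseudo-Venn) diagram
#'
#' Draws the overlap of 2 to 6 sets; each displayed region is labeled with
#' its variant count and the percentage of the union it represents, in
#' parentheses. The complete tally (all `2^k - 1` patterns) is always written
#' to the CSV sibling; for 6 sets the drawing realizes only a subset of the
#' 63 regions, so labels cover the displayed subset.
#'
#' @param tally a [venn_tally()].
#' @param path output PNG path.
#' @param style a [style_spec()]; `pseudo_venn = TRUE` requires 6 sets.
#' @return Invisibly, the paths written (`png`, `csv`).
#' @export
render_venn <- function(tally, path, style = style_spec()) {
  k <- length(tally$set_names)
  if (style$pseudo_venn && k != 6)
    stop("pseudo_venn is only valid for 6 sets")
  shapes <- venn_shapes(k, style$pseudo_venn)
  pal <- grDevices::hcl.colors(k, "Dark 3")
  labels <- venn_label_positions(shapes)
  counts <- stats::setNames(tally$patterns$count, tally$patterns$pattern)
  pct <- stats::setNames(tally$patterns$percentage, tally$patterns$pattern)
  grDevices::png(path, width = 900, height = 800, res = 120)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, 1.05), asp = 1,
       axes = FALSE, xlab = "", ylab = "")
  for (i in seq_len(k)) {
    o <- ellipse_outline(shapes[[i]])
    graphics::polygon(o$x, o$y,
                      col = grDevices::adjustcolor(pal[i], alpha.f = 0.25),
                      border = pal[i], lwd = 2)
  }
  cex <- style$font_size / 12
  for (r in seq_len(nrow(labels))) {
    pat <- labels$pattern[r]
    if (!pat %in% names(counts)) next
    graphics::text(labels$x[r], labels$y[r],
                   sprintf("%d (%.1f%%)", counts[pat], 100 * pct[pat]),
                   cex = 0.8 * cex)
  }
  # set names just outside each shape, pushed away from the canvas center
  for (i in seq_len(k)) {
    e <- shapes[[i]]
    dx <- e$cx - 0.5; dy <- e$cy - 0.5
    nrm <- max(sqrt(dx^2 + dy^2), 1e-6)
    r_out <- max(e$a, e$b) + 0.04
    graphics::text(0.5 + dx / nrm * (nrm + r_out) * 0.92,
                   0.5 + dy / nrm * (nrm + r_out) * 0.92,
                   tally$set_names[i], col = pal[i], font = 2, cex = cex)
  }
  graphics::title(sprintf("Variant overlap (%d sets, union %d)",
                          k, tally$total), cex.main = cex)
  csv <- csv_sibling(path)
  write_table_csv(tally$patterns, csv)
  invisible(list(png = path, csv = csv))
}

#' Render a clustergram (heatmap with dendrograms)
#'
#' Heatmap of pairwise Jaccard similarities with rows and columns in the
#' clustering leaf order and dendrograms from the merge list. Row labels can
#' be color-coded by metadata columns.
#'
#' @param m a [jaccard_matrix()].
#' @param order a [cluster_order()] result for `m`.
#' @param path output PNG path.
#' @param style a [style_spec()]; `colormap` selects the palette.
#' @param annotations optional data.frame of label properties (one row per
#'   matrix label, rownames = labels) used to color-code rows and columns.
#' @return Invisibly, the paths written (`png`, `csv`).
#' @export
render_clustergram <- function(m, order = cluster_order(m), path,
                               style = style_spec(), annotations = NULL) {
  mat <- unclass(m)
  args <- list(mat = mat, cluster_rows = order$hclust,
               cluster_cols = order$hclust,
               color = heat_palette(style$colormap),
               fontsize = style$font_size,
               filename = path, silent = TRUE)
  if (!is.null(annotations)) {
    args$annotation_row <- annotations
    args$annotation_col <- annotations
  }
  do.call(pheatmap::pheatmap, args)
  csv <- csv_sibling(path)
  write_table_csv(mat, csv)
  invisible(list(png = path, csv = csv))
}

#' Render a precision-recall scatter plot
#'
#' One marker per benchmark result, precision on the x-axis and recall on the
#' y-axis, both in \[0, 1\]. Marker colors and shapes can follow metadata
#' columns so performance patterns across categories are visible on one plot.
#'
#' @param results list of `BenchmarkResult`s.
#' @param path output PNG path.
#' @param style a [style_spec()]; `color_by`/`shape_by` name metadata columns.
#' @param meta optional `MetadataTable` supplying the style columns, matched
#'   to results by name against `FILENAME`.
#' @return Invisibly, the paths written (`png`, `csv`).
#' @export
render_pr_plot <- function(results, path, style = style_spec(),
                           meta = NULL) {
  df <- benchmark_table(results)
  for (col in c(style$color_by, style$shape_by)) {
    if (is.null(meta) || !col %in% names(meta))
      stop(sprintf("style column '%s' is not a metadata column", col))
    df[[col]] <- meta[[col]][match(df$name, meta$FILENAME)]
  }
  aes_args <- list(x = quote(.data$precision), y = quote(.data$recall))
  if (!is.null(style$color_by))
    aes_args$colour <- str2lang(sprintf(".data$`%s`", style$color_by))
  if (!is.null(style$shape_by))
    aes_args$shape <- str2lang(sprintf(".data$`%s`", style$shape_by))
  p <- ggplot2::ggplot(df, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "precision", y = "recall",
                  colour = style$color_by, shape = style$shape_by) +
    ggplot2::theme_bw(base_size = style$font_size)
  ggplot2::ggsave(path, p, width = 6.5, height = 5.5, dpi = 120)
  csv <- csv_sibling(path)
  write_table_csv(df, csv)
  invisible(list(png = path, csv = csv))
}
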