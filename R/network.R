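#' Colour bin of a connected cell pair
#'
#' Significant cell pairs are binned by correlation strength for display:
#' green for R in 0.25--0.5, yellow for 0.5--0.75, red for 0.75--1.0.
#' Boundary values (0.5, 0.75) go to the upper bin (half-open intervals,
#' closed above). Values within 1e-9 above 1 are treated as numeric noise and
#' clipped to 1 before binning.
#'
#' @param r numeric vector of correlation coefficients, each `> 0.25` and
#'   `<= 1`.
#' @return A character vector over `"green"`, `"yellow"`, `"red"`.
#' @examples
#' classify_edge_bin(c(0.30, 0.60, 0.80))
#' @export
classify_edge_bin <- function(r) {
  if (!is.numeric(r) || anyNA(r)) stopf("`r` must be numeric without NAs")
  r <- ifelse(r > 1 & r <= 1 + 1e-9, 1, r)
  if (any(r <= 0.25) || any(r > 1)) {
    stopf("edge correlations must lie in (0.25, 1]; got %s",
          paste(signif(r[r <= 0.25 | r > 1], 4), collapse = ", "))
  }
  ifelse(r < 0.5, "green", ifelse(r < 0.75, "yellow", "red"))
}

#' Build a thresholded connectivity graph
#'
#' Applies the edge rule: a cell pair is connected iff its correlation
#' exceeds `r_min` (strictly) and its bootstrap significance is below `alpha`
#' (strictly). Each edge is colour-binned by [classify_edge_bin()].
#'
#' @param corr a `correlation_result` from [bootstrap_pvalues()].
#' @param coords data frame `cell_id, x, y` of ROI coordinates sharing
#'   `corr`'s cell ids, or `NULL` for a coordinate-free graph (the line map
#'   cannot be plotted then).
#' @param r_min correlation threshold; default 0.25.
#' @param alpha significance threshold; default 0.001.
#' @return An object of class `connectivity_graph`: a list with `nodes`
#'   (data frame `cell_id, x, y`), `edges` (data frame
#'   `cell_a, cell_b, r, p, bin`), and `thresholds`.
#' @examples
#' sim <- simulate_islet(islet_sim_spec(n_cells = 8, n_frames = 120, seed = 5))
#' tm <- normalise_f0(sim$traces, 30)
#' corr <- suppressWarnings(bootstrap_pvalues(tm, n_boot = 1000, seed = 5))
#' g <- build_graph(corr, sim$coords)
#' g
#' @export
build_graph <- function(corr, coords = NULL, r_min = 0.25, alpha = 0.001) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!is_number(r_min) || !is_number(alpha) || alpha <= 0 || alpha > 1) {
    stopf("`r_min` must be a number and `alpha` in (0, 1]")
  }
  if (is.null(coords)) {
    nodes <- data.frame(cell_id = corr$cell_ids, x = NA_real_, y = NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("cell_id", "x", "y") %in% names(coords)))
    only_corr <- setdiff(corr$cell_ids, coords$cell_id)
    only_coords <- setdiff(coords$cell_id, corr$cell_ids)
    if (length(only_corr) || length(only_coords)) {
      stopf("cell ids differ between correlations and coordinates: %s",
            paste(c(sprintf("missing coordinates for %s", only_corr),
                    sprintf("no traces for %s", only_coords)),
                  collapse = "; "))
    }
    nodes <- coords[match(corr$cell_ids, coords$cell_id),
                    c("cell_id", "x", "y")]
    rownames(nodes) <- NULL
  }
  ut <- which(upper.tri(corr$R), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  r <- corr$R[ut]
  p <- corr$P[ut]
  keep <- r > r_min & p < alpha
  edges <- data.frame(cell_a = corr$cell_ids[ut[keep, 1L]],
                      cell_b = corr$cell_ids[ut[keep, 2L]],
                      r = r[keep], p = p[keep],
                      stringsAsFactors = FALSE)
  edges$bin <- if (nrow(edges)) classify_edge_bin(edges$r) else character()
  structure(
    list(nodes = nodes, edges = edges,
         thresholds = list(r_min = r_min, alpha = alpha)),
    class = "connectivity_graph"
  )
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d cells, %d edges (R > %g, p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$thresholds$r_min,
              x$thresholds$alpha))
  if (nrow(x$edges)) {
    tb <- table(factor(x$edges$bin, levels = c("green", "yellow", "red")))
    cat(sprintf("  bins: green %d, yellow %d, red %d\n",
                tb["green"], tb["yellow"], tb["red"]))
  }
  invisible(x)
}

#' Islet-level connectivity summary
#'
#' @param g a `connectivity_graph` from [build_graph()].
#' @return A list of class `connectivity_summary` with
#'   `pct_connected_pairs` (percentage of all unordered pairs carrying an
#'   edge), `degree` (named per-cell edge counts), `mean_r_significant`
#'   (mean correlation over edges, `NaN` when there are none), `n_cells`,
#'   `n_edges`.
#' @export
connectivity_summary <- function(g) {
  stopifnot(inherits(g, "connectivity_graph"))
  n_cells <- nrow(g$nodes)
  if (n_cells < 2L) stopf("need at least 2 cells to summarise connectivity")
  n_edges <- nrow(g$edges)
  degree <- stats::setNames(integer(n_cells), g$nodes$cell_id)
  if (n_edges) {
    tab <- table(c(g$edges$cell_a, g$edges$cell_b))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(
    list(pct_connected_pairs = 100 * n_edges / choose(n_cells, 2),
         degree = degree,
         mean_r_significant = if (n_edges) mean(g$edges$r) else NaN,
         n_cells = n_cells, n_edges = n_edges),
    class = "connectivity_summary"
  )
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat(sprintf("%d cells, %d edges: %.2f%% of pairs connected; mean R over edges %.3f\n",
              x$n_cells, x$n_edges, x$pct_connected_pairs,
              x$mean_r_significant))
  invisible(x)
}

#' Export the Pearson heatmap matrix
#'
#' Writes the square correlation table used for heatmap display: tab-delimited,
#' cell ids on both axes, diagonal `NA`, values clipped to the display range
#' `[-1, 1]`.
#'
#' @param corr a `correlation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_heatmap_matrix <- function(corr, path) {
  stopifnot(inherits(corr, "correlation_result"))
  m <- pmin(pmax(corr$R, -1), 1)
  diag(m) <- NA_real_
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the thresholded edge list
#'
#' @param g a `connectivity_graph`.
#' @param path output path for a tab-delimited table
#'   `cell_a, cell_b, r, p, bin`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  stopifnot(inherits(g, "connectivity_graph"))
  utils::write.table(g$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

edge_bin_colours <- c(green = "green3", yellow = "gold2", red = "red2")

#' Plot a connectivity line map
#'
#' Draws every cell at its Cartesian ROI coordinates and connects each
#' significant pair with a straight line coloured by its strength bin
#' (green 0.25--0.5, yellow 0.5--0.75, red 0.75--1.0).
#'
#' @param x a `connectivity_graph` with finite node coordinates.
#' @param node_cex point size of the cells.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.connectivity_graph <- function(x, node_cex = 1.2, ...) {
  if (!all(is.finite(x$nodes$x)) || !all(is.finite(x$nodes$y))) {
    stopf("graph nodes lack coordinates; supply `coords` to build_graph()")
  }
  plot(x$nodes$x, x$nodes$y, type = "n", asp = 1,
       xlab = "x (a.u.)", ylab = "y (a.u.)", ...)
  if (nrow(x$edges)) {
    a <- match(x$edges$cell_a, x$nodes$cell_id)
    b <- match(x$edges$cell_b, x$nodes$cell_id)
    graphics::segments(x$nodes$x[a], x$nodes$y[a],
                       x$nodes$x[b], x$nodes$y[b],
                       col = edge_bin_colours[x$edges$bin], lwd = 1.5)
  }
  graphics::points(x$nodes$x, x$nodes$y, pch = 21, bg = "grey30",
                   cex = node_cex)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = edge_bin_colours,
                   legend = c("0.25 < R < 0.5", "0.5 <= R < 0.75",
                              "0.75 <= R <= 1"))
  invisible(x)
}

#' Plot a Pearson heatmap matrix
#'
#' Renders the pairwise correlation matrix with the colour scale fixed to
#' `[-1, 1]` regardless of the observed range, diagonal blanked.
#'
#' @param x a `correlation_result`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.correlation_result <- function(x, ...) {
  m <- pmin(pmax(x$R, -1), 1)
  n <- nrow(m)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = x$cell_ids, las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(x$cell_ids), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
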