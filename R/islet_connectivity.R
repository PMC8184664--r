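#' Fit a functional-connectivity network to islet Ca2+ traces
#'
#' The full analysis in one call: trailing-average smoothing, F/F0
#' normalisation, removal of zero-variance cells, all-pairs Pearson
#' correlation with per-pair bootstrap significance, and thresholding into a
#' colour-binned connectivity graph.
#'
#' The default preprocessing follows the conventional recipe for islet
#' recordings: a 10-frame retrospective average, then division by each cell's
#' baseline F0. Smoothing induces serial correlation in the traces; when
#' `smooth_window > 1` and `method = "pairs_bootstrap"` the fit therefore
#' warns and the moving-block bootstrap (`method = "block_bootstrap"`, with
#' `block_len` defaulting to the smoothing window) is recommended. Setting
#' `smooth_window = 1` skips smoothing and keeps the iid frame bootstrap
#' exactly calibrated.
#'
#' @param traces a [trace_matrix()] of raw fluorescence, or a path to a trace
#'   CSV understood by [read_traces()].
#' @param coords optional data frame `cell_id, x, y` (or a path readable by
#'   [read_coords()]) for the connectivity line map.
#' @param smooth_window trailing smoothing window in frames (default 10);
#'   `1` disables smoothing.
#' @param f0_frames frames defining the per-cell baseline F0 (default 30).
#' @param n_boot bootstrap replicates (default 10000).
#' @param method resampling scheme, see [bootstrap_pvalues()].
#' @param block_len block length for the block bootstrap; defaults to
#'   `smooth_window`.
#' @param r_min,alpha edge thresholds (defaults 0.25 and 0.001), see
#'   [build_graph()].
#' @param seed integer seed for the bootstrap substreams.
#' @return An object of class `islet_connectivity`: a list with `traces`
#'   (preprocessed), `removed` (degenerate cell ids), `corr`
#'   (`correlation_result`), `graph` (`connectivity_graph`), `summary`
#'   (`connectivity_summary`) and `call`.
#' @examples
#' sim <- simulate_islet(islet_sim_spec(n_cells = 10, n_frames = 150, seed = 8))
#' fit <- islet_connectivity(sim$traces, sim$coords, smooth_window = 1,
#'                           n_boot = 1000, seed = 8)
#' fit
#' summary(fit)
#' @export
islet_connectivity <- function(traces, coords = NULL,
                               smooth_window = 10L, f0_frames = 30L,
                               n_boot = 10000L,
                               method = c("pairs_bootstrap", "block_bootstrap",
                                          "permutation"),
                               block_len = NULL, r_min = 0.25, alpha = 0.001,
                               seed = 1L) {
  method <- match.arg(method)
  if (is.character(traces)) traces <- read_traces(traces)
  stopifnot(inherits(traces, "trace_matrix"))
  if (is.character(coords)) coords <- read_coords(coords)
  if (smooth_window > 1L) {
    traces <- smooth_retrospective(traces, window = smooth_window)
    if (method == "pairs_bootstrap") {
      warnf(paste0("smoothed traces are serially correlated; the iid frame ",
                   "bootstrap is anticonservative. Consider ",
                   "method = \"block_bootstrap\"."))
    }
  }
  traces <- normalise_f0(traces, f0_frames = f0_frames)
  qc <- drop_degenerate_cells(traces)
  traces <- qc$traces
  corr <- suppressWarnings(
    bootstrap_pvalues(traces, n_boot = n_boot, method = method,
                      block_len = block_len %||% max(smooth_window, 1L),
                      seed = seed)
  )
  if (!is.null(coords) && length(qc$removed)) {
    coords <- coords[!coords$cell_id %in% qc$removed, , drop = FALSE]
  }
  graph <- build_graph(corr, coords, r_min = r_min, alpha = alpha)
  structure(
    list(traces = traces, removed = qc$removed, corr = corr, graph = graph,
         summary = connectivity_summary(graph), call = match.call()),
    class = "islet_connectivity"
  )
}

#' @export
print.islet_connectivity <- function(x, ...) {
  s <- x$summary
  cat("Islet functional connectivity fit\n")
  cat(sprintf("  %d cells, %d frames; %s with %d replicates (seed %d)\n",
              s$n_cells, nrow(x$traces$values), x$corr$method, x$corr$n_boot,
              x$corr$seed))
  if (length(x$removed)) {
    cat(sprintf("  degenerate cells removed: %s\n",
                paste(x$removed, collapse = ", ")))
  }
  cat(sprintf("  edges (R > %g, p < %g): %d of %d pairs (%.2f%%)\n",
              x$graph$thresholds$r_min, x$graph$thresholds$alpha, s$n_edges,
              choose(s$n_cells, 2), s$pct_connected_pairs))
  invisible(x)
}

#' @export
summary.islet_connectivity <- function(object, ...) object$summary

#' @export
coef.islet_connectivity <- function(object, ...) object$corr$R

#' Plot an islet connectivity fit
#'
#' @param x an `islet_connectivity` fit.
#' @param type `"map"` for the Cartesian connectivity line map or
#'   `"heatmap"` for the Pearson matrix (colour scale fixed to `[-1, 1]`).
#' @param ... passed to the underlying plot method.
#' @return `x`, invisibly.
#' @export
plot.islet_connectivity <- function(x, type = c("map", "heatmap"), ...) {
  type <- match.arg(type)
  if (type == "map") plot(x$graph, ...) else plot(x$corr, ...)
  invisible(x)
}
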