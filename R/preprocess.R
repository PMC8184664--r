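#' Retrospective (trailing) moving-average smoothing
#'
#' Replaces every sample by the mean of the trailing window of `window`
#' samples ending at (and including) that sample. The first `window - 1`
#' samples average over all samples available so far, so the output keeps the
#' input length and never looks ahead. With `include_current = FALSE` the
#' window instead covers the `window` samples strictly preceding the current
#' one (the first sample is left unchanged, having no predecessors); this
#' stricter reading is provided but is not the default.
#'
#' @param t a [trace_matrix()], not yet smoothed.
#' @param window trailing window length in frames; default 10.
#' @param include_current logical; include the current sample in the window
#'   (default `TRUE`).
#' @return A [trace_matrix()] with `flags$smoothed = TRUE` and
#'   `flags$smooth_window` recorded.
#' @examples
#' tm <- trace_matrix(matrix(c(1, 2, 3, 4), ncol = 1))
#' smooth_retrospective(tm, window = 2)$values  # 1, 1.5, 2.5, 3.5
#' @export
smooth_retrospective <- function(t, window = 10L, include_current = TRUE) {
  stopifnot(inherits(t, "trace_matrix"))
  if (!is_count(window)) stopf("`window` must be a positive integer")
  window <- as.integer(window)
  if (isTRUE(t$flags$smoothed)) stopf("traces are already smoothed")
  nf <- n_frames(t)
  if (window >= nf) {
    stopf("smoothing window (%d) must be smaller than the number of frames (%d)",
          window, nf)
  }
  vals <- apply(t$values, 2L, trailing_mean, window = window,
                include_current = include_current)
  vals <- matrix(vals, nrow = nf, dimnames = dimnames(t$values))
  out <- t
  out$values <- vals
  out$flags$smoothed <- TRUE
  out$flags$smooth_window <- window
  out
}

trailing_mean <- function(x, window, include_current = TRUE) {
  n <- length(x)
  if (include_current) {
    cs <- cumsum(x)
    i <- seq_len(n)
    lo <- pmax(i - window, 0L)
    (cs - c(0, cs)[lo + 1L]) / (i - lo)
  } else {
    # mean of the `window` samples strictly before i; x[1] has none and is kept
    cs <- cumsum(x)
    i <- seq_len(n)
    lo <- pmax(i - 1L - window, 0L)
    hi <- i - 1L
    out <- x
    idx <- i > 1L
    out[idx] <- (cs[hi[idx]] - c(0, cs)[lo[idx] + 1L]) / (hi[idx] - lo[idx])
    out
  }
}

#' Normalise traces to baseline fluorescence F0
#'
#' Divides every sample of each cell by that cell's F0, defined as the mean of
#' its first `f0_frames` samples, yielding F/F0 traces whose baseline mean is
#' exactly 1.
#'
#' @param t a [trace_matrix()].
#' @param f0_frames number of leading frames whose mean defines F0 per cell;
#'   use the pre-stimulus baseline length when known (default 30 frames,
#'   i.e. 60 s at 0.5 Hz).
#' @return A [trace_matrix()] with `flags$normalised = TRUE` and
#'   `flags$f0_frames` recorded.
#' @export
normalise_f0 <- function(t, f0_frames = 30L) {
  stopifnot(inherits(t, "trace_matrix"))
  if (!is_count(f0_frames)) stopf("`f0_frames` must be a positive integer")
  f0_frames <- as.integer(f0_frames)
  if (f0_frames >= n_frames(t)) {
    stopf("`f0_frames` (%d) must be smaller than the number of frames (%d)",
          f0_frames, n_frames(t))
  }
  f0 <- colMeans(t$values[seq_len(f0_frames), , drop = FALSE])
  zero <- abs(f0) < 1e-12
  if (any(zero)) {
    stopf("F0 is zero (|F0| < 1e-12) for cell(s): %s",
          paste(t$cell_ids[zero], collapse = ", "))
  }
  out <- t
  out$values <- sweep(t$values, 2L, f0, "/")
  out$flags$normalised <- TRUE
  out$flags$f0_frames <- f0_frames
  out
}

#' Drop zero-variance (degenerate) traces
#'
#' Pearson correlation is undefined against a constant series, so cells whose
#' trace variance is zero (below 1e-12) are removed before correlation. The
#' order of surviving cells is preserved and each removal is reported.
#'
#' @param t a [trace_matrix()].
#' @return A list with elements `traces` (the filtered [trace_matrix()]) and
#'   `removed` (character vector of removed cell ids, possibly empty).
#' @export
drop_degenerate_cells <- function(t) {
  stopifnot(inherits(t, "trace_matrix"))
  v <- apply(t$values, 2L, stats::var)
  degenerate <- v < 1e-12
  if (all(degenerate)) stopf("all cells have zero-variance traces")
  removed <- t$cell_ids[degenerate]
  for (id in removed) {
    message(sprintf("dropping degenerate (zero-variance) cell '%s'", id))
  }
  if (!any(degenerate)) return(list(traces = t, removed = character()))
  out <- t
  out$values <- t$values[, !degenerate, drop = FALSE]
  out$cell_ids <- t$cell_ids[!degenerate]
  list(traces = out, removed = removed)
}
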