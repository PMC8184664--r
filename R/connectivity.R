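#' All-pairs Pearson correlation matrix
#'
#' Computes the product-moment correlation between every unordered pair of
#' cell traces. The diagonal (autocorrelation) is excluded from the analysis
#' and reported as `NA` rather than 1.
#'
#' @param t a [trace_matrix()]; a warning is raised if it has not been
#'   smoothed and normalised (the conventional preprocessing), but the
#'   computation proceeds.
#' @return A symmetric numeric matrix with cell ids on both dimensions and
#'   `NA` on the diagonal.
#' @examples
#' tm <- trace_matrix(cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10)))
#' pearson_matrix(suppressWarnings(tm))["a", "b"]  # 1
#' @export
pearson_matrix <- function(t) {
  stopifnot(inherits(t, "trace_matrix"))
  if (!isTRUE(t$flags$smoothed) || !isTRUE(t$flags$normalised)) {
    warnf("traces are not smoothed and normalised; correlating raw values")
  }
  if (n_frames(t) < 3L) stopf("need at least 3 frames to correlate")
  v <- apply(t$values, 2L, stats::var)
  if (any(v < 1e-12)) {
    stopf("zero-variance trace(s): %s; run drop_degenerate_cells() first",
          paste(t$cell_ids[v < 1e-12], collapse = ", "))
  }
  R <- stats::cor(t$values)
  diag(R) <- NA_real_
  dimnames(R) <- list(t$cell_ids, t$cell_ids)
  R
}

#' Bootstrap significance of pairwise correlations
#'
#' Attaches a resampling-based significance value to every cell pair's
#' Pearson correlation. Three schemes are available:
#'
#' * `"pairs_bootstrap"` (default): frame indices are resampled with
#'   replacement and applied identically to both members of a pair; the
#'   correlation is recomputed per replicate and the one-sided significance is
#'   `p = (1 + #\{replicate R <= 0\}) / (n_boot + 1)` — i.e. the bootstrap
#'   confidence interval for R must exclude zero, treating connectivity as
#'   positive coupling.
#' * `"block_bootstrap"`: as above, but contiguous blocks of `block_len`
#'   frames are resampled, preserving short-range serial correlation (use
#'   this on smoothed traces, whose trailing average induces autocorrelation).
#' * `"permutation"`: one member's frames are permuted per replicate and
#'   `p = (1 + #\{replicate R >= observed R\}) / (n_boot + 1)`.
#'
#' Every pair draws from its own RNG substream derived deterministically from
#' `seed`, so results are fully reproducible; [boot_replicate_indices()]
#' regenerates any pair's resampling indices for auditing. A replicate in
#' which either resampled series is constant is discarded and redrawn; if
#' more than 10% of a pair's replicates are discarded, the computation for
#' that pair aborts with an error.
#'
#' @param t a [trace_matrix()] with at least 10 frames.
#' @param n_boot number of bootstrap/permutation replicates; default 10000 so
#'   that the significance threshold 0.001 is resolvable (the minimum
#'   attainable p is `1 / (n_boot + 1)`). A warning is raised below 1000.
#' @param method resampling scheme, see Details.
#' @param block_len block length for `"block_bootstrap"`; defaults to the
#'   smoothing window recorded in `t` (else 10).
#' @param seed integer seed for the per-pair substreams.
#' @return An object of class `correlation_result`: a list with `cell_ids`,
#'   `R` (symmetric Pearson matrix, diagonal `NA`), `P` (significance matrix,
#'   diagonal `NA`), `n_boot`, `method`, `block_len`, `seed`, and
#'   `n_discarded` (matrix of redrawn-replicate counts).
#' @examples
#' sim <- simulate_islet(islet_sim_spec(n_cells = 5, n_frames = 60, seed = 2))
#' tm <- normalise_f0(sim$traces, f0_frames = 30)
#' res <- suppressWarnings(bootstrap_pvalues(tm, n_boot = 1000, seed = 9))
#' res
#' @export
bootstrap_pvalues <- function(t, n_boot = 10000L,
                              method = c("pairs_bootstrap", "block_bootstrap",
                                         "permutation"),
                              block_len = NULL, seed = 1L) {
  stopifnot(inherits(t, "trace_matrix"))
  method <- match.arg(method)
  if (!is_count(n_boot)) stopf("`n_boot` must be a positive integer")
  if (n_boot < 1000L) {
    warnf("n_boot = %d gives minimum attainable p = %.3g; use >= 1000 to resolve p < 0.001",
          n_boot, 1 / (n_boot + 1))
  }
  if (n_frames(t) < 10L) stopf("need at least 10 frames for resampling")
  if (!is_count(seed, min = -.Machine$integer.max)) {
    stopf("`seed` must be a single integer")
  }
  if (is.null(block_len)) {
    block_len <- if (!is.na(t$flags$smooth_window)) t$flags$smooth_window else 10L
  }
  if (!is_count(block_len) || block_len > n_frames(t)) {
    stopf("`block_len` must be an integer in [1, n_frames]")
  }
  R <- pearson_matrix(t)
  mcode <- match(method, c("pairs_bootstrap", "block_bootstrap", "permutation"))
  out <- .boot_pvalues_cpp(t$values, R, as.integer(n_boot), mcode,
                           as.integer(block_len), as.numeric(seed))
  if (any(out$failed)) {
    bad <- which(out$failed & upper.tri(out$failed), arr.ind = TRUE)
    stopf("more than 10%% of replicates degenerate for pair(s): %s",
          paste(t$cell_ids[bad[, 1L]], t$cell_ids[bad[, 2L]],
                sep = "~", collapse = ", "))
  }
  ndisc <- sum(out$discarded[upper.tri(out$discarded)])
  if (ndisc > 0) {
    message(sprintf("%d degenerate replicate(s) discarded and redrawn", ndisc))
  }
  P <- out$P
  dimnames(P) <- dimnames(R)
  dimnames(out$discarded) <- dimnames(R)
  structure(
    list(cell_ids = t$cell_ids, R = R, P = P, n_boot = as.integer(n_boot),
         method = method,
         block_len = if (method == "block_bootstrap") as.integer(block_len) else NA_integer_,
         seed = as.integer(seed), n_discarded = out$discarded),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  ut <- upper.tri(x$R)
  cat(sprintf("<correlation_result> %d cells, %d pairs; %s, n_boot = %d, seed = %d\n",
              length(x$cell_ids), sum(ut), x$method, x$n_boot, x$seed))
  cat(sprintf("  R: median %.3f [%.3f, %.3f]; pairs with p < 0.001: %d\n",
              stats::median(x$R[ut]), min(x$R[ut]), max(x$R[ut]),
              sum(x$P[ut] < 0.001)))
  invisible(x)
}

#' Regenerate the resampling indices of one cell pair
#'
#' Returns the raw replicate-by-replicate frame indices (1-based) drawn by
#' [bootstrap_pvalues()] for a given pair, enabling independent re-computation
#' of that pair's significance. For `"permutation"` the indices are the
#' permutation applied to the second member of the pair. Discarded
#' (degenerate) replicates consume additional draws from the same substream;
#' the returned matrix is the first `n_boot` raw draws, which equal the
#' accepted replicates whenever no replicate was discarded.
#'
#' @param seed,n_boot,method,block_len as passed to [bootstrap_pvalues()].
#' @param pair_index 1-based index of the pair in row-major upper-triangle
#'   order, i.e. (1,2), (1,3), ..., (1,p), (2,3), ... See [pair_index()].
#' @param n_frames number of frames in the trace matrix.
#' @return An integer matrix of dimension `n_frames x n_boot`.
#' @export
boot_replicate_indices <- function(seed, pair_index, n_frames, n_boot,
                                   method = c("pairs_bootstrap",
                                              "block_bootstrap", "permutation"),
                                   block_len = 10L) {
  method <- match.arg(method)
  mcode <- match(method, c("pairs_bootstrap", "block_bootstrap", "permutation"))
  stopifnot(is_count(pair_index), is_count(n_frames), is_count(n_boot))
  .boot_indices_cpp(as.numeric(seed), as.numeric(pair_index - 1L),
                    as.integer(n_frames), as.integer(n_boot), mcode,
                    as.integer(block_len))
}

#' Position of a cell pair in upper-triangle order
#'
#' Maps cell indices `i < j` to the 1-based pair index used by the per-pair
#' RNG substreams (row-major upper triangle).
#'
#' @param i,j cell indices with `1 <= i < j <= n`.
#' @param n number of cells.
#' @return The 1-based pair index.
#' @export
pair_index <- function(i, j, n) {
  stopifnot(i >= 1, j > i, j <= n)
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

#' Export correlation and significance matrices
#'
#' Writes square tab-delimited tables (cell ids as header row and first
#' column, diagonal `NA`) and a long-format pair table
#' `cell_a, cell_b, r, p`.
#'
#' @param corr a `correlation_result` from [bootstrap_pvalues()].
#' @param r_path,p_path,pairs_path output paths; any may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_correlation <- function(corr, r_path = NULL, p_path = NULL,
                              pairs_path = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  write_square <- function(m, path) {
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(r_path)) write_square(corr$R, r_path)
  if (!is.null(p_path)) write_square(corr$P, p_path)
  if (!is.null(pairs_path)) {
    ut <- which(upper.tri(corr$R), arr.ind = TRUE)
    ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
    df <- data.frame(cell_a = corr$cell_ids[ut[, 1L]],
                     cell_b = corr$cell_ids[ut[, 2L]],
                     r = corr$R[ut], p = corr$P[ut])
    utils::write.table(df, pairs_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(c(r_path, p_path, pairs_path))
}
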