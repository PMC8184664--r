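# Independent reference implementations used as oracles. They deliberately
# avoid the package's code paths (and stats::cor) so agreement is meaningful.

# Textbook two-pass product-moment correlation of two vectors.
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (k in seq_len(n)) {
    sxy <- sxy + (x[k] - mx) * (y[k] - my)
    sxx <- sxx + (x[k] - mx)^2
    syy <- syy + (y[k] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Full naive correlation matrix (diagonal NA to match pearson_matrix).
naive_pearson_matrix <- function(vals) {
  p <- ncol(vals)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(vals), colnames(vals)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      out[i, j] <- out[j, i] <- naive_pearson(vals[, i], vals[, j])
    }
  }
  out
}

# Double-loop bootstrap/permutation p-values consuming the package's
# published resampling indices; the statistic and the counting are
# re-implemented from scratch.
naive_boot_pvalues <- function(vals, robs, n_boot, method, block_len, seed) {
  p <- ncol(vals)
  n <- nrow(vals)
  P <- matrix(NA_real_, p, p, dimnames = dimnames(robs))
  k <- 0L
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      k <- k + 1L
      idx <- boot_replicate_indices(seed, k, n, n_boot, method = method,
                                    block_len = block_len)
      count <- 0L
      for (b in seq_len(n_boot)) {
        if (method == "permutation") {
          r <- naive_pearson(vals[, i], vals[idx[, b], j])
          if (r >= robs[i, j]) count <- count + 1L
        } else {
          r <- naive_pearson(vals[idx[, b], i], vals[idx[, b], j])
          if (r <= 0) count <- count + 1L
        }
      }
      P[i, j] <- P[j, i] <- (1 + count) / (n_boot + 1)
    }
  }
  P
}

# Independent running-sum enrichment score: explicit walk down the list.
naive_es <- function(stat, hit, weight) {
  n <- length(stat)
  nh <- sum(hit)
  denom <- sum(abs(stat[hit])^weight)
  run <- 0
  best <- 0
  for (k in seq_len(n)) {
    run <- run + if (hit[k]) abs(stat[k])^weight / denom else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# A small deterministic trace matrix for IO / preprocessing tests.
make_tm <- function(n_frames = 20, n_cells = 3, seed = 1, dt = 2) {
  set.seed(seed)
  vals <- matrix(100 + rnorm(n_frames * n_cells, sd = 5), n_frames, n_cells,
                 dimnames = list(NULL, paste0("c", seq_len(n_cells))))
  trace_matrix(vals, frame_interval_s = dt)
}

# Wrap arbitrary R/P matrices as a correlation_result for network tests.
make_corr <- function(R, P, cell_ids = rownames(R)) {
  if (is.null(cell_ids)) {
    cell_ids <- paste0("c", seq_len(nrow(R)))
    dimnames(R) <- dimnames(P) <- list(cell_ids, cell_ids)
  }
  diag(R) <- NA_real_
  diag(P) <- NA_real_
  structure(list(cell_ids = cell_ids, R = R, P = P, n_boot = 1000L,
                 method = "pairs_bootstrap", block_len = NA_integer_,
                 seed = 1L,
                 n_discarded = matrix(0L, nrow(R), ncol(R))),
            class = "correlation_result")
}

precision_recall <- function(graph, truth) {
  found <- paste(graph$edges$cell_a, graph$edges$cell_b)
  planted <- paste(truth$true_edges$cell_a, truth$true_edges$cell_b)
  tp <- sum(found %in% planted)
  c(precision = if (length(found)) tp / length(found) else NA_real_,
    recall = tp / length(planted))
}
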