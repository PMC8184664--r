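test_that("edge bins follow the published colour ranges", {
  expect_identical(classify_edge_bin(0.30), "green")
  expect_identical(classify_edge_bin(0.60), "yellow")
  expect_identical(classify_edge_bin(0.80), "red")
  # boundary values go to the upper bin
  expect_identical(classify_edge_bin(c(0.5, 0.75, 1.0)),
                   c("yellow", "red", "red"))
  # numeric noise just above 1 is clipped
  expect_identical(classify_edge_bin(1 + 1e-10), "red")
  expect_error(classify_edge_bin(0.25), "0.25")
  expect_error(classify_edge_bin(0.1), "0.25")
  expect_error(classify_edge_bin(1.01), "0.25")
  # the bins partition (0.25, 1]
  grid <- seq(0.2501, 1, by = 0.0001)
  bins <- classify_edge_bin(grid)
  expect_true(all(bins %in% c("green", "yellow", "red")))
  expect_identical(unique(bins[grid < 0.5]), "green")
  expect_identical(unique(bins[grid >= 0.5 & grid < 0.75]), "yellow")
  expect_identical(unique(bins[grid >= 0.75]), "red")
})

test_that("the edge rule is strict on both thresholds", {
  R <- matrix(0, 3, 3); P <- matrix(1, 3, 3)
  ids <- c("a", "b", "d")
  dimnames(R) <- dimnames(P) <- list(ids, ids)
  coords <- data.frame(cell_id = ids, x = c(0, 1, 2), y = c(0, 0, 1))

  # r = 0.30, p = 0.0005 -> edge, green
  R["a", "b"] <- R["b", "a"] <- 0.30
  P["a", "b"] <- P["b", "a"] <- 5e-4
  g <- build_graph(make_corr(R, P), coords)
  expect_equal(nrow(g$edges), 1L)
  expect_identical(g$edges$bin, "green")

  # r = 0.30, p = 0.01 -> no edge (not significant)
  P["a", "b"] <- P["b", "a"] <- 0.01
  expect_equal(nrow(build_graph(make_corr(R, P), coords)$edges), 0L)

  # r = 0.25 exactly, p = 1e-4 -> no edge (strict R > 0.25)
  R["a", "b"] <- R["b", "a"] <- 0.25
  P["a", "b"] <- P["b", "a"] <- 1e-4
  expect_equal(nrow(build_graph(make_corr(R, P), coords)$edges), 0L)

  # p = alpha exactly -> no edge (strict p < alpha)
  R["a", "b"] <- R["b", "a"] <- 0.4
  P["a", "b"] <- P["b", "a"] <- 0.001
  expect_equal(nrow(build_graph(make_corr(R, P), coords)$edges), 0L)
})

test_that("graph construction validates shared cell ids", {
  tm <- make_tm(n_frames = 30, n_cells = 3)
  res <- suppressWarnings(bootstrap_pvalues(tm, n_boot = 1000, seed = 1))
  coords <- data.frame(cell_id = c("c1", "c2", "zz"), x = 1:3, y = 1:3)
  expect_error(build_graph(res, coords), "c3")
  expect_error(build_graph(res, coords), "zz")
})

test_that("raising thresholds never adds edges (monotone filtering)", {
  set.seed(4)
  n <- 8
  R <- matrix(runif(n * n, -1, 1), n); R[lower.tri(R)] <- t(R)[lower.tri(R)]
  P <- matrix(runif(n * n), n); P[lower.tri(P)] <- t(P)[lower.tri(P)]
  ids <- paste0("c", 1:n)
  dimnames(R) <- dimnames(P) <- list(ids, ids)
  corr <- make_corr(R, P)
  key <- function(g) paste(g$edges$cell_a, g$edges$cell_b)
  base <- build_graph(corr, NULL, r_min = 0.25, alpha = 0.5)
  expect_true(all(key(build_graph(corr, NULL, 0.4, 0.5)) %in% key(base)))
  expect_true(all(key(build_graph(corr, NULL, 0.25, 0.1)) %in% key(base)))
})

test_that("connectivity summaries count pairs exhaustively", {
  ids <- paste0("c", 1:4)
  coords <- data.frame(cell_id = ids, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  mk <- function(rval, pairs) {
    R <- matrix(0, 4, 4); P <- matrix(1, 4, 4)
    dimnames(R) <- dimnames(P) <- list(ids, ids)
    for (pr in pairs) {
      R[pr[1], pr[2]] <- R[pr[2], pr[1]] <- rval
      P[pr[1], pr[2]] <- P[pr[2], pr[1]] <- 1e-4
    }
    build_graph(make_corr(R, P), coords)
  }
  none <- mk(0.9, list())
  s0 <- connectivity_summary(none)
  expect_equal(s0$pct_connected_pairs, 0)
  expect_true(is.nan(s0$mean_r_significant))

  all6 <- mk(0.9, asplit(combn(4, 2), 2))
  expect_equal(connectivity_summary(all6)$pct_connected_pairs, 100)

  two <- mk(0.6, list(c(1, 2), c(3, 4)))
  s2 <- connectivity_summary(two)
  expect_equal(s2$pct_connected_pairs, 100 * 2 / 6, tolerance = 1e-12)
  expect_equal(s2$n_edges, sum(s2$degree) / 2)
  expect_equal(s2$mean_r_significant, 0.6)
})

test_that("the heatmap matrix export is square, clipped and re-readable", {
  tm <- make_tm(n_frames = 30, n_cells = 3, seed = 6)
  res <- suppressWarnings(bootstrap_pvalues(tm, n_boot = 1000, seed = 6))
  f <- tempfile()
  export_heatmap_matrix(res, f)
  m <- as.matrix(read.delim(f, row.names = 1))
  expect_equal(dim(m), c(3L, 3L))
  expect_true(all(is.na(diag(m))))
  expect_equal(unname(m), unname(t(m)))
  expect_true(all(abs(m[upper.tri(m)]) <= 1))
  expect_equal(unname(m[upper.tri(m)]), unname(res$R[upper.tri(res$R)]),
               tolerance = 1e-9)

  # clipping to the display range
  R <- matrix(c(NA, 1 + 1e-12, 1 + 1e-12, NA), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  corr <- make_corr(R, matrix(1, 2, 2))
  f2 <- tempfile()
  export_heatmap_matrix(corr, f2)
  m2 <- as.matrix(read.delim(f2, row.names = 1))
  expect_lte(m2[1, 2], 1)
})

test_that("edge lists and plots render from a graph", {
  sim <- simulate_islet(islet_sim_spec(n_cells = 8, n_frames = 150,
                                       coupled_mask = rep(c(TRUE, FALSE), 4),
                                       seed = 12))
  tm <- normalise_f0(sim$traces, 30)
  res <- suppressWarnings(bootstrap_pvalues(tm, n_boot = 1000, seed = 12))
  g <- build_graph(res, sim$coords)
  f <- tempfile()
  write_edges(g, f)
  edges <- read.delim(f)
  expect_identical(names(edges), c("cell_a", "cell_b", "r", "p", "bin"))
  expect_equal(nrow(edges), nrow(g$edges))
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_silent(plot(g))
  expect_silent(plot(res))
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)
  gg <- build_graph(res, NULL)
  grDevices::pdf(tempfile(fileext = ".pdf"))
  expect_error(plot(gg), "coordinates")
  grDevices::dev.off()
})
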