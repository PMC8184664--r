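worked_ranked <- function() {
  ranked_gene_list(paste0("g", 1:6), c(3, 2, 1, -1, -2, -3))
}

test_that("the running-sum score reproduces hand-executed examples", {
  # single member at the very top / very bottom, unweighted
  rl <- ranked_gene_list(paste0("g", 1:10), 10:1)
  expect_equal(enrichment_score(rl, gene_set("top", "g1"), weight = 0)$es, 1)
  expect_equal(enrichment_score(rl, gene_set("bottom", "g10"), weight = 0)$es,
               -1)

  # hits +3/4 and +1/4 at ranks 1 and 3, misses -1/4: extremum 0.75
  es <- enrichment_score(worked_ranked(), gene_set("demo", c("g1", "g3")))
  expect_equal(es$es, 0.75)
  expect_equal(es$running, c(0.75, 0.5, 0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  expect_identical(es$leading_edge, "g1")  # first extremum, rank 1

  # negative score: leading edge sits at or after the extremum
  bot <- enrichment_score(rl, gene_set("b", "g10"), weight = 0)
  expect_identical(bot$leading_edge, "g10")
})

test_that("the running sum is conservative and matches a naive walk", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(20:60, 1)
    stat <- rnorm(n)
    rl <- ranked_gene_list(paste0("g", 1:n), stat)
    members <- sample(rl$gene, sample(3:8, 1))
    for (w in c(0, 1)) {
      es <- enrichment_score(rl, gene_set("s", members), weight = w)
      expect_equal(es$running[n], 0, tolerance = 1e-12)
      hit <- rl$gene %in% members
      expect_equal(es$es, naive_es(rl$stat, hit, w), tolerance = 1e-12)
    }
  }
})

test_that("the score agrees with an established GSEA statistic", {
  skip_if_not_installed("fgsea")
  for (s in 1:5) {
    set.seed(s)
    rl <- ranked_gene_list(paste0("g", 1:50), rnorm(50))
    members <- sample(rl$gene, 8)
    mine <- enrichment_score(rl, gene_set("s", members), weight = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(rl$stat, rl$gene),
                               which(rl$gene %in% members), gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("score invariances hold under rescaling of the statistics", {
  set.seed(2)
  rl <- ranked_gene_list(paste0("g", 1:30), rnorm(30))
  members <- sample(rl$gene, 6)
  gs <- gene_set("s", members)
  # weight 0: any monotone transform of the stats leaves the ES unchanged
  mono <- ranked_gene_list(rl$gene, qnorm(pnorm(rl$stat))^3 + rank(rl$stat))
  expect_equal(enrichment_score(rl, gs, 0)$es,
               enrichment_score(mono, gs, 0)$es, tolerance = 1e-12)
  # weight 1: positive scalar multiplication leaves the ES unchanged
  scaled <- ranked_gene_list(rl$gene, 17.3 * rl$stat)
  expect_equal(enrichment_score(rl, gs, 1)$es,
               enrichment_score(scaled, gs, 1)$es, tolerance = 1e-12)
})

test_that("degenerate gene sets are rejected", {
  rl <- worked_ranked()
  expect_error(enrichment_score(rl, gene_set("none", c("x1", "x2"))),
               "no member")
  expect_error(enrichment_score(rl, gene_set("all", rl$gene)),
               "entire ranked list")
  expect_message(enrichment_score(rl, gene_set("part", c("g1", "zz"))),
                 "absent")
})

test_that("exact enumeration matches the hand-countable 6-gene example", {
  rl <- worked_ranked()
  gs <- gene_set("demo", c("g1", "g3"))
  res <- permutation_significance(rl, gs, seed = 1)
  expect_true(res$exact)
  # independent enumeration of all C(6,2) = 15 placements
  null_es <- apply(combn(6, 2), 2, function(pos) {
    hit <- seq_len(6) %in% pos
    naive_es(rl$stat, hit, 1)
  })
  expect_length(null_es, 15L)
  # conditional on sign: 4 of the 7 non-negative placements reach 0.75
  p_ref <- sum(null_es >= 0.75) / sum(null_es >= 0)
  expect_equal(res$p_perm, p_ref)
  expect_equal(res$es, 0.75)
  # Monte-Carlo agrees within binomial error
  mc <- permutation_significance(rl, gs, n_perm = 2000, seed = 7,
                                 exact = FALSE)
  expect_lt(abs(mc$p_perm - p_ref),
            3 * sqrt(p_ref * (1 - p_ref) / mc$n_same_sign))
})

test_that("an overwhelming set attains the minimum p", {
  sim <- simulate_ranked_list(200, 8, shift = 50, seed = 9)
  res <- permutation_significance(sim$ranked, sim$gene_set, n_perm = 500,
                                  seed = 9, exact = FALSE)
  # no null placement can be as extreme: the numerator stays at its floor
  expect_equal(res$p_perm, 1 / (res$n_same_sign + 1), tolerance = 1e-12)
  expect_gt(res$nes, 1)
})

test_that("permutation significance is deterministic per seed", {
  sim <- simulate_ranked_list(100, 10, shift = 1, seed = 5)
  a <- permutation_significance(sim$ranked, sim$gene_set, n_perm = 300,
                                seed = 11, exact = FALSE)
  b <- permutation_significance(sim$ranked, sim$gene_set, n_perm = 300,
                                seed = 11, exact = FALSE)
  expect_identical(a, b)
})

test_that("null lists give approximately uniform permutation p-values", {
  ps <- vapply(1:60, function(s) {
    sim <- simulate_ranked_list(60, 6, shift = 0, seed = s)
    permutation_significance(sim$ranked, sim$gene_set, n_perm = 200,
                             seed = s, exact = FALSE)$p_perm
  }, 0)
  frac <- mean(ps < 0.25)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 60) + 0.05)
})

test_that("Benjamini-Hochberg adjustment reproduces the step-up hand example", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.9, 0.001, 0.04, 0.3)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # input order preserved: adjusting a permuted vector permutes the output
  o <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p[o]), q[o])
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("family-level scoring adjusts across sets and serialises", {
  sim1 <- simulate_ranked_list(150, 10, shift = 2, seed = 2)
  null_set <- gene_set("null_set", sample(sim1$ranked$gene, 12))
  res <- gsea_preranked(sim1$ranked, list(sim1$gene_set, null_set),
                        n_perm = 300, seed = 2)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$q >= res$p))
  expect_equal(res$q, bh_adjust(res$p))
  expect_lt(res$p[res$set == "planted_set"], res$p[res$set == "null_set"])
  f <- tempfile()
  write_enrichment(res, f)
  back <- read.delim(f)
  expect_equal(back$es, res$es, tolerance = 1e-9)
})

test_that("RNK and GMT files roundtrip", {
  sim <- simulate_ranked_list(40, 5, shift = 1, seed = 6)
  rf <- tempfile(fileext = ".rnk")
  write_rnk(sim$ranked, rf)
  back <- read_rnk(rf)
  expect_identical(back$gene, sim$ranked$gene)
  expect_equal(back$stat, sim$ranked$stat, tolerance = 1e-9)

  gf <- tempfile(fileext = ".gmt")
  write_gmt(list(sim$gene_set, gene_set("other", c("a", "b"))), gf)
  sets <- read_gmt(gf)
  expect_named(sets, c("planted_set", "other"))
  expect_identical(sets$planted_set$members, sim$gene_set$members)
  writeLines("badline\tonly2fields", gf)
  expect_error(read_gmt(gf), "fewer than 3")

  fixture <- system.file("extdata", "synthetic_emt_sets.gmt",
                         package = "isletcon")
  expect_true(nzchar(fixture))
  emt <- read_gmt(fixture)
  expect_true(all(c("epithelial_markers", "mesenchymal_markers") %in%
                    names(emt)))
})
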