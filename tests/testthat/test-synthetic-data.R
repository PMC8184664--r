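test_that("coordinate placement respects the disc and the spacing constraint", {
  one <- generate_coordinates(1, field_radius = 5, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_lte(one$x^2 + one$y^2, 25)

  two <- generate_coordinates(2, field_radius = 5, min_spacing = 0, seed = 2)
  expect_true(all(two$x^2 + two$y^2 <= 25))

  xy <- generate_coordinates(50, field_radius = 100, min_spacing = 10, seed = 7)
  expect_equal(nrow(xy), 50L)
  expect_true(all(xy$x^2 + xy$y^2 <= 100^2))
  # brute-force check over all C(50, 2) pairs
  for (pr in asplit(combn(50, 2), 2)) {
    d <- sqrt((xy$x[pr[1]] - xy$x[pr[2]])^2 + (xy$y[pr[1]] - xy$y[pr[2]])^2)
    expect_gte(d, 10)
  }
  expect_identical(xy, generate_coordinates(50, 100, 10, seed = 7))
  expect_error(
    generate_coordinates(200, field_radius = 2, min_spacing = 1.5,
                         max_tries = 200),
    "densest feasible"
  )
})

test_that("simulated islets have the advertised shape and planted truth", {
  sim <- simulate_islet(islet_sim_spec(seed = 4))
  expect_equal(ncol(sim$traces$values), 50L)  # ~50 ROIs per islet
  expect_equal(nrow(sim$traces$values), 300L)
  expect_equal(diff(sim$traces$frame_times_s[1:2]), 2)  # 0.5 Hz
  n_coupled <- sum(sim$truth$coupled_mask)
  expect_equal(nrow(sim$truth$true_edges), choose(n_coupled, 2))
  # true edges are exactly the pairs within the coupled set
  coupled_ids <- names(sim$truth$coupled_mask)[sim$truth$coupled_mask]
  expect_true(all(sim$truth$true_edges$cell_a %in% coupled_ids))
  expect_true(all(sim$truth$true_edges$cell_b %in% coupled_ids))
  # an explicit mask overrides the coupling fraction
  mask <- rep(c(TRUE, FALSE), c(4, 6))
  sim2 <- simulate_islet(islet_sim_spec(n_cells = 10, n_frames = 50,
                                        coupled_mask = mask, seed = 1))
  expect_identical(unname(sim2$truth$coupled_mask), mask)
})

test_that("identical spec and seed give bit-identical output", {
  spec <- islet_sim_spec(n_cells = 12, n_frames = 80, seed = 99)
  a <- simulate_islet(spec)
  b <- simulate_islet(spec)
  expect_identical(a, b)
  fa <- tempfile(); fb <- tempfile()
  write_traces(a$traces, fa); write_traces(b$traces, fb)
  expect_identical(readLines(fa), readLines(fb))
  rl1 <- simulate_ranked_list(50, 5, shift = 1, seed = 3)
  rl2 <- simulate_ranked_list(50, 5, shift = 1, seed = 3)
  expect_identical(rl1, rl2)
})

test_that("uncoupled islets show no mean pairwise correlation", {
  sim <- simulate_islet(islet_sim_spec(n_cells = 10, n_frames = 2000,
                                       coupling_amplitude = 0, seed = 21))
  R <- suppressWarnings(pearson_matrix(sim$traces))
  expect_lt(mean(abs(R[upper.tri(R)])), 0.03)
})

test_that("the closed-form expected correlation behaves at its edges", {
  sp0 <- islet_sim_spec(coupling_amplitude = 0, f0_sd = 0)
  expect_equal(expected_pairwise_r(sp0), 0)
  sp1 <- islet_sim_spec(noise_sd = 0, f0_sd = 0)
  expect_equal(expected_pairwise_r(sp1), 1)
  # a^2 v = sigma^2  =>  R = 1/2, by calibrating the noise to the signal
  base <- islet_sim_spec(f0_sd = 0)
  half <- islet_sim_spec(f0_sd = 0, noise_sd = noise_sd_for_target_r(base, 0.5))
  expect_equal(expected_pairwise_r(half), 0.5, tolerance = 1e-12)
  expect_error(expected_pairwise_r(islet_sim_spec(phase_jitter_s = 2, f0_sd = 0)),
               "closed form")
  expect_error(expected_pairwise_r(islet_sim_spec(drift_slope = 0.1, f0_sd = 0)),
               "closed form")
  expect_error(expected_pairwise_r(islet_sim_spec(f0_sd = 10)), "f0_sd")
})

test_that("ranked-list simulation sorts, plants, and validates", {
  sim <- simulate_ranked_list(100, 5, shift = 0, seed = 1)
  expect_equal(nrow(sim$ranked), 100L)
  expect_true(all(diff(sim$ranked$stat) <= 0))
  expect_length(sim$gene_set$members, 5L)
  # a huge shift puts all members in the top ranks, across seeds
  for (s in 1:20) {
    sim <- simulate_ranked_list(100, 5, shift = 10, seed = s)
    expect_setequal(sim$ranked$gene[1:5], sim$gene_set$members)
  }
  expect_error(simulate_ranked_list(10, 10, seed = 1), "set_size")
})

test_that("null ranked lists score at the permutation-null mean", {
  # with shift = 0 the planted set is exchangeable with any random set,
  # so the mean observed ES over seeds matches the permutation-null mean
  obs <- vapply(1:100, function(s) {
    sim <- simulate_ranked_list(100, 10, shift = 0, seed = s)
    enrichment_score(sim$ranked, sim$gene_set)$es
  }, 0)
  sim1 <- simulate_ranked_list(100, 10, shift = 0, seed = 1)
  null_es <- with(sim1, {
    set.seed(7)
    vapply(1:400, function(b) {
      gs <- gene_set("null", sample(ranked$gene, 10))
      enrichment_score(ranked, gs)$es
    }, 0)
  })
  se <- sqrt(var(obs) / length(obs) + var(null_es) / length(null_es))
  expect_lt(abs(mean(obs) - mean(null_es)), 4 * se)
})

test_that("ground truth and coordinates serialise to plain text", {
  sim <- simulate_islet(islet_sim_spec(n_cells = 6, n_frames = 50, seed = 2))
  mp <- tempfile(); ep <- tempfile(); cp <- tempfile()
  write_ground_truth(sim$truth, mp, ep)
  mask <- read.delim(mp)
  expect_identical(mask$coupled, unname(sim$truth$coupled_mask))
  edges <- read.delim(ep)
  expect_equal(nrow(edges), nrow(sim$truth$true_edges))
  write_coords(sim$coords, cp)
  expect_equal(read_coords(cp), sim$coords, tolerance = 1e-12)
})
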