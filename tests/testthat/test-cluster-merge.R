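test_that("pairwise CC behaves like a Pearson correlation on common uniques", {
  a <- tiny_refl_set("a", c(1, 2, 3, 4))
  expect_equal(cc_common(a, a, min_common = 3)$cc, 1)

  b <- tiny_refl_set("b", 2.5 * c(1, 2, 3, 4))
  expect_equal(cc_common(a, b, min_common = 3)$cc, 1)   # scale-invariant

  anti <- tiny_refl_set("c", c(4, 3, 2, 1))
  pc <- cc_common(a, anti, min_common = 3)
  expect_equal(pc$cc, -1)
  expect_equal(pc$n_common, 4L)

  few <- cc_common(a, b, min_common = 10)
  expect_true(is.na(few$cc))

  other <- tiny_refl_set("d", c(1, 2, 3, 4), laue = "4/m")
  expect_error(cc_common(a, other), "Laue")
})

test_that("the correlation distance transform and inverse are consistent", {
  expect_equal(cc_to_distance(1), 0)
  expect_equal(cc_to_distance(0), 1)
  expect_equal(cc_to_distance(NA), 1)
  expect_equal(cc_to_distance(-0.5), 1)
  expect_equal(cc_to_distance(0.98), sqrt(1 - 0.98^2))

  grid <- seq(0, 1, by = 0.001)
  d <- cc_to_distance(grid)
  expect_true(all(diff(d) < 0))                      # strictly decreasing
  expect_equal(distance_to_cc(d), grid, tolerance = 1e-12)
})

test_that("reflection clustering handles degenerate cuts", {
  a <- tiny_refl_set("a", c(1, 5, 2, 8))
  b <- tiny_refl_set("b", c(1, 5, 2, 8))
  cl <- cluster_reflections(list(a, b), cut = 0.2, min_common = 3)
  expect_equal(length(unique(cl$assignment$cluster)), 1)

  cl0 <- cluster_reflections(list(a, b), cut = 0, min_common = 3)
  expect_equal(sort(cl0$assignment$cluster), 1:2)
})

test_that("reflection clustering separates same-cell phases (5 seeds)", {
  for (seed in 1:5) {
    sim <- simulate_mixture("similar_cells", n_per_phase = 10, seed = seed)
    prepped <- lapply(sim$sets, function(s) {
      merge_within(filter_reflections(s, d_min = 1.2, min_i_over_sigma = 2))
    })
    cl <- cluster_reflections(prepped, cut = 0.4)
    truth <- sim$labels$phase[match(cl$assignment$id, sim$labels$dataset_id)]
    tab <- table(cl$assignment$cluster, truth)
    expect_equal(sum(apply(tab, 1, max)), 20, info = paste("seed", seed))
    expect_equal(nrow(tab), 2, info = paste("seed", seed))
  }
})

test_that("scaling recovers planted factors", {
  a <- tiny_refl_set("a", c(10, 40, 25, 60))
  b <- tiny_refl_set("b", c(10, 40, 25, 60))
  sc_dup <- scale_sets(list(a, b))
  expect_equal(sc_dup$scale, c(1, 1), tolerance = 1e-9)

  half <- tiny_refl_set("h", 0.5 * c(10, 40, 25, 60))
  sc2 <- scale_sets(list(a, half))
  expect_equal(sc2$scale[2], 2, tolerance = 1e-6)

  sim <- simulate_mixture("single", n_per_phase = 5, seed = 2, noise_frac = 0)
  prepped <- lapply(sim$sets, merge_within)
  sc <- scale_sets(prepped)
  true_scale <- vapply(seq_len(5), function(i) {
    cseed <- 2 + 1000 + i
    0.5 + 1.5 * (((cseed * 17) %% 100) / 99)
  }, numeric(1))
  ref <- which.max(sc$n_unique)
  expect_equal(sc$scale, true_scale[ref] / true_scale, tolerance = 1e-4)
})

test_that("disconnected common-reflection graphs are rejected with components", {
  a <- tiny_refl_set("a", c(1, 2, 3, 4))
  lonely <- refl_set("z", unit_cell(10, 10, 10), "mmm", "P",
                     tibble::tibble(h = 5, k = 5, l = 5, I = 3, sigma = 1),
                     merged = TRUE)
  expect_error(scale_sets(list(a, lonely)), "disconnected")
})

test_that("merging pools measurements and conserves their count", {
  a <- tiny_refl_set("a", c(10, 20, 30, 40))
  self <- merge_cluster(list(a, refl_set("a2", a$cell, "mmm", "P",
                                         a$reflections, merged = TRUE)))
  expect_equal(self$reflections$I, a$reflections$I)
  expect_equal(self$reflections$n_obs, rep(2L, 4))
  meas <- attr(self, "measurements")
  expect_equal(nrow(meas), 8)
  expect_equal(sum(self$reflections$n_obs), nrow(meas))

  far <- refl_set("far", unit_cell(12, 10, 10), "mmm", "P",
                  a$reflections, merged = TRUE)
  expect_error(merge_cluster(list(a, far)), "deviates")
})

test_that("two noiseless half-wedges reassemble the true intensity table", {
  ph <- phase_spec("p", unit_cell(13.4, 19.9, 20.1), seed = 4)
  tab <- simulate_phase_intensities(ph, d_min = 1.5)
  s1 <- simulate_crystal_dataset(tab, ph, crystal_sim_spec(
    "p", wedge_start = 0, wedge_range = 180, scale = 1, noise_frac = 0,
    sigma_floor = 0.01, seed = 21), "w1")$set
  s2 <- simulate_crystal_dataset(tab, ph, crystal_sim_spec(
    "p", wedge_start = 180, wedge_range = 180, scale = 2, noise_frac = 0,
    sigma_floor = 0.01, seed = 21), "w2")$set
  m1 <- merge_within(s1); m2 <- merge_within(s2)
  sc <- scale_sets(list(m1, m2))
  mg <- merge_cluster(list(m1, m2), sc)
  truth <- tab$I_true[match(paste(mg$reflections$h, mg$reflections$k,
                                  mg$reflections$l),
                            paste(tab$h, tab$k, tab$l))]
  expect_equal(nrow(mg$reflections), nrow(tab))    # union covers the table
  fac <- stats::median(mg$reflections$I / truth)   # overall scale is free
  expect_equal(mg$reflections$I, fac * truth, tolerance = 1e-9)
})

test_that("merge statistics honour their closed-form cases", {
  a <- tiny_refl_set("a", c(10, 20, 30, 40))
  dup <- merge_cluster(list(a, refl_set("a2", a$cell, "mmm", "P",
                                        a$reflections, merged = TRUE)))
  st <- compute_stats(dup, d_min = 4, seed = 1)
  expect_equal(st$r_meas, 0)
  expect_equal(st$cc_half, 1)

  # full enumeration observed -> 100%; half of it -> 50%
  cl <- unit_cell(10, 10, 10)
  u <- enumerate_unique(cl, "mmm", "P", d_min = 3.5)
  full <- refl_set("full", cl, "mmm", "P",
                   tibble::tibble(h = u$h, k = u$k, l = u$l,
                                  I = seq_len(nrow(u)) + 0.5, sigma = 1),
                   merged = TRUE)
  mg_full <- merge_cluster(list(full, refl_set("full2", cl, "mmm", "P",
                                               full$reflections,
                                               merged = TRUE)))
  expect_equal(compute_stats(mg_full, d_min = 3.5, seed = 1)$completeness, 100)

  stopifnot(nrow(u) %% 2 == 0)
  half_refl <- full$reflections[seq_len(nrow(u) / 2), ]
  half <- refl_set("half", cl, "mmm", "P", half_refl, merged = TRUE)
  mg_half <- merge_cluster(list(half, refl_set("half2", cl, "mmm", "P",
                                               half_refl, merged = TRUE)))
  expect_equal(compute_stats(mg_half, d_min = 3.5, seed = 1)$completeness, 50)
})

test_that("statistics are invariant to a global rescale of all inputs", {
  sim <- simulate_mixture("single", n_per_phase = 3, seed = 6)
  prepped <- lapply(sim$sets, merge_within)
  mg1 <- merge_cluster(prepped, scale_sets(prepped))
  st1 <- compute_stats(mg1, d_min = 1.2, seed = 3)

  boosted <- lapply(prepped, function(s) {
    r <- s$reflections
    r$I <- r$I * 1000; r$sigma <- r$sigma * 1000
    refl_set(s$dataset_id, s$cell, s$laue, s$centering, r, merged = TRUE)
  })
  mg2 <- merge_cluster(boosted, scale_sets(boosted))
  st2 <- compute_stats(mg2, d_min = 1.2, seed = 3)
  for (col in c("completeness", "r_meas", "cc_half", "mean_i_over_sigma",
                "mean_multiplicity")) {
    expect_equal(st1[[col]], st2[[col]], tolerance = 1e-9, info = col)
  }
})

test_that("completeness grows weakly as more wedges are merged", {
  sim <- simulate_mixture("single", n_per_phase = 6, seed = 8)
  prepped <- lapply(sim$sets, merge_within)
  comp <- vapply(2:6, function(k) {
    mg <- merge_cluster(prepped[1:k], scale_sets(prepped[1:k]))
    compute_stats(mg, d_min = 1.2, seed = 1)$completeness
  }, numeric(1))
  expect_true(all(diff(comp) >= 0))
})

test_that("cluster ranking prefers completeness, then CC_1/2, then R_meas", {
  tab <- tibble::tibble(cluster = 1:2, completeness = c(91.0, 96.6),
                        r_meas = c(0.2, 0.25), cc_half = c(0.959, 0.914))
  r <- rank_clusters(tab)
  expect_equal(r$cluster[1], 2)     # higher completeness wins

  tie <- tibble::tibble(cluster = 1:2, completeness = c(90, 90),
                        r_meas = c(0.2, 0.3), cc_half = c(0.91, 0.99))
  r2 <- rank_clusters(tie)
  expect_equal(r2$cluster[1], 2)    # CC_1/2 breaks the tie

  single <- tab[1, ]
  expect_equal(rank_clusters(single)$cluster, 1)
})
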