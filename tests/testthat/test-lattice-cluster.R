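test_that("average linkage reproduces the hand-traced UPGMA merges", {
  d <- matrix(0, 2, 2); d[1, 2] <- d[2, 1] <- 5
  tr <- average_linkage(d)
  expect_equal(tr$height, 5)

  d3 <- matrix(0, 3, 3)
  d3[1, 2] <- d3[2, 1] <- 2
  d3[1, 3] <- d3[3, 1] <- 6
  d3[2, 3] <- d3[3, 2] <- 8
  tr3 <- average_linkage(d3)
  expect_equal(sort(tr3$height), c(2, 7))   # {1,2}@2 then @(6+8)/2

  dbad <- d3; dbad[1, 2] <- NaN; dbad[2, 1] <- NaN
  expect_error(average_linkage(dbad), "NaN")
})

test_that("average linkage matches brute-force UPGMA on random instances", {
  set.seed(97)
  for (rep in 1:20) {
    x <- matrix(rnorm(10 * 3), ncol = 3)
    D <- as.matrix(dist(x))
    tr <- average_linkage(D)
    expect_equal(sort(tr$height), brute_upgma_heights(D), tolerance = 1e-9)
  }
})

test_that("merge heights are non-decreasing for random inputs", {
  set.seed(101)
  for (rep in 1:10) {
    D <- as.matrix(dist(matrix(runif(12 * 4), ncol = 4)))
    tr <- average_linkage(D)
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("dendrogram cuts form components strictly below the cut", {
  d3 <- matrix(0, 3, 3)
  d3[1, 2] <- d3[2, 1] <- 2
  d3[1, 3] <- d3[3, 1] <- 6
  d3[2, 3] <- d3[3, 2] <- 8
  tr3 <- average_linkage(d3)

  above <- cut_dendrogram(tr3, 100)
  expect_equal(length(unique(above$cluster)), 1)

  zero <- cut_dendrogram(tr3, 0)
  expect_equal(sort(zero$cluster), 1:3)

  mid <- cut_dendrogram(tr3, 4)
  expect_equal(mid$cluster[1], mid$cluster[2])
  expect_false(mid$cluster[3] == mid$cluster[1])
  # ordering rule: larger cluster first
  expect_equal(mid$cluster[1], 1)
})

test_that("cluster labels order by size with ties to the smallest member", {
  # 5 items: {3,4,5} and {1,2}
  D <- matrix(10, 5, 5); diag(D) <- 0
  D[3, 4] <- D[4, 3] <- 1; D[3, 5] <- D[5, 3] <- 1; D[4, 5] <- D[5, 4] <- 1
  D[1, 2] <- D[2, 1] <- 1
  asg <- cut_dendrogram(average_linkage(D), 2)
  expect_equal(asg$cluster, c(2, 2, 1, 1, 1))

  # equal sizes: the cluster holding item 1 gets label 1
  D2 <- matrix(10, 4, 4); diag(D2) <- 0
  D2[3, 4] <- D2[4, 3] <- 1; D2[1, 2] <- D2[2, 1] <- 1
  asg2 <- cut_dendrogram(average_linkage(D2), 2)
  expect_equal(asg2$cluster, c(1, 1, 2, 2))
})

test_that("cell clustering separates a two-phase mixture at the gap cut", {
  for (seed in 1:5) {
    sim <- simulate_mixture("distinct_cells", n_per_phase = 20, seed = seed)
    cl <- cluster_cells(sim$cells)
    truth <- sim$labels$phase[match(cl$cells$dataset_id,
                                    sim$labels$dataset_id)]
    tab <- table(cl$cells$cluster, truth)
    expect_equal(nrow(tab), 2)
    expect_equal(sum(apply(tab, 1, max)), 40)   # zero misassignments
  }
})

test_that("planted outlier cells are the last leaves to merge", {
  sim <- simulate_mixture("with_outliers", n_per_phase = 10, seed = 2)
  cl <- cluster_cells(sim$cells)
  m <- cl$tree$merge
  last_two <- c(m[nrow(m), ], m[nrow(m) - 1, ])
  leaves <- -last_two[last_two < 0]
  expect_setequal(cl$tree$labels[leaves], c("outlier_01", "outlier_02"))
})

test_that("histogram fits return windowed Gaussian MLE estimates", {
  tab <- random_cells_table(6, seed = 5)
  tab[, c("a", "b", "c")] <- list(rep(20.07, 6), rep(19.92, 6), rep(13.42, 6))
  tab[, c("alpha", "beta", "gamma")] <- list(rep(90, 6), rep(90, 6), rep(90, 6))
  fits <- fit_cell_histograms(tab)
  expect_equal(fits$mean[fits$parameter == "a"], 20.07)
  expect_equal(fits$sigma[fits$parameter == "a"], 0)

  set.seed(11)
  n <- 200
  tab2 <- tibble::tibble(
    dataset_id = as.character(1:n),
    a = rnorm(n, 20.07, 0.5), b = rnorm(n, 19.92, 0.5),
    c = rnorm(n, 13.42, 0.5),
    alpha = rnorm(n, 90, 1), beta = rnorm(n, 90, 1), gamma = rnorm(n, 90, 1),
    lattice_type = "oP", n_indexed = 100L, rotation_range = 10)
  fits2 <- fit_cell_histograms(tab2, windows = list(a = c(18, 22)))
  se <- 0.5 / sqrt(n)
  expect_lt(abs(fits2$mean[fits2$parameter == "a"] - 20.07), 3 * se)

  # a window that excludes planted outliers reports the reduced count
  tab3 <- tab2
  tab3$a[1:5] <- 40
  fits3 <- fit_cell_histograms(tab3, windows = list(a = c(18, 22)))
  expect_equal(fits3$n_in_window[fits3$parameter == "a"], n - 5)
  expect_error(fit_cell_histograms(tab3, windows = list(a = c(50, 60))),
               "'a'")
})

test_that("lattice-type voting sums indexed reflections per symbol", {
  tab <- random_cells_table(3, seed = 9)
  tab$lattice_type <- c("oP", "oP", "mC")
  tab$n_indexed <- c(100L, 200L, 250L)
  v <- vote_lattice_type(tab)
  expect_equal(v$lattice_type[1], "oP")
  expect_equal(v$n_indexed[1], 300)

  tab$n_indexed <- c(100L, 200L, 300L)   # tie at 300
  v2 <- vote_lattice_type(tab)
  expect_equal(v2$lattice_type, c("mC", "oP"))
  expect_equal(v2$n_indexed, c(300, 300))

  single <- tab[1, ]; single$n_indexed <- 500L
  expect_equal(vote_lattice_type(single)$n_indexed, 500)

  tab$lattice_type <- ""
  expect_error(vote_lattice_type(tab), "lattice type")
})
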