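test_that("operator sets are closed groups of the expected order", {
  orders <- c("-1" = 2, "2/m" = 4, "mmm" = 8, "4/m" = 8, "4/mmm" = 16,
              "-3" = 6, "-3m" = 12, "6/m" = 12, "6/mmm" = 24,
              "m-3" = 24, "m-3m" = 48)
  for (s in laue_symbols()) {
    lg <- laue_group(s)
    expect_equal(lg$order, unname(orders[s]), info = s)
    keys <- vapply(lg$ops, function(m) paste(as.integer(m), collapse = ","),
                   character(1))
    expect_true(any(keys == paste(as.integer(diag(3)), collapse = ",")),
                info = s)
    expect_true(any(keys == paste(as.integer(-diag(3)), collapse = ",")),
                info = s)
    # exhaustive closure under composition
    for (m1 in lg$ops) for (m2 in lg$ops) {
      expect_true(paste(as.integer(m1 %*% m2), collapse = ",") %in% keys,
                  info = s)
    }
  }
})

test_that("asu_map is idempotent and constant on orbits", {
  expect_equal(unname(asu_map("mmm", c(-1, 2, -3))[1, ]), c(1, 2, 3))
  set.seed(5)
  for (s in laue_symbols()) {
    lg <- laue_group(s)
    hkl <- matrix(sample(-8:8, 30, replace = TRUE), ncol = 3)
    hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
    canon <- asu_map(lg, hkl)
    expect_equal(asu_map(lg, canon), canon, info = s)     # idempotent
    for (m in lg$ops) {
      expect_equal(asu_map(lg, hkl %*% m), canon, info = s)  # orbit-invariant
    }
  }
})

test_that("asu_map matches the brute-force orbit maximum in m-3m", {
  set.seed(13)
  hkl <- unique(matrix(sample(-9:9, 300, replace = TRUE), ncol = 3))
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE][1:100, ]
  canon <- asu_map("m-3m", hkl)
  for (i in seq_len(nrow(hkl))) {
    expect_equal(unname(canon[i, ]), unname(orbit_max_oracle("m-3m", hkl[i, ])))
  }
})

test_that("d_spacing is invariant under metrically consistent Laue operators", {
  for (case in laue_test_cases()) {
    cl <- as_unit_cell(case$cell)
    lg <- laue_group(case$symbol)
    hkl <- rbind(c(1, 2, 3), c(2, 0, 1), c(3, -1, 2))
    d0 <- d_spacing(cl, hkl)
    for (m in lg$ops) {
      expect_equal(d_spacing(cl, hkl %*% m), d0, tolerance = 1e-9,
                   info = case$symbol)
    }
  }
})

test_that("enumerate_unique reproduces the cubic closed-form example", {
  u <- enumerate_unique(unit_cell(10, 10, 10), "m-3m", "P", d_min = 5)
  expect_equal(nrow(u), 4)
  expect_setequal(paste(u$h, u$k, u$l),
                  c("1 0 0", "1 1 0", "1 1 1", "2 0 0"))
  expect_equal(nrow(enumerate_unique(unit_cell(10, 10, 10), "m-3m", "P",
                                     d_min = 11)), 0)
})

test_that("I-centering removes exactly the odd-sum reflections", {
  cl <- unit_cell(7, 7, 10)
  uP <- enumerate_unique(cl, "4/mmm", "P", d_min = 2)
  uI <- enumerate_unique(cl, "4/mmm", "I", d_min = 2)
  keep <- (uP$h + uP$k + uP$l) %% 2 == 0
  expect_equal(nrow(uI), sum(keep))
  expect_setequal(paste(uI$h, uI$k, uI$l),
                  paste(uP$h[keep], uP$k[keep], uP$l[keep]))
})

test_that("unique count times orbit sizes conserves the sphere count", {
  for (case in laue_test_cases()[c(1, 3, 5, 7, 11)]) {
    cl <- as_unit_cell(case$cell)
    u <- enumerate_unique(cl, case$symbol, case$centering, d_min = 2.5)
    orbit_sizes <- vapply(seq_len(nrow(u)), function(i) {
      orb <- orbit_oracle(case$symbol, c(u$h[i], u$k[i], u$l[i]))
      sum(apply(orb, 1, function(v) {
        isTRUE(centering_oracle(case$centering, v)) &&
          d_oracle(unclass(cl), v) >= 2.5
      }))
    }, numeric(1))
    ref <- enumerate_oracle(unclass(cl), case$symbol, case$centering, 2.5)
    expect_equal(sum(orbit_sizes), ref$n_all, info = case$symbol)
  }
})

test_that("within-dataset merging follows the mean/sigma/multiplicity rules", {
  cl <- unit_cell(10, 10, 10)
  s <- refl_set("m", cl, "mmm", "P",
                tibble::tibble(h = c(1, -1), k = c(2, -2), l = c(3, -3),
                               I = c(10, 20), sigma = c(1, 1)))
  m <- merge_within(s)
  expect_equal(nrow(m$reflections), 1)
  expect_equal(m$reflections$I, 15)
  expect_equal(m$reflections$sigma, sqrt(2) / 2)
  expect_equal(m$reflections$n_obs, 2L)
  expect_identical(merge_within(m), m)   # idempotent

  set.seed(17)
  hkl <- matrix(sample(-5:5, 120, replace = TRUE), ncol = 3)
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  s2 <- refl_set("m2", cl, "4/m", "P",
                 tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                                I = runif(nrow(hkl)), sigma = 1))
  m2 <- merge_within(s2)
  expect_equal(sum(m2$reflections$n_obs), nrow(hkl))  # conservation
})

test_that("reflection filters respect boundaries and log removals", {
  cl <- unit_cell(10, 10, 10)
  s <- refl_set("f", cl, "-1", "P",
                tibble::tibble(h = 1:3, k = 0L, l = 0L,
                               I = c(1.9, 2, 5), sigma = 1))
  kept <- filter_reflections(s, min_i_over_sigma = 2)
  expect_equal(nrow(kept$reflections), 2)   # boundary inclusive
  expect_identical(filter_reflections(s)$reflections, s$reflections)
  expect_error(filter_reflections(s, d_min = 3, d_max = 2), "d_min")

  # enumeration oracle for the resolution cut on a cubic lattice
  grid <- as.matrix(expand.grid(h = -3:3, k = -3:3, l = -3:3))
  grid <- grid[rowSums(grid != 0) > 0 & rowSums(grid^2) <= 9, ]
  s3 <- refl_set("f3", cl, "-1", "P",
                 tibble::tibble(h = grid[, 1], k = grid[, 2], l = grid[, 3],
                                I = 10, sigma = 1))
  kept3 <- filter_reflections(s3, d_min = 5)
  expect_true(all(rowSums(as.matrix(
    kept3$reflections[, c("h", "k", "l")])^2) <= 4))
  expect_equal(nrow(kept3$reflections), sum(rowSums(grid^2) <= 4))
})

test_that("reindexing operators act as a group and permute the cell", {
  cl <- unit_cell(10, 12, 14)
  s <- refl_set("r", cl, "mmm", "P",
                tibble::tibble(h = c(1, 2), k = c(2, 3), l = c(3, 4),
                               I = c(5, 6), sigma = 1))
  ident <- reindex_op(diag(3))
  expect_equal(apply_reindex(s, ident)$reflections, s$reflections)

  cyc <- reindex_op(c(0, 0, 1, 1, 0, 0, 0, 1, 0))   # a'=b, b'=c, c'=a
  s3x <- apply_reindex(apply_reindex(apply_reindex(s, cyc), cyc), cyc)
  expect_equal(s3x$reflections, s$reflections)       # order-3 cycle
  expect_equal(unclass(apply_reindex(s, cyc)$cell)[1:3],
               c(a = 12, b = 14, c = 10))
  expect_error(reindex_op(matrix(c(2, 0, 0, 0, 1, 0, 0, 0, 1), 3)), "det")
})
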