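# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles, not by calling the package's
# own code paths.

# Brute-force UPGMA: explicit cluster lists, all cross-pair means recomputed
# at every step. Returns the sorted merge heights.
brute_upgma_heights <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(members) > 1) {
    best_d <- Inf; best <- c(NA, NA)
    for (i in seq_along(members)) {
      for (j in seq_len(i - 1)) {
        d <- mean(D[members[[i]], members[[j]], drop = FALSE])
        if (d < best_d) { best_d <- d; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_d)
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  sort(heights)
}

# Cell volume via the Cartesian triple product a . (b x c), built directly
# from the textbook basis-vector construction (not the metric determinant).
volume_oracle <- function(a, b, c, al, be, ga) {
  d2r <- pi / 180
  va <- c(a, 0, 0)
  vb <- c(b * cos(ga * d2r), b * sin(ga * d2r), 0)
  cx <- c * cos(be * d2r)
  cy <- c * (cos(al * d2r) - cos(be * d2r) * cos(ga * d2r)) / sin(ga * d2r)
  cz <- sqrt(max(0, c^2 - cx^2 - cy^2))
  vc <- c(cx, cy, cz)
  cross <- c(vb[2] * vc[3] - vb[3] * vc[2],
             vb[3] * vc[1] - vb[1] * vc[3],
             vb[1] * vc[2] - vb[2] * vc[1])
  abs(sum(va * cross))
}

# d-spacing via numeric inversion of the direct metric tensor, assembled
# here independently.
d_oracle <- function(cell, hkl) {
  d2r <- pi / 180
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  ca <- cos(cell[4] * d2r); cb <- cos(cell[5] * d2r); cg <- cos(cell[6] * d2r)
  G <- matrix(c(a^2, a * b * cg, a * cc * cb,
                a * b * cg, b^2, b * cc * ca,
                a * cc * cb, b * cc * ca, cc^2), 3, 3)
  hkl <- matrix(hkl, ncol = 3)
  apply(hkl, 1, function(v) 1 / sqrt(drop(t(v) %*% solve(G) %*% v)))
}

# Independent Laue generator sets (index images written out longhand) and a
# BFS orbit expansion that never uses the package's closed operator lists.
oracle_generators <- function(symbol) {
  gen <- list(
    inv = function(v) -v,
    two_z = function(v) c(-v[1], -v[2], v[3]),
    two_y = function(v) c(-v[1], v[2], -v[3]),
    four_z = function(v) c(-v[2], v[1], v[3]),
    three_h = function(v) c(v[2], -v[1] - v[2], v[3]),
    six_h = function(v) c(-v[2], v[1] + v[2], v[3]),
    two_d = function(v) c(v[2], v[1], -v[3]),
    three_c = function(v) c(v[3], v[1], v[2]))
  switch(symbol,
    "-1"    = gen[c("inv")],
    "2/m"   = gen[c("inv", "two_y")],
    "mmm"   = gen[c("inv", "two_y", "two_z")],
    "4/m"   = gen[c("inv", "four_z")],
    "4/mmm" = gen[c("inv", "four_z", "two_d")],
    "-3"    = gen[c("inv", "three_h")],
    "-3m"   = gen[c("inv", "three_h", "two_d")],
    "6/m"   = gen[c("inv", "six_h")],
    "6/mmm" = gen[c("inv", "six_h", "two_d")],
    "m-3"   = gen[c("inv", "two_z", "two_y", "three_c")],
    "m-3m"  = gen[c("inv", "two_z", "two_y", "three_c", "two_d")])
}

orbit_oracle <- function(symbol, hkl) {
  gens <- oracle_generators(symbol)
  seen <- new.env()
  queue <- list(as.numeric(hkl))
  out <- list()
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    key <- paste(v, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1]] <- v
    for (g in gens) queue <- c(queue, list(g(v)))
  }
  do.call(rbind, out)
}

orbit_max_oracle <- function(symbol, hkl) {
  orb <- orbit_oracle(symbol, hkl)
  orb[order(orb[, 1], orb[, 2], orb[, 3], decreasing = TRUE)[1], ]
}

centering_oracle <- function(centering, v) {
  switch(centering,
    P = TRUE,
    A = (v[2] + v[3]) %% 2 == 0,
    B = (v[1] + v[3]) %% 2 == 0,
    C = (v[1] + v[2]) %% 2 == 0,
    I = sum(v) %% 2 == 0,
    F = length(unique(v %% 2)) == 1,
    R = (-v[1] + v[2] + v[3]) %% 3 == 0)
}

# Brute-force unique enumeration: walk an index box, keep allowed in-sphere
# reflections, reduce each through orbit_max_oracle, deduplicate.
enumerate_oracle <- function(cell, symbol, centering, d_min) {
  hmax <- ceiling(cell[1:3] / d_min) + 1
  uniq <- new.env()
  n_all <- 0
  for (h in -hmax[1]:hmax[1]) for (k in -hmax[2]:hmax[2])
    for (l in -hmax[3]:hmax[3]) {
      v <- c(h, k, l)
      if (all(v == 0)) next
      if (d_oracle(cell, v) < d_min) next
      if (!centering_oracle(centering, v)) next
      n_all <- n_all + 1
      m <- orbit_max_oracle(symbol, v)
      uniq[[paste(m, collapse = ",")]] <- m
    }
  list(uniques = do.call(rbind, as.list(uniq)), n_all = n_all)
}

# Metrically consistent test cells (and centerings) for each Laue class.
laue_test_cases <- function() {
  list(
    list(symbol = "-1",    cell = c(6.1, 7.3, 8.7, 82, 95, 104), centering = "P"),
    list(symbol = "2/m",   cell = c(6, 8, 10, 90, 101, 90),      centering = "C"),
    list(symbol = "mmm",   cell = c(6, 8, 10, 90, 90, 90),       centering = "P"),
    list(symbol = "4/m",   cell = c(7, 7, 10, 90, 90, 90),       centering = "P"),
    list(symbol = "4/mmm", cell = c(7, 7, 10, 90, 90, 90),       centering = "I"),
    list(symbol = "-3",    cell = c(8, 8, 10, 90, 90, 120),      centering = "P"),
    list(symbol = "-3m",   cell = c(8, 8, 10, 90, 90, 120),      centering = "R"),
    list(symbol = "6/m",   cell = c(8, 8, 10, 90, 90, 120),      centering = "P"),
    list(symbol = "6/mmm", cell = c(8, 8, 10, 90, 90, 120),      centering = "P"),
    list(symbol = "m-3",   cell = c(8, 8, 8, 90, 90, 90),        centering = "P"),
    list(symbol = "m-3m",  cell = c(8, 8, 8, 90, 90, 90),        centering = "F"))
}

random_cell <- function() {
  repeat {
    cl <- try(unit_cell(runif(1, 5, 30), runif(1, 5, 30), runif(1, 5, 30),
                        runif(1, 60, 120), runif(1, 60, 120),
                        runif(1, 60, 120)), silent = TRUE)
    if (!inherits(cl, "try-error")) return(cl)
  }
}
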