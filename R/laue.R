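#' Laue groups
#'
#' The 11 Laue classes are the possible point symmetries of diffraction
#' intensities (crystal class combined with inversion, since Friedel pairs
#' are equivalent for intensity data). A `laue_group` carries the symbol and
#' the full set of 3x3 integer matrices acting on Miller indices as row
#' vectors: `hkl' = hkl %*% M`.
#'
#' Conventions: monoclinic unique axis b; trigonal/rhombohedral groups in
#' the hexagonal setting (use centering `"R"`, obverse, for rhombohedral
#' lattices); the -3m class uses the -3m1 setting (twofold axes normal to
#' the hexagonal a axes), which is the setting compatible with R-centred
#' lattices.
#'
#' @param symbol One of `"-1"`, `"2/m"`, `"mmm"`, `"4/m"`, `"4/mmm"`,
#'   `"-3"`, `"-3m"`, `"6/m"`, `"6/mmm"`, `"m-3"`, `"m-3m"`.
#' @return An object of class `laue_group`: list with `symbol`, `ops`
#'   (list of 3x3 integer matrices, including the identity and -identity)
#'   and `order`.
#' @examples
#' lg <- laue_group("mmm")
#' lg$order  # 8
#' @export
laue_group <- function(symbol) {
  if (inherits(symbol, "laue_group")) return(symbol)
  gens <- laue_generators(symbol)
  ops <- group_closure(gens)
  expected <- laue_orders()[[symbol]]
  stopifnot(length(ops) == expected)
  structure(list(symbol = symbol, ops = ops, order = length(ops)),
            class = "laue_group")
}

#' @rdname laue_group
#' @export
laue_symbols <- function() names(laue_orders())

laue_orders <- function() {
  list("-1" = 2, "2/m" = 4, "mmm" = 8, "4/m" = 8, "4/mmm" = 16,
       "-3" = 6, "-3m" = 12, "6/m" = 12, "6/mmm" = 24,
       "m-3" = 24, "m-3m" = 48)
}

# Generator matrices act on row vectors: hkl' = hkl %*% M. Columns of M are
# the images' coefficients; matrices below are written so that the mapping
# reads off the commented index images.
laue_generators <- function(symbol) {
  inv <- -diag(3)
  two_z <- diag(c(-1, -1, 1))          # (h,k,l) -> (-h,-k, l)
  two_y <- diag(c(-1, 1, -1))          # (h,k,l) -> (-h, k,-l)
  four_z <- matrix(c(0, 1, 0,          # (h,k,l) -> (-k, h, l)
                     -1, 0, 0,
                     0, 0, 1), nrow = 3, byrow = TRUE)
  three_hex <- matrix(c(0, -1, 0,      # (h,k,l) -> ( k,-h-k, l)
                        1, -1, 0,
                        0, 0, 1), nrow = 3, byrow = TRUE)
  six_hex <- matrix(c(0, 1, 0,         # (h,k,l) -> (-k, h+k, l)
                      -1, 1, 0,
                      0, 0, 1), nrow = 3, byrow = TRUE)
  two_110 <- matrix(c(0, 1, 0,         # (h,k,l) -> ( k, h,-l)
                      1, 0, 0,
                      0, 0, -1), nrow = 3, byrow = TRUE)
  three_111 <- matrix(c(0, 0, 1,       # (h,k,l) -> ( l, h, k)
                        1, 0, 0,
                        0, 1, 0), nrow = 3, byrow = TRUE)
  switch(symbol,
    "-1"    = list(inv),
    "2/m"   = list(two_y, inv),
    "mmm"   = list(two_z, two_y, inv),
    "4/m"   = list(four_z, inv),
    "4/mmm" = list(four_z, two_110, inv),
    "-3"    = list(three_hex, inv),
    "-3m"   = list(three_hex, two_110, inv),
    "6/m"   = list(six_hex, inv),
    "6/mmm" = list(six_hex, two_110, inv),
    "m-3"   = list(three_111, two_z, two_y, inv),
    "m-3m"  = list(three_111, two_z, two_y, two_110, inv),
    stop("unknown Laue symbol: ", symbol, call. = FALSE)
  )
}

# Close a generator list under matrix multiplication (groups here are tiny,
# order <= 48, so repeated sweeps are fine).
group_closure <- function(gens) {
  storage.mode(gens[[1]]) <- "double"
  key <- function(m) paste(as.integer(m), collapse = ",")
  ops <- list(diag(3))
  names(ops) <- key(diag(3))
  queue <- gens
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    k <- key(m)
    if (!is.null(ops[[k]])) next
    ops[[k]] <- m
    for (o in ops) {
      queue <- c(queue, list(o %*% m), list(m %*% o))
    }
  }
  unname(ops)
}

#' @export
print.laue_group <- function(x, ...) {
  cat(sprintf("<laue_group> %s  order %d\n", x$symbol, x$order))
  invisible(x)
}

#' Map Miller indices to their asymmetric-unit representative
#'
#' The canonical representative of the symmetry orbit of `hkl` under a Laue
#' group is defined as the lexicographic maximum (on h, then k, then l) over
#' the full orbit `{hkl %*% M}`. The map is idempotent and constant on
#' orbits, so two measurements of symmetry-equivalent reflections receive
#' the same index.
#'
#' @param laue A [laue_group()] or its symbol.
#' @param hkl Length-3 vector or n x 3 matrix/data frame of indices.
#' @return Matrix of the same shape (n x 3) of canonical indices.
#' @examples
#' asu_map("mmm", c(-1, 2, -3))  # (1, 2, 3)
#' @export
asu_map <- function(laue, hkl) {
  laue <- laue_group(laue)
  hkl <- as_hkl_matrix(hkl)
  n <- nrow(hkl)
  best <- hkl %*% laue$ops[[1]]
  for (m in laue$ops[-1]) {
    cand <- hkl %*% m
    repl <- (cand[, 1] > best[, 1]) |
      (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
      (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
    if (any(repl)) best[repl, ] <- cand[repl, , drop = FALSE]
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}

#' Lattice-centering extinction rule
#'
#' @param centering One of `"P"`, `"A"`, `"B"`, `"C"`, `"I"`, `"F"`, `"R"`
#'   (R = rhombohedral obverse in the hexagonal setting: -h+k+l = 0 mod 3).
#' @param hkl n x 3 matrix of indices.
#' @return Logical vector: `TRUE` where the reflection is allowed.
#' @export
centering_allowed <- function(centering, hkl) {
  hkl <- as_hkl_matrix(hkl)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  switch(centering,
    P = rep(TRUE, length(h)),
    A = (k + l) %% 2 == 0,
    B = (h + l) %% 2 == 0,
    C = (h + k) %% 2 == 0,
    I = (h + k + l) %% 2 == 0,
    F = (h %% 2 == k %% 2) & (k %% 2 == l %% 2),
    R = (-h + k + l) %% 3 == 0,
    stop("unknown centering: ", centering, call. = FALSE)
  )
}

#' Enumerate the symmetry-unique reflections to a resolution limit
#'
#' All centering-allowed Miller indices with d >= `d_min`, reduced to their
#' asymmetric-unit representatives and deduplicated; (0,0,0) is excluded.
#' This is the denominator of completeness. Index bounds are derived from
#' the cell edges (`ceiling(a/d_min)` etc. plus a safety margin).
#'
#' @param cell A [unit_cell()].
#' @param laue A [laue_group()] or symbol.
#' @param centering Centering letter, see [centering_allowed()].
#' @param d_min Resolution limit in Angstrom (> 0).
#' @param max_reflections Guard against runaway enumeration: error if the
#'   index box holds more than this many candidate reflections.
#' @return Tibble with columns `h, k, l` (canonical) and `d` (Angstrom),
#'   sorted by decreasing d.
#' @examples
#' enumerate_unique(unit_cell(10, 10, 10), "m-3m", "P", d_min = 5)
#' @export
enumerate_unique <- function(cell, laue, centering = "P", d_min,
                             max_reflections = 2e6) {
  stopifnot(d_min > 0)
  cell <- as_unit_cell(cell)
  laue <- laue_group(laue)
  hmax <- ceiling(cell[1:3] / d_min) + 1
  if (prod(2 * hmax + 1) > max_reflections) {
    stop("enumeration bound exceeds ", max_reflections,
         " candidate reflections; increase d_min", call. = FALSE)
  }
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  gstar <- solve(metric_tensor(cell))
  d <- 1 / sqrt(rowSums((grid %*% gstar) * grid))
  keep <- d >= d_min & centering_allowed(centering, grid)
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  canon <- asu_map(laue, grid)
  uid <- paste(canon[, 1], canon[, 2], canon[, 3])
  first <- !duplicated(uid)
  out <- tibble::tibble(h = canon[first, 1], k = canon[first, 2],
                        l = canon[first, 3], d = d[first])
  dplyr::arrange(out, dplyr::desc(.data$d), .data$h, .data$k, .data$l)
}

#' Reindexing operators
#'
#' A reindexing operator is a 3x3 integer matrix M with |det M| = 1 mapping
#' Miller indices as `hkl' = hkl %*% M`. Such operators express indexing
#' ambiguities: lattices whose cell edges are (nearly) equal admit several
#' metrically consistent but symmetry-inequivalent index assignments, and
#' datasets indexed in different conventions only correlate after one of
#' them is reindexed (e.g. the axis permutation a'=b, b'=c, c'=a).
#'
#' @param m A 3x3 integer matrix, or a length-9 vector row-major.
#' @return The validated matrix with class `reindex_op`.
#' @examples
#' reindex_op(c(0, 0, 1, 1, 0, 0, 0, 1, 0))  # a'=b, b'=c, c'=a
#' @export
reindex_op <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 3, byrow = TRUE)
  stopifnot(all(dim(m) == c(3, 3)), all(m == round(m)))
  storage.mode(m) <- "double"
  if (abs(round(det(m))) != 1) {
    stop("reindex operator must have |det| = 1", call. = FALSE)
  }
  structure(m, class = c("reindex_op", "matrix"))
}
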