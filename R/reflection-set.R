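#' Reflection sets
#'
#' A reflection set is one crystal's indexed intensity list together with
#' the metadata needed for symmetry handling: the unit cell, the Laue group,
#' the lattice centering, and whether symmetry-equivalent measurements have
#' already been merged. Intensities are on an arbitrary per-crystal scale
#' (each crystal diffracts differently); inter-dataset scaling happens at
#' the merging step.
#'
#' @param dataset_id Identifier string.
#' @param cell A [unit_cell()].
#' @param laue Laue symbol or [laue_group()].
#' @param centering Centering letter (see [centering_allowed()]).
#' @param reflections Tibble/data frame with columns `h, k, l` (integers,
#'   not all zero), `I` (finite) and `sigma` (> 0). An optional `n_obs`
#'   column carries multiplicities of already-merged records.
#' @param merged Logical: are records unique under the Laue group already?
#' @return Object of class `refl_set`.
#' @export
refl_set <- function(dataset_id, cell, laue, centering = "P",
                     reflections, merged = FALSE) {
  cell <- as_unit_cell(cell)
  laue <- laue_group(laue)
  refl <- tibble::as_tibble(reflections)
  stopifnot(all(c("h", "k", "l", "I", "sigma") %in% names(refl)))
  refl$h <- as.integer(refl$h); refl$k <- as.integer(refl$k)
  refl$l <- as.integer(refl$l)
  if (nrow(refl)) {
    if (any(refl$h == 0 & refl$k == 0 & refl$l == 0)) {
      stop("reflection (0,0,0) is not allowed", call. = FALSE)
    }
    if (any(!is.finite(refl$I))) stop("non-finite intensity", call. = FALSE)
    if (any(!is.finite(refl$sigma) | refl$sigma <= 0)) {
      stop("sigma must be positive and finite", call. = FALSE)
    }
  }
  if (!"n_obs" %in% names(refl)) refl$n_obs <- 1L
  x <- structure(list(dataset_id = dataset_id, cell = cell, laue = laue,
                      centering = centering, reflections = refl,
                      merged = merged),
                 class = "refl_set")
  if (merged) {
    uid <- asu_uid(laue, refl)
    if (anyDuplicated(uid)) {
      stop("merged set has duplicated asymmetric-unit indices", call. = FALSE)
    }
  }
  x
}

asu_uid <- function(laue, refl) {
  canon <- asu_map(laue, refl)
  paste(canon[, 1], canon[, 2], canon[, 3])
}

#' @export
print.refl_set <- function(x, ...) {
  cat(sprintf("<refl_set> %s: %d reflections (%s), Laue %s, centering %s\n",
              x$dataset_id, nrow(x$reflections),
              if (x$merged) "merged" else "unmerged",
              x$laue$symbol, x$centering))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reflection set into a tibble
#' @param x A [refl_set()].
#' @param ... Unused.
#' @return The reflection tibble with a `d` (resolution) column appended.
#' @method tidy refl_set
#' @export
tidy.refl_set <- function(x, ...) {
  refl <- x$reflections
  if (nrow(refl)) refl$d <- d_spacing(x$cell, refl) else refl$d <- numeric()
  refl
}

#' Merge symmetry-equivalent measurements within one dataset
#'
#' Measurements are grouped by their asymmetric-unit index (Friedel mates
#' always merge, since every Laue group contains -1). Per unique reflection
#' the merged intensity is the unweighted mean, the merged sigma is
#' \eqn{\sqrt{\sum \sigma_i^2}/n} (error propagation of the mean), and the
#' multiplicity n is recorded in `n_obs`. Already-merged sets pass through
#' unchanged.
#'
#' @param set A [refl_set()].
#' @param weighted Use inverse-variance weights instead of the unweighted
#'   mean (off by default; robust when sigma models differ between sources).
#' @return A merged [refl_set()] whose records carry canonical indices.
#' @export
merge_within <- function(set, weighted = FALSE) {
  stopifnot(inherits(set, "refl_set"))
  if (set$merged) return(set)
  refl <- set$reflections
  if (!nrow(refl)) {
    return(refl_set(set$dataset_id, set$cell, set$laue, set$centering,
                    refl, merged = TRUE))
  }
  canon <- asu_map(set$laue, refl)
  refl$h <- canon[, 1]; refl$k <- canon[, 2]; refl$l <- canon[, 3]
  merged <- refl |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(
      I = if (weighted) {
        stats::weighted.mean(.data$I, 1 / .data$sigma^2)
      } else {
        mean(.data$I)
      },
      sigma = sqrt(sum(.data$sigma^2)) / dplyr::n(),
      n_obs = sum(.data$n_obs),
      .groups = "drop")
  refl_set(set$dataset_id, set$cell, set$laue, set$centering, merged,
           merged = TRUE)
}

#' Filter reflections by resolution and signal-to-noise
#'
#' Keeps reflections with `d_min <= d <= d_max` and `I/sigma >=
#' min_i_over_sigma` (boundaries inclusive). Mirrors the usual practice of
#' restricting the resolution range and requiring a minimum I/sigma
#' (typically 2) before computing inter-dataset correlations, so that
#' poorly measured reflections do not dominate the distance matrix.
#'
#' @param set A [refl_set()].
#' @param d_min,d_max Resolution window in Angstrom.
#' @param min_i_over_sigma Minimum I/sigma.
#' @return The filtered [refl_set()]; the counts removed by each criterion
#'   are attached as attribute `"removed"`.
#' @export
filter_reflections <- function(set, d_min = 0, d_max = Inf,
                               min_i_over_sigma = 0) {
  stopifnot(inherits(set, "refl_set"))
  if (d_min > d_max) stop("d_min > d_max", call. = FALSE)
  refl <- set$reflections
  if (!nrow(refl)) return(set)
  d <- d_spacing(set$cell, refl)
  ok_d <- d >= d_min & d <= d_max
  ok_sig <- refl$I / refl$sigma >= min_i_over_sigma
  out <- refl_set(set$dataset_id, set$cell, set$laue, set$centering,
                  refl[ok_d & ok_sig, , drop = FALSE], merged = set$merged)
  attr(out, "removed") <- c(resolution = sum(!ok_d),
                            i_over_sigma = sum(ok_d & !ok_sig))
  out
}

#' Apply a reindexing operator to a dataset
#'
#' Transforms all indices as `hkl' = hkl %*% M` and permutes the cell axes
#' consistently (|column entries| of M say which old axis each new index
#' refers to). Intensities are unchanged.
#'
#' @param set A [refl_set()].
#' @param op A [reindex_op()] (or matrix acceptable to it).
#' @return The reindexed [refl_set()].
#' @export
apply_reindex <- function(set, op) {
  stopifnot(inherits(set, "refl_set"))
  op <- reindex_op(op)
  refl <- set$reflections
  if (nrow(refl)) {
    hkl <- as_hkl_matrix(refl) %*% unclass(op)
    refl$h <- as.integer(hkl[, 1])
    refl$k <- as.integer(hkl[, 2])
    refl$l <- as.integer(hkl[, 3])
  }
  # new index i reads along old axis j where M[j, i] != 0
  perm <- apply(abs(unclass(op)) > 0, 2, which.max)
  cell <- unclass(set$cell)
  new_cell <- unit_cell(cell[perm[1]], cell[perm[2]], cell[perm[3]],
                        cell[3 + perm[1]], cell[3 + perm[2]],
                        cell[3 + perm[3]])
  refl_set(set$dataset_id, new_cell, set$laue, set$centering, refl,
           merged = FALSE) |>
    (\(s) if (set$merged) merge_within(s) else s)()
}
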