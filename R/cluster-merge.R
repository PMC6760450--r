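#' Correlation of common reflection intensities between two datasets
#'
#' The Pearson correlation coefficient CC_I of the intensities of
#' reflections common to two datasets (after asymmetric-unit reduction) is
#' the stage-2 similarity: two crystals of the same phase share a true
#' intensity table and correlate strongly regardless of their individual
#' scale factors, while crystals of different phases (or mis-indexed
#' crystals) do not.
#'
#' @param set_a,set_b Merged [refl_set()]s in the same Laue group, filters
#'   already applied.
#' @param min_common Minimum number of common unique reflections for the
#'   correlation to be considered defined; below it `cc` is `NA`.
#' @return One-row tibble `id_i, id_j, n_common, cc`.
#' @export
cc_common <- function(set_a, set_b, min_common = 10) {
  stopifnot(inherits(set_a, "refl_set"), inherits(set_b, "refl_set"))
  if (set_a$laue$symbol != set_b$laue$symbol) {
    stop("Laue groups differ: ", set_a$laue$symbol, " vs ",
         set_b$laue$symbol, call. = FALSE)
  }
  if (!set_a$merged || !set_b$merged) {
    stop("cc_common needs merged sets; call merge_within() first",
         call. = FALSE)
  }
  ua <- asu_uid(set_a$laue, set_a$reflections)
  ub <- asu_uid(set_b$laue, set_b$reflections)
  common <- intersect(ua, ub)
  cc <- NA_real_
  if (length(common) >= max(min_common, 3)) {
    ia <- set_a$reflections$I[match(common, ua)]
    ib <- set_b$reflections$I[match(common, ub)]
    if (stats::sd(ia) > 0 && stats::sd(ib) > 0) {
      cc <- stats::cor(ia, ib)
    }
  }
  tibble::tibble(id_i = set_a$dataset_id, id_j = set_b$dataset_id,
                 n_common = length(common), cc = cc)
}

#' Correlation-based clustering distance
#'
#' The distance used for reflection-based hierarchical clustering is
#' \eqn{d = \sqrt{1 - CC^2}} for CC >= 0; negative or undefined
#' correlations map to the maximal distance 1 (anticorrelated intensity
#' sets must never cluster). The transform is strictly decreasing on CC in
#' \[0, 1\], with d(1) = 0 and d(0) = 1. `distance_to_cc()` inverts it on
#' that branch, which is how a cut distance reads as a CC threshold (e.g.
#' a cut of 0.40 corresponds to CC = 0.92).
#'
#' @param cc Correlation coefficient(s) in \[-1, 1\], `NA` allowed.
#' @return Distance(s) in \[0, 1\].
#' @examples
#' cc_to_distance(0.98)       # ~0.199
#' distance_to_cc(0.40)       # ~0.9165, prints as 0.92
#' @export
cc_to_distance <- function(cc) {
  bad <- !is.na(cc) & (cc < -1 | cc > 1)
  if (any(bad)) stop("cc outside [-1, 1]", call. = FALSE)
  d <- ifelse(is.na(cc) | cc < 0, 1, sqrt(pmax(0, 1 - cc^2)))
  as.numeric(d)
}

#' @rdname cc_to_distance
#' @param d Distance(s) in \[0, 1\].
#' @export
distance_to_cc <- function(d) {
  if (any(d < 0 | d > 1)) stop("distance outside [0, 1]", call. = FALSE)
  sqrt(pmax(0, 1 - d^2))
}

#' Stage-2 clustering of datasets on reflection correlations
#'
#' Builds the pairwise CC_I matrix over all merged sets, transforms it with
#' [cc_to_distance()], runs average-linkage clustering and cuts the tree.
#' Pairs with fewer than `min_common` common uniques are maximally distant.
#'
#' @param sets List of merged [refl_set()]s (>= 2), same Laue group.
#' @param cut Cut distance (default 0.4, i.e. CC = 0.92).
#' @param min_common Passed to [cc_common()].
#' @return Object of class `refl_clustering`: list with `tree`,
#'   `assignment`, `cut`, `pairs` (tibble of all pairwise correlations) and
#'   `ids`.
#' @export
cluster_reflections <- function(sets, cut = 0.4, min_common = 10) {
  stopifnot(length(sets) >= 2)
  ids <- vapply(sets, function(s) s$dataset_id, character(1))
  stopifnot(!anyDuplicated(ids))
  n <- length(sets)
  uids <- lapply(sets, function(s) asu_uid(s$laue, s$reflections))
  dmat <- matrix(0, n, n, dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pc <- cc_common(sets[[i]], sets[[j]], min_common = min_common)
      pairs[[length(pairs) + 1]] <- pc
      dmat[i, j] <- dmat[j, i] <- cc_to_distance(pc$cc)
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  if (all(is.na(pairs$cc))) {
    stop("all pairwise correlations undefined (too few common reflections)",
         call. = FALSE)
  }
  tree <- average_linkage(stats::as.dist(dmat))
  tree$labels <- ids
  assignment <- cut_dendrogram(tree, cut)
  structure(list(tree = tree, assignment = assignment, cut = cut,
                 pairs = pairs, ids = ids),
            class = "refl_clustering")
}

#' @export
print.refl_clustering <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  cat(sprintf("<refl_clustering> %d datasets, cut %.3g (CC >= %.3g) -> %d cluster(s): %s\n",
              length(x$ids), x$cut, distance_to_cc(min(x$cut, 1)),
              length(sizes),
              paste(sprintf("#%s(n=%d)", names(sizes), as.integer(sizes)),
                    collapse = " ")))
  invisible(x)
}

#' @rdname cluster_reflections
#' @param x A `refl_clustering`.
#' @param ... Unused.
#' @method tidy refl_clustering
#' @export
tidy.refl_clustering <- function(x, ...) x$assignment

#' Least-squares scale factors for the datasets of one cluster
#'
#' Each dataset j receives a multiplicative factor k_j aligning it with a
#' running merged reference, via the closed form
#' \eqn{k_j = \sum I_{ref} I_j / \sum I_j^2} over the reflections the
#' dataset shares with the reference; the reference intensities are the
#' per-unique means of the scaled datasets, iterated until the largest
#' relative change is below `tol` (at most `max_iter` sweeps). The dataset
#' with the most unique reflections is fixed at k = 1.
#'
#' @param sets List of merged [refl_set()]s (>= 2) whose common-reflection
#'   graph is connected.
#' @param tol Relative-change convergence threshold.
#' @param max_iter Maximum number of sweeps.
#' @return Tibble `dataset_id, scale, n_unique` in input order.
#' @export
scale_sets <- function(sets, tol = 1e-6, max_iter = 20) {
  stopifnot(length(sets) >= 2)
  ids <- vapply(sets, function(s) s$dataset_id, character(1))
  uids <- lapply(sets, function(s) asu_uid(s$laue, s$reflections))
  check_connected(uids, ids)
  all_uid <- unique(unlist(uids))
  imat <- matrix(NA_real_, length(all_uid), length(sets))
  for (j in seq_along(sets)) {
    imat[match(uids[[j]], all_uid), j] <- sets[[j]]$reflections$I
  }
  n_unique <- colSums(!is.na(imat))
  ref_j <- which.max(n_unique)
  k <- rep(1, length(sets))
  for (iter in seq_len(max_iter)) {
    scaled <- sweep(imat, 2, k, "*")
    iref <- rowMeans(scaled, na.rm = TRUE)
    k_new <- vapply(seq_along(sets), function(j) {
      obs <- !is.na(imat[, j])
      sum(iref[obs] * imat[obs, j]) / sum(imat[obs, j]^2)
    }, numeric(1))
    k_new <- k_new / k_new[ref_j]
    delta <- max(abs(k_new - k) / pmax(abs(k), 1e-12))
    k <- k_new
    if (delta < tol) break
  }
  tibble::tibble(dataset_id = ids, scale = k, n_unique = n_unique)
}

check_connected <- function(uids, ids) {
  n <- length(uids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(uids[[i]], uids[[j]]))) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comps <- vapply(seq_len(n), find, integer(1))
  if (length(unique(comps)) > 1) {
    grp <- split(ids, comps)
    stop("common-reflection graph is disconnected; components: ",
         paste(vapply(grp, paste, character(1), collapse = "+"),
               collapse = " | "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Merge the scaled datasets of a cluster into one multi-crystal set
#'
#' All scaled measurements (each dataset's merged unique value counts as
#' one measurement) are pooled per canonical index: merged I is the mean of
#' scaled intensities, merged sigma is \eqn{\sqrt{\sum \sigma_i^2}/n}, and
#' the per-unique measurement list is retained (attribute
#' `"measurements"`) for the quality statistics. Datasets must share the
#' cell within `cell_tol` per axis — serial data show real cell variation
#' from sample-height differences, hence the generous default of 5%.
#'
#' @param sets List of merged [refl_set()]s.
#' @param scales Tibble from [scale_sets()] (or `NULL` for all 1).
#' @param cell_tol Relative per-axis tolerance for cell agreement.
#' @return A merged multi-crystal [refl_set()] with attribute
#'   `"measurements"` (tibble `uid, h, k, l, I, sigma, dataset_id`).
#' @export
merge_cluster <- function(sets, scales = NULL, cell_tol = 0.05) {
  stopifnot(length(sets) >= 1)
  ids <- vapply(sets, function(s) s$dataset_id, character(1))
  if (is.null(scales)) {
    scales <- tibble::tibble(dataset_id = ids, scale = rep(1, length(sets)))
  }
  ref_cell <- unclass(sets[[1]]$cell)[1:3]
  for (s in sets) {
    dev <- abs(unclass(s$cell)[1:3] - ref_cell) / ref_cell
    if (any(dev > cell_tol)) {
      stop(sprintf("cell of %s deviates %.1f%% from %s (tolerance %.0f%%)",
                   s$dataset_id, 100 * max(dev), sets[[1]]$dataset_id,
                   100 * cell_tol), call. = FALSE)
    }
  }
  meas <- purrr::map_dfr(sets, function(s) {
    kfac <- scales$scale[match(s$dataset_id, scales$dataset_id)]
    refl <- s$reflections
    canon <- asu_map(s$laue, refl)
    tibble::tibble(h = canon[, 1], k = canon[, 2], l = canon[, 3],
                   I = refl$I * kfac, sigma = refl$sigma * kfac,
                   n_obs = refl$n_obs, dataset_id = s$dataset_id)
  })
  meas$uid <- paste(meas$h, meas$k, meas$l)
  merged <- meas |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(I = mean(.data$I),
                     sigma = sqrt(sum(.data$sigma^2)) / dplyr::n(),
                     n_obs = sum(.data$n_obs), .groups = "drop")
  out <- refl_set(paste(ids, collapse = "+"), sets[[1]]$cell,
                  sets[[1]]$laue, sets[[1]]$centering, merged, merged = TRUE)
  attr(out, "measurements") <- meas
  attr(out, "member_ids") <- ids
  out
}

#' Quality statistics of a merged multi-crystal dataset
#'
#' Standard merging statistics at a resolution limit `d_min`:
#' completeness (% of the symmetry-unique reflections enumerable to
#' `d_min` that were observed), the multiplicity-weighted merging R factor
#' \eqn{R_{meas} = \sum_h \sqrt{n_h/(n_h-1)} \sum_i |I_{hi} - \bar I_h| /
#' \sum_h \sum_i I_{hi}} over uniques measured at least twice (signed
#' intensities in the denominator, as negative merged intensities are
#' legitimate in electron diffraction data), the half-set correlation
#' CC_1/2 from one seeded random split of the measurements, the mean
#' merged I/sigma, and the mean multiplicity.
#'
#' @param merged A multi-crystal set from [merge_cluster()] (must carry the
#'   `"measurements"` attribute).
#' @param d_min Resolution limit in Angstrom for the statistics.
#' @param seed Integer seed for the half-set split (recorded in the
#'   output, so reports are reproducible).
#' @return One-row tibble of class `merge_stats`: `d_min, n_unique,
#'   n_possible, completeness, r_meas, cc_half, mean_i_over_sigma,
#'   mean_multiplicity, n_datasets, seed`. `r_meas`/`cc_half` are `NA` when
#'   no unique was measured twice.
#' @export
compute_stats <- function(merged, d_min, seed = 1L) {
  stopifnot(inherits(merged, "refl_set"), merged$merged)
  meas <- attr(merged, "measurements")
  if (is.null(meas)) {
    stop("set lacks per-unique measurement lists; use merge_cluster()",
         call. = FALSE)
  }
  refl <- merged$reflections
  d <- d_spacing(merged$cell, refl)
  refl <- refl[d >= d_min, , drop = FALSE]
  meas <- meas[d_spacing(merged$cell, meas[, c("h", "k", "l")]) >= d_min, ,
               drop = FALSE]
  possible <- enumerate_unique(merged$cell, merged$laue, merged$centering,
                               d_min = d_min)
  n_unique <- nrow(refl)
  completeness <- 100 * n_unique / nrow(possible)

  split_meas <- split(seq_len(nrow(meas)), meas$uid)
  multi <- split_meas[lengths(split_meas) >= 2]
  r_meas <- NA_real_
  cc_half <- NA_real_
  if (length(multi)) {
    num <- 0; den <- 0
    half1 <- numeric(length(multi)); half2 <- numeric(length(multi))
    with_local_seed(as.integer(seed) + 911L, {
      for (t in seq_along(multi)) {
        ii <- multi[[t]]
        iv <- meas$I[ii]
        nh <- length(iv)
        num <- num + sqrt(nh / (nh - 1)) * sum(abs(iv - mean(iv)))
        den <- den + sum(iv)
        pick <- sample.int(nh)          # random halves; odd n: extra in half 2
        sel <- seq_len(nh) %in% pick[seq_len(floor(nh / 2))]
        half1[t] <- mean(iv[sel]); half2[t] <- mean(iv[!sel])
      }
    })
    r_meas <- num / den
    if (length(multi) >= 3 && stats::sd(half1) > 0 && stats::sd(half2) > 0) {
      cc_half <- stats::cor(half1, half2)
    } else if (isTRUE(all.equal(half1, half2))) {
      cc_half <- 1
    }
  }
  out <- tibble::tibble(
    d_min = d_min, n_unique = n_unique, n_possible = nrow(possible),
    completeness = completeness, r_meas = r_meas, cc_half = cc_half,
    mean_i_over_sigma = if (n_unique) mean(refl$I / refl$sigma) else NA_real_,
    mean_multiplicity = if (n_unique) mean(refl$n_obs) else NA_real_,
    n_datasets = length(attr(merged, "member_ids") %||% 1),
    seed = as.integer(seed))
  class(out) <- c("merge_stats", class(out))
  out
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream (the global .Random.seed is saved and restored).
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Glance at merge statistics
#' @param x A `merge_stats` row.
#' @param ... Unused.
#' @return The underlying one-row tibble.
#' @method glance merge_stats
#' @export
glance.merge_stats <- function(x, ...) tibble::as_tibble(unclass(x))

#' Rank merged clusters by data quality
#'
#' Clusters are ordered by completeness (descending), then CC_1/2
#' (descending), then R_meas (ascending) — the order in which one would
#' pick a cluster for structure determination: coverage first, internal
#' consistency as tie-breaker.
#'
#' @param stats_table Tibble with one row per cluster: a `cluster` id
#'   column plus [compute_stats()] columns.
#' @return The table sorted by the ranking rule, with a `rank` column.
#' @export
rank_clusters <- function(stats_table) {
  stopifnot(nrow(stats_table) >= 1)
  out <- stats_table |>
    dplyr::arrange(dplyr::desc(.data$completeness),
                   dplyr::desc(dplyr::coalesce(.data$cc_half, -Inf)),
                   dplyr::coalesce(.data$r_meas, Inf))
  out$rank <- seq_len(nrow(out))
  out
}
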