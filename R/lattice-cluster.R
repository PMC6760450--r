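#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Thin, validated wrapper around [stats::hclust()] with the `"average"`
#' method: the distance between two clusters is the arithmetic mean of all
#' cross-pair distances, which makes merge heights monotone non-decreasing.
#'
#' @param d A [stats::dist()] object or a symmetric, zero-diagonal,
#'   nonnegative distance matrix (n >= 2 items).
#' @return An `hclust` tree.
#' @export
average_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    stopifnot(nrow(m) == ncol(m))
    if (any(!is.finite(m))) stop("distance matrix contains NaN/NA", call. = FALSE)
    if (any(m < 0)) stop("distances must be nonnegative", call. = FALSE)
    if (max(abs(m - t(m))) > 1e-8 || any(diag(m) != 0)) {
      stop("distance matrix must be symmetric with zero diagonal",
           call. = FALSE)
    }
    d <- stats::as.dist(m)
  } else if (any(!is.finite(d))) {
    stop("distance matrix contains NaN/NA", call. = FALSE)
  }
  if (attr(d, "Size") < 2) stop("need at least 2 items", call. = FALSE)
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into clusters
#'
#' Clusters are the connected components formed by merges at height
#' *strictly below* the cut, so `cut = 0` yields all singletons. Labels are
#' 1-based and ordered by decreasing cluster size, ties broken by the
#' smallest member index, which keeps reports deterministic.
#'
#' @param tree An `hclust` tree (e.g. from [average_linkage()]).
#' @param cut Nonnegative cut height.
#' @return Tibble with columns `id` (item label, or index as character when
#'   the tree is unlabelled), `item` (1-based item index) and `cluster`.
#' @export
cut_dendrogram <- function(tree, cut) {
  stopifnot(inherits(tree, "hclust"), cut >= 0)
  n <- length(tree$order)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cluster_of_node <- integer(nrow(tree$merge))  # representative leaf per merge
  for (m in seq_len(nrow(tree$merge))) {
    if (tree$height[m] >= cut) {
      cluster_of_node[m] <- leaf_of(tree, m)
      next
    }
    a <- tree$merge[m, 1]; b <- tree$merge[m, 2]
    ra <- find(if (a < 0) -a else cluster_of_node[a])
    rb <- find(if (b < 0) -b else cluster_of_node[b])
    parent[rb] <- ra
    cluster_of_node[m] <- ra
  }
  comp <- vapply(seq_len(n), find, integer(1))
  label_clusters(comp, labels = tree$labels)
}

# any leaf under merge node m (used as representative for uncut nodes)
leaf_of <- function(tree, m) {
  a <- tree$merge[m, 1]
  while (a > 0) a <- tree$merge[a, 1]
  -a
}

# order component ids: decreasing size, ties by smallest member index
label_clusters <- function(comp, labels = NULL) {
  n <- length(comp)
  reps <- unique(comp)
  sizes <- vapply(reps, function(r) sum(comp == r), numeric(1))
  firsts <- vapply(reps, function(r) min(which(comp == r)), numeric(1))
  lab <- stats::setNames(seq_along(reps), reps[order(-sizes, firsts)])
  tibble::tibble(
    id = if (is.null(labels)) as.character(seq_len(n)) else labels,
    item = seq_len(n),
    cluster = unname(lab[as.character(comp)]))
}

#' Stage-1 clustering of datasets by unit cell
#'
#' Builds the pairwise distance matrix between dataset unit cells using
#' either the Euclidean distance over the six lattice parameters
#' (`metric = "params"`, mixed Angstrom/degree units) or the absolute
#' volume difference (`metric = "volume"`), runs average-linkage
#' clustering, and cuts the tree. No lattice-symmetry idealization is
#' applied before clustering: angles near 90 degrees enter as refined.
#'
#' @param cells Cell table (tibble from [read_cells_table()] /
#'   [parse_correct_lp()]).
#' @param metric `"params"` or `"volume"`.
#' @param cut Cut height; default `NULL` cuts at the largest gap between
#'   consecutive merge heights (a robust automatic choice when phases are
#'   well separated).
#' @param normalize Passed to [cell_distance_params()]; when `TRUE` each
#'   parameter is z-scored by its standard deviation across datasets.
#' @return Object of class `cell_clustering`: list with `tree` (hclust),
#'   `assignment` (tibble `id, item, cluster`), `cut`, `metric` and
#'   `cells` (the input table with the cluster column joined).
#' @export
cluster_cells <- function(cells, metric = c("params", "volume"),
                          cut = NULL, normalize = FALSE) {
  metric <- match.arg(metric)
  cells <- validate_cells_table(cells, context = "cluster_cells")
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 datasets to cluster", call. = FALSE)
  if (metric == "params") {
    p <- as.matrix(cells[, c("a", "b", "c", "alpha", "beta", "gamma")])
    if (normalize) {
      s <- apply(p, 2, stats::sd)
      s[s == 0] <- 1
      p <- sweep(p, 2, s, "/")
    }
    d <- stats::dist(p, method = "euclidean")
  } else {
    v <- vapply(seq_len(n), function(i) cell_volume(as_unit_cell(cells[i, ])),
                numeric(1))
    d <- stats::dist(matrix(v, ncol = 1), method = "manhattan")
  }
  tree <- average_linkage(d)
  tree$labels <- cells$dataset_id
  if (is.null(cut)) cut <- gap_cut(tree)
  assignment <- cut_dendrogram(tree, cut)
  cells$cluster <- assignment$cluster[match(cells$dataset_id, assignment$id)]
  structure(list(tree = tree, assignment = assignment, cut = cut,
                 metric = metric, cells = cells),
            class = "cell_clustering")
}

# cut at the midpoint of the largest gap between consecutive merge heights
# (the root-side boundary of the gap when there is a single merge)
gap_cut <- function(tree) {
  h <- sort(tree$height)
  if (length(h) == 1) return(h + .Machine$double.eps)
  gaps <- diff(h)
  i <- which.max(gaps)
  (h[i] + h[i + 1]) / 2
}

#' @export
print.cell_clustering <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  cat(sprintf("<cell_clustering> %d datasets, metric '%s', cut %.4g -> %d cluster(s): %s\n",
              nrow(x$assignment), x$metric, x$cut, length(sizes),
              paste(sprintf("#%s(n=%d)", names(sizes), as.integer(sizes)),
                    collapse = " ")))
  invisible(x)
}

#' @rdname cluster_cells
#' @param x A `cell_clustering`.
#' @param ... Unused.
#' @method tidy cell_clustering
#' @export
tidy.cell_clustering <- function(x, ...) x$cells

#' Fit per-parameter normal distributions to lattice-parameter histograms
#'
#' For each of the six lattice parameters, values inside a user-chosen
#' window are summarized by the Gaussian maximum-likelihood estimates
#' (sample mean, population standard deviation). This is how the average
#' unit cell of a cluster of datasets is obtained; histogram bin counts are
#' reported for plotting only and do not influence the fit.
#'
#' @param cells Cell table.
#' @param windows Named list of `c(lo, hi)` windows per parameter
#'   (`a, b, c, alpha, beta, gamma`); parameters not named get the full
#'   data range. Values outside the window (e.g. outlier cells) are
#'   excluded from the fit.
#' @param n_bins Number of equal-width display bins inside the window.
#' @return Tibble of class `cell_histogram_fit`: one row per parameter with
#'   `parameter, lo, hi, mean, sigma, n_in_window, n_total` and a `breaks` /
#'   `counts` list column for plotting.
#' @export
fit_cell_histograms <- function(cells, windows = list(), n_bins = 50) {
  cells <- validate_cells_table(cells, context = "fit_cell_histograms")
  params <- c("a", "b", "c", "alpha", "beta", "gamma")
  rows <- lapply(params, function(p) {
    v <- cells[[p]]
    w <- windows[[p]] %||% range(v)
    if (is.null(windows[[p]]) && w[1] == w[2]) {
      w <- w + c(-0.5, 0.5)   # degenerate spread: all values identical
    }
    if (w[1] >= w[2]) stop("window for '", p, "' has lo >= hi", call. = FALSE)
    inside <- v[v >= w[1] & v <= w[2]]
    if (length(inside) < 2) {
      stop("fewer than 2 values inside the window for parameter '", p, "'",
           call. = FALSE)
    }
    breaks <- seq(w[1], w[2], length.out = n_bins + 1)
    counts <- graphics::hist(inside, breaks = breaks, plot = FALSE)$counts
    tibble::tibble(parameter = p, lo = w[1], hi = w[2],
                   mean = mean(inside),
                   sigma = stats::sd(inside) * sqrt((length(inside) - 1) /
                                                      length(inside)),
                   n_in_window = length(inside), n_total = length(v),
                   breaks = list(breaks), counts = list(counts))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cell_histogram_fit", class(out))
  out
}

#' Average cell from histogram fits
#' @param fits Result of [fit_cell_histograms()].
#' @return A [unit_cell()] built from the six fitted means.
#' @export
average_cell <- function(fits) {
  m <- stats::setNames(fits$mean, fits$parameter)
  unit_cell(m[["a"]], m[["b"]], m[["c"]],
            m[["alpha"]], m[["beta"]], m[["gamma"]])
}

#' Vote the most likely lattice type
#'
#' Datasets are grouped by Bravais lattice symbol and the number of indexed
#' reflections is summed per group; the symbol with the highest total is
#' the most likely lattice type (a poorly fitting lattice indexes fewer
#' reflections). Ties are broken alphabetically by symbol.
#'
#' @param cells Cell table with `lattice_type` and `n_indexed`.
#' @return Tibble `lattice_type, n_indexed` sorted by descending score.
#' @export
vote_lattice_type <- function(cells) {
  cells <- validate_cells_table(cells, context = "vote_lattice_type")
  cells <- cells[cells$lattice_type != "", , drop = FALSE]
  if (!nrow(cells)) {
    stop("no dataset carries a lattice type; cannot vote", call. = FALSE)
  }
  cells |>
    dplyr::group_by(.data$lattice_type) |>
    dplyr::summarise(n_indexed = sum(.data$n_indexed), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_indexed), .data$lattice_type)
}
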