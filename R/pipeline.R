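#' Pipeline configuration
#'
#' Bundles every tunable of the two-stage workflow. Defaults follow common
#' multi-crystal electron-diffraction practice: reflections are restricted
#' to d >= 1.2 Angstrom and I/sigma >= 2 before correlations are computed,
#' the reflection-clustering cut distance is 0.4 (CC = 0.92), and a pair
#' needs at least 10 common unique reflections for a defined correlation.
#'
#' @param input_dir Directory with input files (cells CSV and/or HKL data).
#' @param output_dir Directory for all artifacts.
#' @param metric Stage-1 metric: `"params"` or `"volume"`.
#' @param cell_cut Stage-1 cut height (`NULL` = largest-gap heuristic).
#' @param windows Per-parameter histogram windows (see
#'   [fit_cell_histograms()]).
#' @param laue,centering Symmetry for stage 2.
#' @param d_min,d_max,min_i_over_sigma Reflection filters for stage 2.
#' @param cc_cut Stage-2 cut distance.
#' @param min_common Minimum common reflections per defined correlation.
#' @param cell_tol Relative per-axis cell tolerance for phase selection and
#'   merging.
#' @param seed Integer seed (half-set splits etc.).
#' @param write_figures Write dendrogram/histogram figures (PDF).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = ".", output_dir = "edmerge_out",
                            metric = "params", cell_cut = NULL,
                            windows = list(), laue = "mmm", centering = "P",
                            d_min = 1.2, d_max = Inf, min_i_over_sigma = 2,
                            cc_cut = 0.4, min_common = 10, cell_tol = 0.05,
                            seed = 1L, write_figures = FALSE) {
  stopifnot(metric %in% c("params", "volume"), d_min <= d_max,
            cc_cut >= 0, min_common >= 0, cell_tol >= 0)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 metric = metric, cell_cut = cell_cut, windows = windows,
                 laue = laue, centering = centering, d_min = d_min,
                 d_max = d_max, min_i_over_sigma = min_i_over_sigma,
                 cc_cut = cc_cut, min_common = min_common,
                 cell_tol = cell_tol, seed = as.integer(seed),
                 write_figures = write_figures),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys match the arguments above.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Stage 1: lattice-based phase analysis
#'
#' Reads the cell table (`cells.csv` in the input directory, or a supplied
#' tibble), clusters the unit cells, fits per-cluster parameter histograms
#' for the average cell, and votes the lattice type. Artifacts (cluster
#' assignment CSV, average cells, vote table, optional figures) are written
#' under the output directory; one log line per dataset records its fate.
#'
#' @param config A [pipeline_config()].
#' @param cells Optional cell table (otherwise `cells.csv` is read).
#' @return List of class `lattice_stage`: `clustering`
#'   ([cluster_cells()] result), `fits` (named list of histogram-fit
#'   tables, one per cluster with >= 2 members), `average_cells` (tibble),
#'   `vote`, `log` (tibble `dataset_id, fate`).
#' @export
run_lattice_stage <- function(config, cells = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cells)) {
    path <- file.path(config$input_dir, "cells.csv")
    if (!file.exists(path)) stop("no cells table at ", path, call. = FALSE)
    cells <- read_cells_table(path)
  }
  if (nrow(cells) < 2) {
    stop("need at least 2 indexable datasets", call. = FALSE)
  }
  clustering <- cluster_cells(cells, metric = config$metric,
                              cut = config$cell_cut)
  fits <- list(); avg <- list()
  for (cl in sort(unique(clustering$assignment$cluster))) {
    sub <- clustering$cells[clustering$cells$cluster == cl, , drop = FALSE]
    if (nrow(sub) < 2) next
    f <- fit_cell_histograms(sub, windows = config$windows)
    fits[[as.character(cl)]] <- f
    ac <- average_cell(f)
    avg[[as.character(cl)]] <- tibble::tibble(
      cluster = cl, n = nrow(sub),
      a = ac[["a"]], b = ac[["b"]], c = ac[["c"]],
      alpha = ac[["alpha"]], beta = ac[["beta"]], gamma = ac[["gamma"]],
      a_sd = f$sigma[f$parameter == "a"],
      b_sd = f$sigma[f$parameter == "b"],
      c_sd = f$sigma[f$parameter == "c"])
  }
  vote <- tryCatch(vote_lattice_type(cells), error = function(e) NULL)
  log <- tibble::tibble(
    dataset_id = clustering$assignment$id,
    fate = paste0("clustered:", clustering$assignment$cluster))

  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(clustering$cells, file.path(out_dir, "cell_clusters.csv"),
                   progress = FALSE)
  avg_tab <- dplyr::bind_rows(avg)
  if (nrow(avg_tab)) {
    readr::write_csv(avg_tab, file.path(out_dir, "average_cells.csv"),
                     progress = FALSE)
  }
  if (!is.null(vote)) {
    readr::write_csv(vote, file.path(out_dir, "lattice_vote.csv"),
                     progress = FALSE)
  }
  if (isTRUE(config$write_figures)) {
    save_figure(plot_dendrogram(clustering$tree, cut = clustering$cut),
                file.path(out_dir, "cell_dendrogram.pdf"))
    if (length(fits)) {
      save_figure(plot_cell_histograms(fits[[1]]),
                  file.path(out_dir, "cell_histograms.pdf"))
    }
  }
  structure(list(clustering = clustering, fits = fits,
                 average_cells = avg_tab, vote = vote, log = log,
                 config = config),
            class = "lattice_stage")
}

#' Stage 2: reflection-based clustering, scaling and merging
#'
#' For one selected phase (given by its average cell), datasets whose
#' reported cell deviates from the phase cell by more than the tolerance
#' are excluded (emulating how re-integration with a fixed cell fails for
#' other phases). The survivors are filtered, merged within, clustered on
#' the \eqn{\sqrt{1-CC^2}} distance, and each cluster of two or more
#' datasets is scaled, merged and scored; clusters are then ranked.
#'
#' @param config A [pipeline_config()].
#' @param sets List of unmerged [refl_set()]s.
#' @param phase_cell The selected phase's [unit_cell()] (e.g. an average
#'   cell from stage 1); `NULL` disables the cell gate.
#' @param cells Optional cell table giving the reported cell per dataset
#'   (defaults to each set's own cell).
#' @return List of class `reflection_stage`: `clustering`, `merged` (named
#'   list per cluster label: `merged`, `scales`, `stats`), `ranking`,
#'   `log`, `excluded`.
#' @export
run_reflection_stage <- function(config, sets, phase_cell = NULL,
                                 cells = NULL) {
  stopifnot(inherits(config, "pipeline_config"), length(sets) >= 1)
  ids <- vapply(sets, function(s) s$dataset_id, character(1))
  log <- list()
  excluded <- character()
  if (!is.null(phase_cell)) {
    phase_cell <- as_unit_cell(phase_cell)
    keep <- vapply(seq_along(sets), function(i) {
      rep_cell <- if (!is.null(cells) && ids[i] %in% cells$dataset_id) {
        as_unit_cell(cells[cells$dataset_id == ids[i], ])
      } else {
        sets[[i]]$cell
      }
      dev <- abs(unclass(rep_cell)[1:3] - unclass(phase_cell)[1:3]) /
        unclass(phase_cell)[1:3]
      all(dev <= config$cell_tol)
    }, logical(1))
    excluded <- ids[!keep]
    for (id in excluded) {
      log[[length(log) + 1]] <- tibble::tibble(dataset_id = id,
                                               fate = "excluded:cell_mismatch")
    }
    sets <- sets[keep]
    if (!length(sets)) {
      stop("no dataset matches the selected phase cell", call. = FALSE)
    }
  }
  prepped <- lapply(sets, function(s) {
    s |>
      filter_reflections(d_min = config$d_min, d_max = config$d_max,
                         min_i_over_sigma = config$min_i_over_sigma) |>
      merge_within()
  })
  if (length(prepped) < 2) {
    stop("fewer than 2 datasets survive the phase gate; nothing to cluster",
         call. = FALSE)
  }
  clustering <- cluster_reflections(prepped, cut = config$cc_cut,
                                    min_common = config$min_common)
  merged <- list()
  stats_rows <- list()
  for (cl in sort(unique(clustering$assignment$cluster))) {
    member_ids <- clustering$assignment$id[clustering$assignment$cluster == cl]
    members <- prepped[match(member_ids, vapply(prepped, function(s)
      s$dataset_id, character(1)))]
    if (length(members) < 2) {
      warning("cluster ", cl, " is a singleton; merge skipped")
      log[[length(log) + 1]] <- tibble::tibble(
        dataset_id = member_ids, fate = paste0("singleton:", cl))
      next
    }
    scales <- scale_sets(members)
    mg <- merge_cluster(members, scales, cell_tol = config$cell_tol)
    st <- compute_stats(mg, d_min = config$d_min, seed = config$seed)
    merged[[as.character(cl)]] <- list(merged = mg, scales = scales,
                                       stats = st)
    stats_rows[[length(stats_rows) + 1]] <-
      dplyr::bind_cols(tibble::tibble(cluster = cl), st)
    log[[length(log) + 1]] <- tibble::tibble(
      dataset_id = member_ids, fate = paste0("merged:", cl))
  }
  ranking <- if (length(stats_rows)) {
    rank_clusters(dplyr::bind_rows(stats_rows))
  } else {
    NULL
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cluster_report(clustering$assignment, merged,
                       file.path(out_dir, "clusters"))
  if (!is.null(ranking)) {
    readr::write_csv(ranking, file.path(out_dir, "cluster_ranking.csv"),
                     progress = FALSE)
  }
  structure(list(clustering = clustering, merged = merged,
                 ranking = ranking,
                 log = dplyr::bind_rows(log),
                 excluded = excluded, config = config),
            class = "reflection_stage")
}
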