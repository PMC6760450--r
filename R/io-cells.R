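#' Parse a CORRECT.LP-style integration log
#'
#' Extracts the per-dataset summary used for lattice-based clustering from
#' an XDS CORRECT.LP-style log: the refined unit cell, the space-group
#' number (if present), the count of indexed/accepted reflections, and the
#' rotation range. Parsing is pattern-based on labelled lines (never column
#' offsets) to tolerate version drift; the labels matched are the constants
#' in `correct_lp_labels()`.
#'
#' Failure modes are distinguished: a log that is recognizably an
#' integration log but lacks a unit-cell line signals *indexing failed*
#' (condition class `edmerge_indexing_failed`), while text with none of the
#' known labels signals a *malformed file* (`edmerge_parse_error`).
#'
#' @param text Character scalar or vector of lines (the log content).
#' @param dataset_id Identifier recorded in the returned row.
#' @param source_path Provenance string recorded in the returned row.
#' @return One-row tibble with columns `dataset_id, a, b, c, alpha, beta,
#'   gamma, lattice_type, n_indexed, rotation_range, source_path` (a cell
#'   table row).
#' @export
parse_correct_lp <- function(text, dataset_id = "dataset",
                             source_path = NA_character_) {
  lines <- if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  labels <- correct_lp_labels()
  recognized <- any(vapply(labels, function(p) any(grepl(p, lines, fixed = TRUE)),
                           logical(1))) ||
    any(grepl("XDS|CORRECT|IDXREF", lines))
  if (!recognized) {
    stop(rlang::error_cnd(class = "edmerge_parse_error",
                          message = "not a recognizable integration log"))
  }
  cell_line <- grep(labels[["cell"]], lines, fixed = TRUE, value = TRUE)
  if (!length(cell_line)) {
    stop(rlang::error_cnd(class = "edmerge_indexing_failed",
                          message = "no unit-cell line: indexing failed"))
  }
  cell_vals <- extract_numbers(sub(".*UNIT_CELL_CONSTANTS=", "",
                                   cell_line[length(cell_line)]))
  if (length(cell_vals) < 6) {
    stop(rlang::error_cnd(class = "edmerge_parse_error",
                          message = "unit-cell line holds fewer than 6 numbers"))
  }
  cell <- as_unit_cell(cell_vals[1:6])

  sg <- NA_integer_
  sg_line <- grep(labels[["space_group"]], lines, fixed = TRUE, value = TRUE)
  if (length(sg_line)) {
    sg <- as.integer(extract_numbers(sg_line[length(sg_line)])[1])
  }
  lattice <- ""
  lat_line <- grep(labels[["lattice"]], lines, fixed = TRUE, value = TRUE)
  if (length(lat_line)) {
    lattice <- trimws(sub(paste0(".*", labels[["lattice"]]), "",
                          lat_line[length(lat_line)]))
  } else if (!is.na(sg)) {
    lattice <- bravais_from_sg(sg)
  }

  n_indexed <- 0L
  idx_line <- grep(labels[["n_indexed"]], lines, fixed = TRUE, value = TRUE)
  if (length(idx_line)) {
    n_indexed <- as.integer(extract_numbers(idx_line[length(idx_line)])[1])
  }

  rot <- 0
  dr <- grep(labels[["data_range"]], lines, fixed = TRUE, value = TRUE)
  osc <- grep(labels[["oscillation"]], lines, fixed = TRUE, value = TRUE)
  if (length(dr) && length(osc)) {
    rng <- extract_numbers(dr[1])
    step <- extract_numbers(osc[1])[1]
    rot <- (rng[2] - rng[1] + 1) * step
  }

  tibble::tibble(dataset_id = dataset_id,
                 a = cell[["a"]], b = cell[["b"]], c = cell[["c"]],
                 alpha = cell[["alpha"]], beta = cell[["beta"]],
                 gamma = cell[["gamma"]],
                 lattice_type = lattice, n_indexed = n_indexed,
                 rotation_range = rot, source_path = source_path)
}

#' @rdname parse_correct_lp
#' @export
correct_lp_labels <- function() {
  c(cell = "UNIT_CELL_CONSTANTS=",
    space_group = "SPACE_GROUP_NUMBER=",
    lattice = "LATTICE_TYPE=",
    n_indexed = "NUMBER OF ACCEPTED OBSERVATIONS",
    data_range = "DATA_RANGE=",
    oscillation = "OSCILLATION_RANGE=")
}

extract_numbers <- function(x) {
  m <- gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?", x)
  as.numeric(regmatches(x, m)[[1]])
}

# Bravais symbol (crystal-family letter + centering) from space-group number.
bravais_from_sg <- function(sg) {
  if (is.na(sg) || sg < 1 || sg > 230) return("")
  family <- if (sg <= 2) "a" else if (sg <= 15) "m" else if (sg <= 74) "o"
    else if (sg <= 142) "t" else if (sg <= 167) "h" else if (sg <= 194) "h"
    else "c"
  # centering cannot be recovered from the number alone without a symbol
  # table; primitive is reported and callers may override.
  paste0(family, "P")
}

#' Read and write cell tables
#'
#' The canonical internal format for per-dataset unit-cell summaries is a
#' CSV with header `dataset_id,a,b,c,alpha,beta,gamma,lattice_type,
#' n_indexed,rotation_range` (an optional `source_path` column is kept when
#' present). The round trip is lossless at 6 decimals and preserves row
#' order.
#'
#' @param path CSV file path.
#' @return `read_cells_table()`: tibble of validated cell rows.
#' @export
read_cells_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cells_table(tab, context = path)
}

#' @rdname read_cells_table
#' @param rows Data frame of cell rows as produced by [parse_correct_lp()]
#'   or [read_cells_table()].
#' @export
write_cells_table <- function(rows, path) {
  rows <- validate_cells_table(rows, context = "write_cells_table")
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

validate_cells_table <- function(tab, context = "cells table") {
  tab <- tibble::as_tibble(tab)
  required <- c("dataset_id", "a", "b", "c", "alpha", "beta", "gamma",
                "lattice_type", "n_indexed", "rotation_range")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(context, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(tab)) return(tab)
  tab$dataset_id <- as.character(tab$dataset_id)
  tab$lattice_type <- dplyr::coalesce(as.character(tab$lattice_type), "")
  if ("source_path" %in% names(tab)) {
    tab$source_path <- as.character(tab$source_path)
  }
  for (col in c("a", "b", "c", "alpha", "beta", "gamma",
                "n_indexed", "rotation_range")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("%s: malformed numeric field in column '%s', row %d",
                     context, col, bad[1]), call. = FALSE)
      }
      tab[[col]] <- v2
    }
    if (anyNA(tab[[col]])) {
      stop(sprintf("%s: missing value in column '%s', row %d",
                   context, col, which(is.na(tab[[col]]))[1]), call. = FALSE)
    }
  }
  for (col in c("a", "b", "c")) {
    bad <- which(tab[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("%s: non-positive length in column '%s', row %d",
                   context, col, bad[1]), call. = FALSE)
    }
  }
  for (col in c("alpha", "beta", "gamma")) {
    bad <- which(tab[[col]] <= 0 | tab[[col]] >= 180)
    if (length(bad)) {
      stop(sprintf("%s: angle outside (0,180) in column '%s', row %d",
                   context, col, bad[1]), call. = FALSE)
    }
  }
  if (any(tab$n_indexed < 0) || any(tab$rotation_range < 0)) {
    stop(context, ": n_indexed and rotation_range must be nonnegative",
         call. = FALSE)
  }
  tab
}

#' Parse the pairwise correlation block of an XSCALE.LP-style log
#'
#' Looks for the "CORRELATIONS BETWEEN INPUT DATA SETS" table and returns
#' one entry per printed pair: the two dataset indices, the number of
#' common reflections, and the correlation coefficient of their common
#' intensities.
#'
#' @param text Character scalar or vector of lines.
#' @return Tibble with columns `id_i, id_j, n_common, cc`; empty (with a
#'   warning) when the block is absent.
#' @export
parse_xscale_correlations <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  empty <- tibble::tibble(id_i = integer(), id_j = integer(),
                          n_common = integer(), cc = numeric())
  start <- grep("CORRELATIONS BETWEEN INPUT DATA SETS", lines)
  if (!length(start)) {
    warning("no correlation block found in XSCALE log")
    return(empty)
  }
  out <- list()
  pair_re <- "^\\s*(\\d+)\\s+(\\d+)\\s+(\\d+)\\s+([-+]?[0-9]*\\.?[0-9]+)"
  seen_rows <- FALSE
  for (ln in lines[(start[1] + 1):length(lines)]) {
    m <- regmatches(ln, regexec(pair_re, ln))[[1]]
    if (length(m)) {
      seen_rows <- TRUE
      cc <- as.numeric(m[5])
      if (cc < -1 || cc > 1) {
        stop("correlation coefficient outside [-1, 1]: ", cc, call. = FALSE)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        id_i = as.integer(m[2]), id_j = as.integer(m[3]),
        n_common = as.integer(m[4]), cc = cc)
    } else if (seen_rows && trimws(ln) == "") {
      break  # table over
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}
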