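#' Write per-cluster merge results to disk
#'
#' Each cluster gets its own subdirectory `cluster_<label>` (labels follow
#' the deterministic ordering of [cut_dendrogram()]: cluster_1 is the
#' largest, ties by smallest member id) containing the merged reflections
#' in SHELX HKL4 format (`merged.hkl`), the quality statistics
#' (`stats.json`) and the member list (`members.txt`).
#'
#' @param assignment Tibble `id, cluster` (e.g. from a clustering result).
#' @param merged_results Named list, one entry per cluster label (as
#'   character), each a list with elements `merged` ([merge_cluster()]
#'   output) and `stats` ([compute_stats()] row); clusters without an entry
#'   (e.g. singletons that were not merged) get only a member list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of cluster directories written.
#' @export
write_cluster_report <- function(assignment, merged_results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  dirs <- character()
  for (cl in sort(unique(assignment$cluster))) {
    cdir <- file.path(out_dir, paste0("cluster_", cl))
    dir.create(cdir, showWarnings = FALSE)
    members <- sort(assignment$id[assignment$cluster == cl])
    writeLines(members, file.path(cdir, "members.txt"))
    res <- merged_results[[as.character(cl)]]
    if (!is.null(res)) {
      write_shelx_hkl(res$merged$reflections, file.path(cdir, "merged.hkl"))
      stats_list <- as.list(tibble::as_tibble(unclass(res$stats)))
      stats_list$members <- members
      jsonlite::write_json(stats_list, file.path(cdir, "stats.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    dirs <- c(dirs, cdir)
  }
  invisible(dirs)
}

#' Read a grayscale image file as an intensity matrix
#'
#' Accepts TIFF or PNG; multi-channel images are averaged to grayscale.
#' Values are returned in the file's native scale, as a (row, col) matrix
#' with origin top-left.
#'
#' @param path Image file path (`.tif`, `.tiff` or `.png`).
#' @return Numeric matrix.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is needed to read TIFF files", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the 'png' package is needed to read PNG files", call. = FALSE)
      }
      png::readPNG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}
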