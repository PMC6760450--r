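#' Read and write SHELX HKL4 reflection files
#'
#' HKL4 records are fixed-width: three integer fields of width 4 (h, k, l)
#' followed by two fixed-point fields of width 8 (I, sigma), i.e. Fortran
#' 3I4+2F8.2. The file is terminated by an all-zero h k l record; the writer
#' always emits it and the reader skips it (a missing terminator is
#' tolerated). Intensities round-trip to 2 decimals; indices exactly.
#'
#' @param path File path.
#' @return `read_shelx_hkl()`: tibble with columns `h, k, l, I, sigma` and a
#'   logical `flagged` column marking records whose sigma was non-positive
#'   on input (kept, with a warning).
#' @examples
#' f <- tempfile(fileext = ".hkl")
#' write_shelx_hkl(data.frame(h = 1, k = 2, l = 3, I = 100, sigma = 5), f)
#' read_shelx_hkl(f)
#' @export
read_shelx_hkl <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  out <- tibble::tibble(h = integer(), k = integer(), l = integer(),
                        I = numeric(), sigma = numeric(), flagged = logical())
  if (!length(lines)) return(out)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (nchar(ln) < 28) {
      stop(sprintf("HKL4 record of wrong width at line %d (%d chars, need >= 28)",
                   i, nchar(ln)), call. = FALSE)
    }
    fields <- c(substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
                substr(ln, 13, 20), substr(ln, 21, 28))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("unparseable HKL4 record at line %d: '%s'", i, ln),
           call. = FALSE)
    }
    recs[[i]] <- vals
  }
  m <- do.call(rbind, recs)
  # all-zero hkl terminates the file
  term <- which(m[, 1] == 0 & m[, 2] == 0 & m[, 3] == 0)
  if (length(term)) m <- m[seq_len(min(term) - 1), , drop = FALSE]
  if (!nrow(m)) return(out)
  flagged <- m[, 5] <= 0
  if (any(flagged)) {
    warning(sum(flagged), " reflection(s) with sigma <= 0 kept but flagged")
  }
  tibble::tibble(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                 l = as.integer(m[, 3]), I = m[, 4], sigma = m[, 5],
                 flagged = flagged)
}

#' @rdname read_shelx_hkl
#' @param reflections Data frame with columns `h, k, l, I, sigma`.
#' @return `write_shelx_hkl()`: invisibly, the common rescale factor applied
#'   (1 unless some |I| or sigma would overflow the F8.2 field, in which
#'   case all I and sigma are divided by a common power of 10).
#' @export
write_shelx_hkl <- function(reflections, path) {
  refl <- tibble::as_tibble(reflections)
  stopifnot(all(c("h", "k", "l", "I", "sigma") %in% names(refl)))
  scale <- 1
  if (nrow(refl)) {
    biggest <- max(abs(refl$I), refl$sigma, 0)
    # F8.2 holds at most 99999.99 (sign costs one column)
    while (biggest / scale >= 1e5) scale <- scale * 10
  }
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f",
                   as.integer(refl$h), as.integer(refl$k),
                   as.integer(refl$l), refl$I / scale, refl$sigma / scale)
  lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  writeLines(lines, path)
  if (scale != 1) {
    message("intensities rescaled by 1/", scale, " to fit the F8.2 field")
  }
  invisible(scale)
}
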