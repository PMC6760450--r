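#' Locate the defocused primary beam in a diffraction frame
#'
#' The frame is summed along rows and columns; each marginal profile is
#' thresholded at `bright_frac` of its range above its minimum, and the
#' outermost above-threshold indices define a bounding box around the
#' defocused beam. Half-range is a robust default for a flat-top defocused
#' beam. The beam centre is the box midpoint.
#'
#' Image convention throughout the tracking functions: matrices indexed
#' (row, col), 1-based, origin top-left; bounds are half-open
#' `[lo, hi)`.
#'
#' @param frame Numeric matrix of nonnegative intensities (>= 16 x 16).
#' @param bright_frac Threshold as a fraction of each marginal's range.
#' @return List of class `beam_box`: `row_lo, row_hi, col_lo, col_hi`
#'   (half-open) and `center` (`c(row, col)`, floats).
#' @export
find_beam_box <- function(frame, bright_frac = 0.5) {
  stopifnot(is.matrix(frame), all(dim(frame) >= 16), all(is.finite(frame)))
  box_1d <- function(marg) {
    thr <- min(marg) + bright_frac * (max(marg) - min(marg))
    idx <- which(marg > thr)
    if (!length(idx)) NULL else c(min(idx), max(idx) + 1L)
  }
  rb <- box_1d(rowSums(frame))
  cb <- box_1d(colSums(frame))
  if (max(frame) == min(frame)) {
    if (max(frame) <= 0) {
      stop("no beam found: no marginal bin above threshold", call. = FALSE)
    }
    # uniformly bright frame: the beam fills the field of view
    rb <- c(1L, nrow(frame) + 1L)
    cb <- c(1L, ncol(frame) + 1L)
  } else {
    # a constant marginal (flat profile in one direction) spans fully
    rb <- rb %||% c(1L, nrow(frame) + 1L)
    cb <- cb %||% c(1L, ncol(frame) + 1L)
  }
  structure(list(row_lo = rb[1], row_hi = rb[2], col_lo = cb[1],
                 col_hi = cb[2],
                 center = c((rb[1] + rb[2] - 1) / 2, (cb[1] + cb[2] - 1) / 2)),
            class = "beam_box")
}

#' Crop the beam region out of a frame
#'
#' The bounding box is expanded by `pad_frac` of its size on each side,
#' clamped to the frame, and cut out for faster downstream analysis. The
#' returned object records the crop origin so coordinates round-trip
#' exactly between crop and frame systems.
#'
#' @param frame Numeric matrix.
#' @param box A [find_beam_box()] result.
#' @param pad_frac Fractional padding per side.
#' @return List of class `beam_crop`: `pixels` (matrix), `origin`
#'   (`c(row, col)` of crop pixel (1,1) in frame coordinates) and
#'   `beam_center` in crop coordinates.
#' @export
crop_beam <- function(frame, box, pad_frac = 0.1) {
  stopifnot(inherits(box, "beam_box"))
  pr <- round(pad_frac * (box$row_hi - box$row_lo))
  pc <- round(pad_frac * (box$col_hi - box$col_lo))
  r0 <- max(1L, box$row_lo - pr); r1 <- min(nrow(frame) + 1L, box$row_hi + pr)
  c0 <- max(1L, box$col_lo - pc); c1 <- min(ncol(frame) + 1L, box$col_hi + pc)
  structure(list(pixels = frame[r0:(r1 - 1), c0:(c1 - 1), drop = FALSE],
                 origin = c(r0, c0),
                 beam_center = box$center - c(r0, c0) + 1),
            class = "beam_crop")
}

#' @rdname crop_beam
#' @param xy `c(row, col)` in crop coordinates.
#' @param crop A `beam_crop`.
#' @return `crop_to_frame()`: the coordinates in frame space.
#' @export
crop_to_frame <- function(crop, xy) xy + crop$origin - 1

#' Segment the crystal's contrast band in a beam crop
#'
#' Selects pixels whose intensity lies in the 10-20% band of the crop's
#' intensity range — the third and fourth bins of a 20-bin equal-width
#' histogram over \[min, max\]. Dark pixels outside the defocused probe and
#' bright carbon-film pixels are thereby ignored; what survives is the
#' crystal's shadow and a thin gradient ring at the beam edge, which the
#' blur step suppresses.
#'
#' @param crop A `beam_crop` or plain matrix with intensity range > 0.
#' @param lo_frac,hi_frac Band bounds as fractions of the range
#'   (`[lo, hi)`, defaults 0.10 and 0.20).
#' @return Logical matrix mask.
#' @export
segment_particle <- function(crop, lo_frac = 0.10, hi_frac = 0.20) {
  px <- if (inherits(crop, "beam_crop")) crop$pixels else crop
  rng <- range(px)
  if (diff(rng) == 0) {
    stop("constant crop: cannot segment", call. = FALSE)
  }
  lo <- rng[1] + lo_frac * diff(rng)
  hi <- rng[1] + hi_frac * diff(rng)
  px >= lo & px < hi
}

#' Locate the particle as the blurred-mask maximum
#'
#' A Gaussian filter of width `blur_sigma` is applied to the binary mask
#' and the brightest filtered pixel is taken as the particle centre: a
#' compact blob (the crystal) outlives a thin ring (the beam edge) under
#' blurring, which eliminates the influence of the beam edge. Ties break
#' to the smallest (row, col).
#'
#' @param mask Logical/numeric matrix from [segment_particle()].
#' @param blur_sigma Gaussian sigma in pixels.
#' @return `c(row, col)` of the particle centre (crop coordinates).
#' @export
locate_particle <- function(mask, blur_sigma) {
  m <- mask * 1
  if (!any(m > 0)) stop("no particle: empty mask", call. = FALSE)
  blurred <- EBImage::gblur(m, sigma = blur_sigma)
  top <- which(blurred == max(blurred), arr.ind = TRUE)
  top <- top[order(top[, 1], top[, 2]), , drop = FALSE]
  as.numeric(top[1, ])
}

#' Beam-shift correction from beam and particle centres
#'
#' The shift needed to re-centre the crystal in the probe is the difference
#' vector particle - beam (pixels). An optional user-supplied 2x2
#' calibration matrix maps pixel shifts to deflector units; calibration is
#' hardware-specific and entirely delegated to that matrix.
#'
#' @param beam_center,particle_center `c(row, col)` in one coordinate frame.
#' @param calibration Optional 2x2 matrix (must be nonsingular).
#' @return List of class `particle_fix`: `particle_center`, `shift_px`
#'   (`c(drow, dcol)`), `shift_calibrated` (or `NULL`).
#' @export
compute_shift <- function(beam_center, particle_center, calibration = NULL) {
  shift <- as.numeric(particle_center) - as.numeric(beam_center)
  cal <- NULL
  if (!is.null(calibration)) {
    stopifnot(all(dim(calibration) == c(2, 2)))
    if (abs(det(calibration)) < .Machine$double.eps) {
      stop("singular calibration matrix", call. = FALSE)
    }
    cal <- as.numeric(calibration %*% shift)
  }
  structure(list(particle_center = as.numeric(particle_center),
                 shift_px = shift, shift_calibrated = cal),
            class = "particle_fix")
}

#' Full crystal-tracking chain on one defocused frame
#'
#' Runs [find_beam_box()], [crop_beam()], [segment_particle()],
#' [locate_particle()] and [compute_shift()] in sequence and reports all
#' intermediate centres in frame coordinates.
#'
#' @param frame Numeric matrix.
#' @param bright_frac,pad_frac,lo_frac,hi_frac See the individual steps.
#' @param blur_sigma Gaussian sigma; default `NULL` uses one fifth of the
#'   beam radius estimated from the bounding box.
#' @param denoise_sigma Gaussian sigma of a light pre-smoothing of the
#'   crop before segmentation; suppresses pixel noise that would otherwise
#'   distort the intensity range the 10-20% band is anchored to. Default
#'   `NULL` scales it as beam radius / 20 (at least 1 px), staying well
#'   below the size of any crystal a quarter of the beam across; 0 disables.
#' @param calibration Optional 2x2 pixel-to-deflector matrix.
#' @return List of class `track_result`: `beam_center`, `particle_center`,
#'   `shift_px`, `shift_calibrated`, `box`.
#' @export
track_particle <- function(frame, bright_frac = 0.5, pad_frac = 0.1,
                           lo_frac = 0.10, hi_frac = 0.20,
                           blur_sigma = NULL, denoise_sigma = NULL,
                           calibration = NULL) {
  box <- find_beam_box(frame, bright_frac)
  crop <- crop_beam(frame, box, pad_frac)
  radius <- min(box$row_hi - box$row_lo, box$col_hi - box$col_lo) / 2
  if (is.null(blur_sigma)) blur_sigma <- max(1, radius / 5)
  if (is.null(denoise_sigma)) denoise_sigma <- max(1, radius / 20)
  px <- crop$pixels
  if (denoise_sigma > 0 && min(dim(px)) > 4 * denoise_sigma) {
    px <- EBImage::gblur(px, sigma = denoise_sigma)
  }
  mask <- segment_particle(px, lo_frac, hi_frac)
  pc_crop <- locate_particle(mask, blur_sigma)
  pc <- crop_to_frame(crop, pc_crop)
  fix <- compute_shift(box$center, pc, calibration)
  structure(list(beam_center = box$center, particle_center = pc,
                 shift_px = fix$shift_px,
                 shift_calibrated = fix$shift_calibrated, box = box),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("<track_result> beam (%.1f, %.1f), particle (%.1f, %.1f), shift (%+.1f, %+.1f) px\n",
              x$beam_center[1], x$beam_center[2], x$particle_center[1],
              x$particle_center[2], x$shift_px[1], x$shift_px[2]))
  invisible(x)
}

#' Find crystal candidates in a low-magnification overview image
#'
#' Crystals appear as dark particles on a lighter support film. The image
#' (inverted unless `invert = FALSE`) is thresholded against a local mean
#' computed in a `window_px` box offset by `offset_frac` of that mean, the
#' mask is labelled into connected components, and components of at least
#' `min_area_px` pixels become candidates with their centroids and areas.
#'
#' @param overview Numeric matrix.
#' @param window_px Half-width of the local-mean window in pixels.
#' @param offset_frac Threshold offset as a fraction of the local mean.
#' @param min_area_px Minimum component area in pixels.
#' @param invert Set `FALSE` when crystals are brighter than the support.
#' @return Tibble `candidate, row, col, area` (one row per component;
#'   empty when nothing is found).
#' @export
find_crystals <- function(overview, window_px = 15, offset_frac = 0.05,
                          min_area_px = 20, invert = TRUE) {
  stopifnot(is.matrix(overview))
  img <- if (invert) max(overview) - overview else overview
  rng <- diff(range(img))
  if (rng == 0) {
    return(tibble::tibble(candidate = integer(), row = numeric(),
                          col = numeric(), area = numeric()))
  }
  img <- (img - min(img)) / rng
  local_mean <- EBImage::filter2(img, box_kernel(2 * window_px + 1))
  mask <- img > local_mean * (1 + offset_frac) + 0.05
  labels <- EBImage::bwlabel(mask)
  if (max(labels) == 0) {
    return(tibble::tibble(candidate = integer(), row = numeric(),
                          col = numeric(), area = numeric()))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  out <- tibble::tibble(
    candidate = as.integer(names(table(lab))),
    row = as.numeric(tapply(idx[, 1], lab, mean)),
    col = as.numeric(tapply(idx[, 2], lab, mean)),
    area = as.numeric(table(lab)))
  out <- out[out$area >= min_area_px, , drop = FALSE]
  out$candidate <- seq_len(nrow(out))
  out
}

box_kernel <- function(n) matrix(1 / n^2, n, n)

#' Flag isolated crystals suitable for data collection
#'
#' Two candidates closer than `min_dist` (micrometres, default 1.2) are
#' *both* flagged not isolated — a nearby neighbour would enter the
#' illuminated area or confuse tracking. Candidates within
#' `edge_margin_frac` of the field of view border are flagged `"edge"`
#' (in the acquisition loop such crystals are re-centred by a stage move
#' and re-tested; this library only flags them). The rest are isolated.
#'
#' @param candidates Tibble from [find_crystals()].
#' @param dim_px `c(nrow, ncol)` of the overview frame.
#' @param pixel_size Micrometres per pixel.
#' @param min_dist Minimum allowed centre-to-centre distance in um.
#' @param edge_margin_frac Border margin as a fraction of each dimension.
#' @return The candidate tibble with logical `isolated` and character
#'   `reason` (`""`, `"too_close"` or `"edge"`) columns; flags are
#'   independent of candidate order.
#' @export
select_isolated <- function(candidates, dim_px, pixel_size,
                            min_dist = 1.2, edge_margin_frac = 0.05) {
  cand <- tibble::as_tibble(candidates)
  n <- nrow(cand)
  if (!n) {
    cand$isolated <- logical(); cand$reason <- character()
    return(cand)
  }
  reason <- rep("", n)
  margin <- edge_margin_frac * dim_px
  at_edge <- cand$row < margin[1] | cand$row > dim_px[1] - margin[1] |
    cand$col < margin[2] | cand$col > dim_px[2] - margin[2]
  reason[at_edge] <- "edge"
  if (n > 1) {
    dmat <- as.matrix(stats::dist(cbind(cand$row, cand$col))) * pixel_size
    too_close <- apply(dmat + diag(Inf, n), 1, min) < min_dist
    reason[too_close] <- "too_close"   # takes precedence: unusable as-is
  }
  cand$isolated <- reason == ""
  cand$reason <- reason
  cand
}
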