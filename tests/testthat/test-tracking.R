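make_disc_frame <- function(nr = 200, nc = 280, center = c(100, 140),
                            radius = 40, value = 1) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  value * ((rows - center[1])^2 + (cols - center[2])^2 <= radius^2)
}

test_that("beam box finds a uniform disc to sub-pixel accuracy", {
  f <- make_disc_frame()
  box <- find_beam_box(f, bright_frac = 0.5)
  expect_lt(max(abs(box$center - c(100, 140))), 0.5)

  bright <- matrix(7, 64, 64)
  box2 <- find_beam_box(bright)
  expect_equal(c(box2$row_lo, box2$row_hi, box2$col_lo, box2$col_hi),
               c(1, 65, 1, 65))

  expect_error(find_beam_box(matrix(0, 64, 64)), "no beam")
})

test_that("beam crop clamps to the frame and round-trips coordinates", {
  f <- make_disc_frame()
  box <- find_beam_box(f)
  crop0 <- crop_beam(f, box, pad_frac = 0)
  expect_equal(dim(crop0$pixels),
               c(box$row_hi - box$row_lo, box$col_hi - box$col_lo))

  corner <- make_disc_frame(center = c(5, 5), radius = 20)
  boxc <- find_beam_box(corner)
  cropc <- crop_beam(corner, boxc, pad_frac = 0.2)
  expect_true(all(dim(cropc$pixels) <= dim(corner)))

  crop <- crop_beam(f, box, pad_frac = 0.15)
  pt_frame <- c(97.5, 141.25)
  pt_crop <- pt_frame - crop$origin + 1
  expect_equal(crop_to_frame(crop, pt_crop), pt_frame)
})

test_that("segmentation selects exactly the 10-20% intensity band", {
  crop <- matrix(rep(0:100, length.out = 40 * 40), 40, 40)
  mask <- segment_particle(crop)
  expect_true(all(crop[mask] >= 10 & crop[mask] < 20))
  expect_equal(sum(mask), sum(crop >= 10 & crop < 20))
  expect_error(segment_particle(matrix(5, 20, 20)), "constant")
})

test_that("segmentation keeps the dark-blob band and drops pure bright", {
  f <- simulate_defocused_frame(200, 256, c(100, 128), 40, c(10, -8),
                                noise_sigma = 0, seed = 3)
  box <- find_beam_box(f$frame)
  crop <- crop_beam(f$frame, box)
  mask <- segment_particle(crop)
  expect_gt(sum(mask), 0)
  expect_true(all(crop$pixels[mask] < 0.5 * max(crop$pixels)))
})

test_that("blurred argmax lands in a compact blob, not a thin ring", {
  m <- matrix(FALSE, 120, 120)
  m[55:59, 55:59] <- TRUE                      # 5x5 square
  ctr <- locate_particle(m, blur_sigma = 2)
  expect_lte(max(abs(ctr - c(57, 57))), 1)

  ring <- matrix(FALSE, 120, 120)
  rows <- matrix(seq_len(120), 120, 120)
  cols <- t(rows)
  rr <- sqrt((rows - 60)^2 + (cols - 60)^2)
  ring[rr >= 39 & rr < 40.2] <- TRUE           # ~ same pixel count as blob
  blob <- matrix(FALSE, 120, 120)
  blob[18:26, 18:26] <- TRUE
  both <- ring | blob
  ctr2 <- locate_particle(both, blur_sigma = 6)
  expect_lt(sqrt(sum((ctr2 - c(22, 22))^2)), 3)

  expect_error(locate_particle(matrix(FALSE, 20, 20), 2), "no particle")
})

test_that("shift computation is a plain difference with optional calibration", {
  fix0 <- compute_shift(c(100, 100), c(100, 100))
  expect_equal(fix0$shift_px, c(0, 0))

  fix <- compute_shift(c(100, 100), c(110, 95), calibration = diag(2))
  expect_equal(fix$shift_px, c(10, -5))
  expect_equal(fix$shift_calibrated, c(10, -5))

  expect_error(compute_shift(c(0, 0), c(1, 1),
                             calibration = matrix(1, 2, 2)), "singular")
})

test_that("the full chain recovers planted offsets within 2 px", {
  for (r in c(20, 40, 80)) {
    set.seed(r)
    for (s in 1:20) {
      th <- runif(1, 0, 2 * pi)
      off <- round(runif(1, 0, r / 2) * c(cos(th), sin(th)))
      ns <- runif(1, 0, 0.10)
      f <- simulate_defocused_frame(200, 256, c(100, 128), r, off,
                                    noise_sigma = ns, seed = s)
      tr <- track_particle(f$frame)
      err <- sqrt(sum((tr$particle_center - f$particle_center)^2))
      expect_lt(err, 2, label = sprintf("radius %d seed %d err %.2f", r, s, err))
    }
  }
})

test_that("shift recovery is translation-equivariant", {
  for (t in list(c(0, 0), c(15, -20), c(-10, 30))) {
    f <- simulate_defocused_frame(220, 280, c(110, 140) + t, 40, c(12, -9),
                                  noise_sigma = 0.05, seed = 5)
    tr <- track_particle(f$frame)
    if (all(t == 0)) ref_shift <- tr$shift_px
    expect_equal(tr$shift_px, ref_shift, tolerance = 1e-8)
  }
})

test_that("crystal finding reports planted blobs above the area cutoff", {
  blank <- matrix(0.8, 220, 220)
  expect_equal(nrow(find_crystals(blank)), 0)

  ov <- matrix(0.8, 220, 220)
  plant <- function(img, ctr, r) {
    rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
    cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
    img[(rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2] <- 0.2
    img
  }
  ov <- plant(ov, c(60, 60), 6)
  ov <- plant(ov, c(150, 80), 7)
  ov <- plant(ov, c(100, 180), 5)
  cand <- find_crystals(ov, min_area_px = 20)
  expect_equal(nrow(cand), 3)
  planted <- rbind(c(60, 60), c(150, 80), c(100, 180))
  for (i in seq_len(3)) {
    d <- sqrt((cand$row - planted[i, 1])^2 + (cand$col - planted[i, 2])^2)
    expect_lt(min(d), 1)
  }

  tiny <- plant(matrix(0.8, 220, 220), c(60, 60), 2)   # area ~ 13 px
  expect_equal(nrow(find_crystals(tiny, min_area_px = 20)), 0)
})

test_that("isolation flags follow the pairwise-distance and edge rules", {
  one <- tibble::tibble(candidate = 1L, row = 128, col = 128, area = 40)
  got1 <- select_isolated(one, c(256, 256), pixel_size = 0.05)
  expect_true(got1$isolated)

  # two crystals 1.0 um apart with a 1.2 um threshold: both rejected
  two <- tibble::tibble(candidate = 1:2, row = c(100, 120), col = 100,
                        area = 40)
  got2 <- select_isolated(two, c(256, 256), pixel_size = 0.05)
  expect_equal(got2$isolated, c(FALSE, FALSE))
  expect_equal(got2$reason, c("too_close", "too_close"))

  # three crystals, two close and one far: exactly one passes
  three <- tibble::tibble(candidate = 1:3, row = c(100, 120, 110),
                          col = c(100, 100, 220), area = 40)
  got3 <- select_isolated(three, c(256, 256), pixel_size = 0.05)
  expect_equal(sum(got3$isolated), 1)
  expect_true(got3$isolated[3])

  edge <- tibble::tibble(candidate = 1L, row = 5, col = 128, area = 40)
  gote <- select_isolated(edge, c(256, 256), pixel_size = 0.05)
  expect_equal(gote$reason, "edge")

  # permutation symmetry
  perm <- three[c(3, 1, 2), ]
  gotp <- select_isolated(perm, c(256, 256), pixel_size = 0.05)
  expect_equal(gotp$isolated[match(three$candidate, perm$candidate)],
               got3$isolated)
})
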