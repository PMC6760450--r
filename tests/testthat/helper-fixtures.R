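# In-code fixtures for the file-format tests.

fixture_correct_lp <- function(cell = c(20.07, 19.92, 13.42, 90, 90, 90),
                               sg = 16, n_accepted = 5321,
                               data_range = c(1, 120), osc = 0.23) {
  c(" ***** CORRECT ***** (VERSION Jan 31, 2020)",
    "",
    sprintf(" DATA_RANGE= %7d %7d", data_range[1], data_range[2]),
    sprintf(" OSCILLATION_RANGE=%10.4f DEGREES", osc),
    "",
    " REFINEMENT OF DIFFRACTION PARAMETERS USING ALL IMAGES",
    sprintf(" SPACE_GROUP_NUMBER=%5d", sg),
    sprintf(" UNIT_CELL_CONSTANTS=%9.2f%9.2f%9.2f%8.3f%8.3f%8.3f",
            cell[1], cell[2], cell[3], cell[4], cell[5], cell[6]),
    "",
    sprintf(" NUMBER OF ACCEPTED OBSERVATIONS   %8d", n_accepted),
    " ***** END *****")
}

fixture_correct_lp_failed <- function() {
  c(" ***** CORRECT ***** (VERSION Jan 31, 2020)",
    "",
    " !!! ERROR !!! INSUFFICIENT PERCENTAGE (< 50%) OF INDEXED REFLECTIONS",
    " AUTOMATIC DATA PROCESSING STOPPED.")
}

fixture_xscale_lp <- function(pairs = data.frame(i = c(1, 1, 2),
                                                 j = c(2, 3, 3),
                                                 n = c(120, 85, 96),
                                                 cc = c(0.92, 0.31, 0.45))) {
  c(" ***** XSCALE ***** ",
    "",
    " CORRELATIONS BETWEEN INPUT DATA SETS AFTER CORRECTIONS FOR SYSTEMATIC ERRORS",
    "",
    " DATA SETS  NUMBER OF COMMON  CORRELATION   RATIO OF COMMON   B-FACTOR",
    "  #i   #j     REFLECTIONS     BETWEEN i,j   INTENSITIES (i/j)  BETWEEN i,j",
    "",
    sprintf(" %4d %4d %14d %14.3f %14.4f %12.4f",
            pairs$i, pairs$j, pairs$n, pairs$cc, 1, 0),
    "",
    " ******************************************************************************")
}

random_cells_table <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    dataset_id = sprintf("d%03d", seq_len(n)),
    a = runif(n, 5, 25), b = runif(n, 5, 25), c = runif(n, 5, 25),
    alpha = runif(n, 70, 110), beta = runif(n, 70, 110),
    gamma = runif(n, 70, 110),
    lattice_type = sample(c("oP", "mC", "aP"), n, replace = TRUE),
    n_indexed = sample.int(5000, n), rotation_range = runif(n, 5, 60),
    source_path = NA_character_)
}

# a small merged reflection set on a cubic cell for statistics tests
tiny_refl_set <- function(id = "t1", intensities = c(10, 20, 30, 40),
                          laue = "mmm") {
  hkl <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(2, 1, 0))
  refl_set(id, unit_cell(10, 10, 10), laue, "P",
           tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                          I = intensities,
                          sigma = pmax(0.1, 0.05 * abs(intensities))),
           merged = TRUE)
}
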