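#' Phase specification for the synthetic generator
#'
#' A phase is a crystalline species with a unit cell, a Laue group, a
#' centering, and a ground-truth intensity table produced by a
#' random-point-scatterer model: `n_atoms` scatterers of unit form factor
#' at seeded random fractional positions give
#' \eqn{I(hkl) = |\sum_j \exp(2\pi i\, hkl \cdot x_j)|^2
#' \exp(-B_{iso}/(2 d^2))}. This yields the positively skewed, internally
#' correlated intensity structure real crystals show within one phase, and
#' essentially zero correlation between phases — the signal that
#' reflection-based clustering exploits.
#'
#' @param name Phase name.
#' @param cell A [unit_cell()].
#' @param laue Laue symbol.
#' @param centering Centering letter.
#' @param n_atoms Number of point scatterers (>= 1).
#' @param b_iso Overall isotropic displacement parameter in Angstrom^2
#'   (resolution-dependent intensity decay; 0 disables it).
#' @param seed Integer seed for the scatterer positions.
#' @return List of class `phase_spec`.
#' @export
phase_spec <- function(name, cell, laue = "mmm", centering = "P",
                       n_atoms = 20, b_iso = 2, seed = 1L) {
  stopifnot(n_atoms >= 1, b_iso >= 0)
  structure(list(name = name, cell = as_unit_cell(cell), laue = laue,
                 centering = centering, n_atoms = n_atoms, b_iso = b_iso,
                 seed = as.integer(seed)),
            class = "phase_spec")
}

#' Ground-truth intensities of a synthetic phase
#'
#' Evaluates the point-scatterer intensity model of [phase_spec()] on the
#' symmetry-unique reflections to `d_min`. Deterministic for a fixed spec.
#'
#' @param spec A [phase_spec()].
#' @param d_min Resolution limit in Angstrom.
#' @return Tibble `h, k, l, d, I_true` on canonical indices.
#' @export
simulate_phase_intensities <- function(spec, d_min = 1.2) {
  stopifnot(inherits(spec, "phase_spec"))
  uniq <- enumerate_unique(spec$cell, spec$laue, spec$centering, d_min)
  xyz <- NULL
  with_local_seed(spec$seed, {
    xyz <- matrix(stats::runif(3 * spec$n_atoms), ncol = 3)
  })
  phase <- 2 * pi * (as.matrix(uniq[, c("h", "k", "l")]) %*% t(xyz))
  f2 <- rowSums(cos(phase))^2 + rowSums(sin(phase))^2
  uniq$I_true <- f2 * exp(-spec$b_iso / (2 * uniq$d^2))
  uniq
}

#' Per-crystal simulation settings
#'
#' One simulated crystal samples a geometric rotation wedge of reciprocal
#' space: a symmetry equivalent of a unique reflection is observed iff the
#' azimuth of its reciprocal vector about a seeded random rotation axis
#' falls inside `[wedge_start, wedge_start + wedge_range)` degrees. This
#' deliberately ignores excitation-error/curvature physics — clustering and
#' merging only depend on *which* uniques are sampled, not on diffraction
#' physics. Observed intensities get a per-crystal scale, multiplicative
#' Gaussian noise, and sigma = max(noise_frac * |I|, sigma_floor); the
#' reported cell is jittered to emulate the sample-height-induced cell
#' variation of serial data.
#'
#' @param phase Phase name (bookkeeping).
#' @param wedge_start Wedge start azimuth in degrees.
#' @param wedge_range Wedge width in degrees (> 0; 360 = complete).
#' @param scale Per-crystal multiplicative scale (> 0).
#' @param noise_frac Relative noise level (fraction of I).
#' @param sigma_floor Absolute sigma floor.
#' @param cell_jitter_sigma Length-2 vector: sd of the reported-cell jitter
#'   for lengths (Angstrom) and angles (degrees).
#' @param misindex Apply a scrambling (mis-indexing) operator to this
#'   crystal, making it an outlier for reflection clustering.
#' @param seed Integer seed for this crystal.
#' @return List of class `crystal_sim_spec`.
#' @export
crystal_sim_spec <- function(phase, wedge_start = 0, wedge_range = 30,
                             scale = 1, noise_frac = 0.1, sigma_floor = 0.1,
                             cell_jitter_sigma = c(0.3, 0.3),
                             misindex = FALSE, seed = 1L) {
  stopifnot(wedge_range > 0, scale > 0, noise_frac >= 0, sigma_floor >= 0)
  structure(list(phase = phase, wedge_start = wedge_start,
                 wedge_range = wedge_range, scale = scale,
                 noise_frac = noise_frac, sigma_floor = sigma_floor,
                 cell_jitter_sigma = rep_len(cell_jitter_sigma, 2),
                 misindex = misindex, seed = as.integer(seed)),
            class = "crystal_sim_spec")
}

#' Simulate one crystal's dataset from a phase intensity table
#'
#' @param phase_tab Output of [simulate_phase_intensities()].
#' @param phase_def The [phase_spec()] the table came from.
#' @param spec A [crystal_sim_spec()].
#' @param dataset_id Identifier for the resulting set.
#' @return List with `set` (unmerged [refl_set()] of observed measurements,
#'   indices being whichever symmetry equivalents fell in the wedge) and
#'   `cell_row` (one cell-table row with the jittered cell).
#' @export
simulate_crystal_dataset <- function(phase_tab, phase_def, spec,
                                     dataset_id = spec$phase) {
  stopifnot(inherits(spec, "crystal_sim_spec"), inherits(phase_def, "phase_spec"))
  laue <- laue_group(phase_def$laue)
  canon <- as.matrix(phase_tab[, c("h", "k", "l")])
  # expand each unique to its full orbit of distinct equivalents
  orbit <- lapply(laue$ops, function(m) canon %*% m)
  equiv <- do.call(rbind, orbit)
  origin <- rep(seq_len(nrow(canon)), times = length(orbit))
  key <- paste(equiv[, 1], equiv[, 2], equiv[, 3], origin)
  keep <- !duplicated(key)
  equiv <- equiv[keep, , drop = FALSE]
  origin <- origin[keep]

  rec <- reciprocal_basis(phase_def$cell)
  svec <- equiv %*% rec
  out <- NULL
  with_local_seed(spec$seed, {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    # orthonormal frame (axis, v, w); azimuth measured in the v-w plane
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ref - sum(ref * axis) * axis
    v <- v / sqrt(sum(v^2))
    w <- c(axis[2] * v[3] - axis[3] * v[2],
           axis[3] * v[1] - axis[1] * v[3],
           axis[1] * v[2] - axis[2] * v[1])
    az <- (atan2(svec %*% w, svec %*% v) * 180 / pi) %% 360
    sel <- ((az - spec$wedge_start) %% 360) < spec$wedge_range
    hkl_obs <- equiv[sel, , drop = FALSE]
    i_true <- phase_tab$I_true[origin[sel]]
    eps <- stats::rnorm(length(i_true), 0, spec$noise_frac)
    i_obs <- spec$scale * i_true * (1 + eps)
    sig <- pmax(spec$noise_frac * abs(i_obs), spec$sigma_floor)
    if (spec$misindex) {
      # scramble with an operator outside the Laue group: looks indexable
      # but correlates with nothing (a wrongly indexed outlier)
      scram <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE)
      hkl_obs <- hkl_obs %*% scram
    }
    jit <- c(stats::rnorm(3, 0, spec$cell_jitter_sigma[1]),
             stats::rnorm(3, 0, spec$cell_jitter_sigma[2]))
    out <- list(hkl = hkl_obs, I = i_obs, sigma = sig, jitter = jit)
  })
  if (nrow(out$hkl) < 10) {
    warning("wedge sampled fewer than 10 reflections for ", dataset_id)
  }
  cell_rep <- unclass(phase_def$cell) + out$jitter
  set <- refl_set(dataset_id, phase_def$cell, phase_def$laue,
                  phase_def$centering,
                  tibble::tibble(h = out$hkl[, 1], k = out$hkl[, 2],
                                 l = out$hkl[, 3], I = out$I,
                                 sigma = out$sigma),
                  merged = FALSE)
  cell_row <- tibble::tibble(
    dataset_id = dataset_id,
    a = cell_rep[1], b = cell_rep[2], c = cell_rep[3],
    alpha = cell_rep[4], beta = cell_rep[5], gamma = cell_rep[6],
    lattice_type = lattice_symbol(phase_def),
    n_indexed = nrow(out$hkl), rotation_range = spec$wedge_range,
    source_path = NA_character_)
  list(set = set, cell_row = cell_row)
}

lattice_symbol <- function(phase_def) {
  family <- switch(phase_def$laue,
                   "-1" = "a", "2/m" = "m", "mmm" = "o",
                   "4/m" = "t", "4/mmm" = "t",
                   "-3" = "h", "-3m" = "h", "6/m" = "h", "6/mmm" = "h",
                   "m-3" = "c", "m-3m" = "c")
  paste0(family, phase_def$centering)
}

#' Simulate a multi-crystal mixture scenario
#'
#' Ready-made study conditions for exercising the two-stage pipeline:
#' \describe{
#'   \item{single}{one phase, n crystals.}
#'   \item{distinct_cells}{two phases with clearly different cells (an
#'     MFI-type and a MOR-type zeolite cell) — separable by lattice-based
#'     clustering alone.}
#'   \item{similar_cells}{two phases sharing an identical cell but with
#'     independent intensity tables — inseparable by lattice clustering,
#'     separable by reflection-based clustering.}
#'   \item{ambiguity}{one orthorhombic phase with b = c; half the crystals
#'     are indexed through the axis swap (h,k,l) -> (h,l,k), emulating the
#'     indexing ambiguity of near-equal axes. The swap operator itself
#'     resolves it.}
#'   \item{with_outliers}{like `single` plus two crystals whose reported
#'     cells deviate strongly (lattice outliers).}
#' }
#'
#' @param scenario Scenario name (see above).
#' @param n_per_phase Crystals per phase.
#' @param seed Master integer seed; each crystal derives its own stream.
#' @param d_min Resolution limit of the ground-truth tables.
#' @param noise_frac,wedge_range,cell_jitter_sigma Per-crystal settings
#'   (see [crystal_sim_spec()]).
#' @return List of class `sim_mixture`: `sets` (list of unmerged
#'   [refl_set()]), `cells` (cell table), `labels` (tibble `dataset_id,
#'   phase, misindexed`), `phases` (list of [phase_spec()]), `tables`
#'   (ground-truth intensity tables), `scenario`.
#' @export
simulate_mixture <- function(scenario = c("single", "distinct_cells",
                                          "similar_cells", "ambiguity",
                                          "with_outliers"),
                             n_per_phase = 10, seed = 1L, d_min = 1.2,
                             noise_frac = 0.1, wedge_range = 30,
                             cell_jitter_sigma = c(0.3, 0.3)) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  mfi_cell <- unit_cell(13.4, 19.9, 20.1)    # MFI-type cell, XDS setting
  mor_cell <- unit_cell(7.5, 18.3, 20.5)     # MOR-type cell, XDS setting
  amb_cell <- unit_cell(13.4, 19.9, 19.9)    # b = c: ambiguous indexing
  phases <- switch(scenario,
    single = list(phase_spec("phase_A", mfi_cell, seed = seed)),
    with_outliers = list(phase_spec("phase_A", mfi_cell, seed = seed)),
    distinct_cells = list(
      phase_spec("phase_A", mfi_cell, seed = seed),
      phase_spec("phase_B", mor_cell, seed = seed + 1L)),
    similar_cells = list(
      phase_spec("phase_A", mfi_cell, seed = seed),
      phase_spec("phase_B", mfi_cell, seed = seed + 1L)),
    ambiguity = list(phase_spec("phase_A", amb_cell, seed = seed)))
  tables <- lapply(phases, simulate_phase_intensities, d_min = d_min)
  names(tables) <- vapply(phases, function(p) p$name, character(1))

  swap_bc <- reindex_op(c(1, 0, 0, 0, 0, 1, 0, 1, 0))  # (h,k,l)->(h,l,k)
  sets <- list(); cell_rows <- list(); labels <- list()
  idx <- 0
  for (pi in seq_along(phases)) {
    ph <- phases[[pi]]
    for (ci in seq_len(n_per_phase)) {
      idx <- idx + 1
      id <- sprintf("%s_%02d", ph$name, ci)
      cseed <- seed + 1000L * pi + ci
      cspec <- crystal_sim_spec(
        phase = ph$name,
        wedge_start = (cseed * 37) %% 360,
        wedge_range = wedge_range,
        scale = 0.5 + 1.5 * (((cseed * 17) %% 100) / 99),
        noise_frac = noise_frac,
        cell_jitter_sigma = cell_jitter_sigma,
        seed = cseed)
      sim <- simulate_crystal_dataset(tables[[ph$name]], ph, cspec,
                                      dataset_id = id)
      swapped <- scenario == "ambiguity" && ci > n_per_phase / 2
      if (swapped) sim$set <- apply_reindex(sim$set, swap_bc)
      sets[[idx]] <- sim$set
      cell_rows[[idx]] <- sim$cell_row
      labels[[idx]] <- tibble::tibble(
        dataset_id = id,
        phase = if (scenario == "ambiguity" && swapped) "phase_A_swapped"
                else ph$name,
        misindexed = FALSE)
    }
  }
  cells <- dplyr::bind_rows(cell_rows)
  if (scenario == "with_outliers") {
    # two cells deviating by far more than the within-cluster spread
    for (j in 1:2) {
      idx <- idx + 1
      id <- sprintf("outlier_%02d", j)
      off <- c(6, -5, 7) * j / 2
      cells <- dplyr::bind_rows(cells, tibble::tibble(
        dataset_id = id,
        a = 13.4 + off[1], b = 19.9 + off[2], c = 20.1 + off[3],
        alpha = 90, beta = 90, gamma = 90,
        lattice_type = "oP", n_indexed = 50L, rotation_range = 10,
        source_path = NA_character_))
      labels[[idx]] <- tibble::tibble(dataset_id = id, phase = "outlier",
                                      misindexed = TRUE)
    }
  }
  structure(list(sets = sets, cells = cells,
                 labels = dplyr::bind_rows(labels),
                 phases = phases, tables = tables, scenario = scenario,
                 seed = seed, d_min = d_min),
            class = "sim_mixture")
}

#' @export
print.sim_mixture <- function(x, ...) {
  cat(sprintf("<sim_mixture> scenario '%s': %d datasets, %d phase(s), seed %d\n",
              x$scenario, nrow(x$labels), length(x$phases), x$seed))
  invisible(x)
}

#' Simulate a defocused-beam diffraction frame with an off-centre crystal
#'
#' Emulates the tracking image: a flat-top bright disc (the defocused
#' primary beam, soft 2-pixel edge), a darker disc inside it (the crystal's
#' shadow at `1 - contrast` of the beam intensity), low-level background
#' texture, and Gaussian noise. Ground-truth beam and particle centres are
#' returned so recovery can be scored.
#'
#' @param nrow_px,ncol_px Frame dimensions in pixels (>= 16).
#' @param beam_center `(row, col)` of the beam centre (1-based pixels).
#' @param beam_radius Beam radius in pixels.
#' @param particle_offset `(drow, dcol)` of the particle centre relative to
#'   the beam centre; must satisfy |offset| < beam_radius.
#' @param particle_radius Particle radius in pixels.
#' @param contrast Fractional attenuation of the beam under the particle
#'   (0.85 puts the particle interior inside the 10-20% segmentation band).
#' @param noise_sigma Gaussian noise sd, as a fraction of beam intensity.
#' @param seed Integer seed.
#' @return List with `frame` (matrix, beam intensity 1), `beam_center`,
#'   `particle_center`.
#' @export
simulate_defocused_frame <- function(nrow_px = 200, ncol_px = 256,
                                     beam_center = c(100, 128),
                                     beam_radius = 40,
                                     particle_offset = c(0, 0),
                                     particle_radius = beam_radius / 4,
                                     contrast = 0.85, noise_sigma = 0,
                                     seed = 1L) {
  stopifnot(nrow_px >= 16, ncol_px >= 16)
  if (sqrt(sum(particle_offset^2)) >= beam_radius) {
    stop("particle_offset must be smaller than beam_radius", call. = FALSE)
  }
  pc <- beam_center + particle_offset
  rows <- matrix(seq_len(nrow_px), nrow_px, ncol_px)
  cols <- matrix(seq_len(ncol_px), nrow_px, ncol_px, byrow = TRUE)
  soft_disc <- function(center, radius, edge = 2) {
    r <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
    pmin(1, pmax(0, (radius - r) / edge + 0.5))
  }
  frame <- soft_disc(beam_center, beam_radius)
  frame <- frame * (1 - contrast * soft_disc(pc, particle_radius))
  with_local_seed(seed, {
    # smooth low-level background texture (carbon film)
    bg <- matrix(stats::rnorm(nrow_px * ncol_px), nrow_px, ncol_px)
    bg <- EBImage::gblur(bg, sigma = 6)
    frame <- frame + 0.02 * bg / max(abs(bg))
    if (noise_sigma > 0) {
      frame <- frame + matrix(stats::rnorm(nrow_px * ncol_px, 0, noise_sigma),
                              nrow_px, ncol_px)
    }
  })
  frame <- pmax(frame, 0)   # detector counts are nonnegative
  list(frame = frame, beam_center = as.numeric(beam_center),
       particle_center = as.numeric(pc))
}
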