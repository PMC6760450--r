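#' Construct a unit cell
#'
#' A unit cell is the six lattice parameters (a, b, c in Angstrom; alpha,
#' beta, gamma in degrees) describing the crystal lattice. The cell volume
#' follows from the triclinic formula
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma+2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return A named numeric vector of class `unit_cell` with elements
#'   `a, b, c, alpha, beta, gamma`.
#' @examples
#' uc <- unit_cell(20.07, 19.92, 13.42)
#' cell_volume(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- c(a = unname(a), b = unname(b), c = unname(c),
            alpha = unname(alpha), beta = unname(beta), gamma = unname(gamma))
  validate_unit_cell(cell)
}

#' @rdname unit_cell
#' @param x Object to coerce: a numeric vector of length 6 (ordered
#'   a, b, c, alpha, beta, gamma) or a one-row data frame with those columns.
#' @export
as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[, c("a", "b", "c", "alpha", "beta", "gamma")])
  }
  stopifnot(is.numeric(x), length(x) == 6)
  cell <- stats::setNames(as.numeric(x),
                          c("a", "b", "c", "alpha", "beta", "gamma"))
  validate_unit_cell(cell)
}

validate_unit_cell <- function(cell) {
  if (any(!is.finite(cell))) {
    stop("unit cell parameters must be finite", call. = FALSE)
  }
  if (any(cell[1:3] <= 0)) {
    stop("cell lengths a, b, c must be positive", call. = FALSE)
  }
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) {
    stop("cell angles are geometrically impossible (non-positive volume)",
         call. = FALSE)
  }
  structure(cell, class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g  V=%.5g A^3\n",
              x[["a"]], x[["b"]], x[["c"]], x[["alpha"]], x[["beta"]],
              x[["gamma"]], cell_volume(x)))
  invisible(x)
}

#' Cell volume in cubic Angstrom
#' @param cell A [unit_cell()].
#' @return Volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  cell <- as_unit_cell(cell)
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  cell[["a"]] * cell[["b"]] * cell[["c"]] * sqrt(disc)
}

#' Direct-space metric tensor of a unit cell
#'
#' @param cell A [unit_cell()].
#' @return 3x3 symmetric matrix G with G\[i,j\] = a_i . a_j.
#' @keywords internal
#' @export
metric_tensor <- function(cell) {
  cell <- as_unit_cell(cell)
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), nrow = 3, byrow = TRUE)
}

#' Cartesian basis of a unit cell
#'
#' Rows are the direct lattice vectors a, b, c in a Cartesian frame with a
#' along x and b in the xy plane.
#' @param cell A [unit_cell()].
#' @return 3x3 matrix; rows are direct basis vectors.
#' @keywords internal
#' @export
cartesian_basis <- function(cell) {
  cell <- as_unit_cell(cell)
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  sg <- sin(cell[["gamma"]] * pi / 180)
  v <- cell_volume(cell)
  rbind(c(a, 0, 0),
        c(b * cg, b * sg, 0),
        c(cc * cb, cc * (ca - cb * cg) / sg, v / (a * b * sg)))
}

#' Reciprocal basis of a unit cell
#'
#' Rows are the reciprocal lattice vectors a*, b*, c* in the Cartesian frame
#' of [cartesian_basis()]; the reciprocal vector of `hkl` is `hkl %*% rec`.
#' @param cell A [unit_cell()].
#' @return 3x3 matrix; rows are reciprocal basis vectors (1/Angstrom).
#' @keywords internal
#' @export
reciprocal_basis <- function(cell) {
  solve(t(cartesian_basis(cell)))
}

#' Resolution (d-spacing) of reflections
#'
#' Interplanar spacing d = 1/|h a* + k b* + l c*| from the reciprocal metric
#' tensor of the general triclinic cell. Smaller d means higher resolution.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or an n x 3 matrix / data frame of
#'   Miller indices. (0,0,0) is an error.
#' @return Numeric vector of d-spacings in Angstrom.
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(1, 1, 1)) # 10/sqrt(3)
#' @export
d_spacing <- function(cell, hkl) {
  cell <- as_unit_cell(cell)
  hkl <- as_hkl_matrix(hkl)
  if (any(rowSums(hkl != 0) == 0)) {
    stop("d_spacing undefined for (0,0,0)", call. = FALSE)
  }
  gstar <- solve(metric_tensor(cell))
  q <- rowSums((hkl %*% gstar) * hkl)   # |s|^2 with s in reciprocal space
  1 / sqrt(q)
}

as_hkl_matrix <- function(hkl) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  storage.mode(hkl) <- "double"
  stopifnot(ncol(hkl) == 3)
  hkl
}

#' Distances between unit cells
#'
#' Two metrics for stage-1 (lattice-based) clustering of multi-crystal
#' datasets: `cell_distance_params()` is the Euclidean norm of the difference
#' of the six lattice parameters (lengths in Angstrom and angles in degrees,
#' unweighted; set `normalize = TRUE` for a z-scored variant computed against
#' supplied scales), and `cell_distance_volume()` is the absolute difference
#' of cell volumes in Angstrom^3.
#'
#' @param c1,c2 [unit_cell()] objects.
#' @param normalize If `TRUE`, divide each parameter difference by the
#'   corresponding entry of `scale` before taking the norm.
#' @param scale Numeric length-6 divisor used when `normalize = TRUE`.
#' @return Nonnegative distance; zero iff the cells are equal.
#' @examples
#' cell_distance_params(unit_cell(10, 10, 10), unit_cell(13, 10, 10)) # 3
#' cell_distance_volume(unit_cell(10, 10, 10), unit_cell(11, 11, 11)) # 331
#' @export
cell_distance_params <- function(c1, c2, normalize = FALSE,
                                 scale = rep(1, 6)) {
  c1 <- as_unit_cell(c1); c2 <- as_unit_cell(c2)
  delta <- unclass(c1) - unclass(c2)
  if (normalize) delta <- delta / scale
  sqrt(sum(delta^2))
}

#' @rdname cell_distance_params
#' @export
cell_distance_volume <- function(c1, c2) {
  abs(cell_volume(c1) - cell_volume(c2))
}
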