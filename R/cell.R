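#' Triclinic unit cell
#'
#' Constructs a unit-cell record holding the lattice parameters
#' \eqn{(a, b, c, \alpha, \beta, \gamma)} and the space-group symbol that
#' govern crystal-symmetry expansion of a collagen template.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param space_group Space-group symbol (Hermann-Mauguin, e.g. `"P 1"`).
#'   The collagen fibril cell is triclinic P1.
#'
#' @return An object of class `unit_cell`: a named list with the six lattice
#'   parameters and `space_group`.
#' @examples
#' unit_cell(10, 10, 10)
#' unit_cell(39.97, 26.95, 677.9, 89.2, 94.6, 105.6)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      space_group = "P 1") {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("unit cell lengths must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  cell <- list(a = a, b = b, c = c,
               alpha = alpha, beta = beta, gamma = gamma,
               space_group = as.character(space_group))
  class(cell) <- "unit_cell"
  # reject cells whose angles admit no real lattice (volume term <= 0)
  v <- cell_volume(cell)
  if (!is.finite(v) || v <= 0) stop("degenerate cell", call. = FALSE)
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  [%s]\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$space_group))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180

#' Analytic triclinic cell volume
#'
#' Closed-form volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#' + 2\cos\alpha\cos\beta\cos\gamma}}, used as the independent check on the
#' orientation-matrix determinant.
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma))
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(NaN)
  cell$a * cell$b * cell$c * sqrt(arg)
}

#' Crystal orientation matrix
#'
#' Builds the upper-triangular matrix \eqn{C} mapping fractional (lattice)
#' coordinates to Cartesian Angstrom. Columns are the cell vectors:
#' \deqn{C = \begin{pmatrix} a & b\cos\gamma & c\cos\beta \\
#'  0 & b\sin\gamma & c_{yz} \\ 0 & 0 & \sqrt{c^2 - c_{xz}^2 - c_{yz}^2}
#'  \end{pmatrix}}
#' with \eqn{c_{xz} = c\cos\beta} and
#' \eqn{c_{yz} = c(\cos\alpha - \cos\beta\cos\gamma)/\sin\gamma}.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 numeric matrix (class `orientation_matrix`); `det(C)` equals
#'   [cell_volume()].
#' @examples
#' orientation_matrix(unit_cell(10, 20, 30, gamma = 120))
#' @export
orientation_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma)); sg <- sin(deg2rad(cell$gamma))
  cxz <- cell$c * cb
  cyz <- cell$c * (ca - cb * cg) / sg
  zz2 <- cell$c^2 - cxz^2 - cyz^2
  if (zz2 <= 0) stop("degenerate cell", call. = FALSE)
  C <- matrix(c(cell$a, cell$b * cg, cxz,
                0,      cell$b * sg, cyz,
                0,      0,           sqrt(zz2)),
              nrow = 3, byrow = TRUE)
  # exact zeros below the diagonal by construction
  structure(C, class = c("orientation_matrix", class(C)))
}

om_matrix <- function(C) {
  if (inherits(C, "unit_cell")) C <- orientation_matrix(C)
  unclass(C)
}

#' Fractional to Cartesian coordinates
#'
#' @param p Numeric 3-vector or n x 3 matrix of fractional coordinates.
#' @param C An [orientation_matrix()] (or a [unit_cell()], converted
#'   internally).
#' @return Cartesian coordinates (Angstrom), same shape as `p`.
#' @export
frac_to_cart <- function(p, C) {
  C <- om_matrix(C)
  if (is.null(dim(p))) as.numeric(C %*% p) else p %*% t(C)
}

#' Cartesian to fractional coordinates
#'
#' @param q Numeric 3-vector or n x 3 matrix of Cartesian coordinates
#'   (Angstrom).
#' @inheritParams frac_to_cart
#' @return Fractional coordinates, same shape as `q`.
#' @export
cart_to_frac <- function(q, C) {
  Ci <- solve(om_matrix(C))
  if (is.null(dim(q))) as.numeric(Ci %*% q) else q %*% t(Ci)
}
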