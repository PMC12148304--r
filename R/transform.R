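#' Euclidean transform
#'
#' A rigid-body transform \eqn{T(q) = Rq + t} applied to atom positions when
#' generating symmetry copies. For the triclinic P1 collagen cell `R` is the
#' identity and `t` an integer combination of cell vectors.
#'
#' @param R 3x3 rotation matrix (orthogonal, det +1).
#' @param t Translation 3-vector (Angstrom).
#' @param lattice Optional integer 3-vector: the Bravais lattice point this
#'   transform corresponds to (`t = C %*% lattice` for pure lattice
#'   translations).
#' @return An object of class `xform`.
#' @export
xform <- function(R = diag(3), t = c(0, 0, 0), lattice = NULL) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    stop("R must be a proper rotation (orthogonal, det +1)", call. = FALSE)
  }
  structure(list(R = R, t = t, lattice = lattice), class = "xform")
}

#' @rdname xform
#' @export
xform_identity <- function() xform(lattice = c(0L, 0L, 0L))

#' Invert a transform
#' @param T An [xform()].
#' @return The inverse `xform` with `R' = t(R)`, `t' = -t(R) %*% t`.
#' @export
xform_inverse <- function(T) {
  stopifnot(inherits(T, "xform"))
  Rt <- t(T$R)
  xform(Rt, -as.numeric(Rt %*% T$t),
        lattice = if (!is.null(T$lattice)) -T$lattice else NULL)
}

is_identity_xform <- function(T, tol = 1e-9) {
  max(abs(T$R - diag(3))) < tol && max(abs(T$t)) < tol
}

#' @export
print.xform <- function(x, ...) {
  cat("<xform> t = (", paste(sprintf("%.3f", x$t), collapse = ", "), ")",
      if (!is.null(x$lattice)) paste0("  lattice (",
                                      paste(x$lattice, collapse = ","), ")"),
      "\n", sep = "")
  if (max(abs(x$R - diag(3))) > 1e-12) print(x$R)
  invisible(x)
}

#' Apply a transform to an atom table
#'
#' Maps every atom position through \eqn{q' = Rq + t}; all non-coordinate
#' columns are preserved.
#'
#' @param atoms Atom tibble with `x`, `y`, `z` columns (Angstrom).
#' @param T An [xform()].
#' @return The atom tibble with transformed coordinates.
#' @export
apply_xform <- function(atoms, T) {
  stopifnot(inherits(T, "xform"))
  q <- as.matrix(atoms[, c("x", "y", "z")])
  qp <- q %*% t(T$R)
  atoms$x <- qp[, 1] + T$t[1]
  atoms$y <- qp[, 2] + T$t[2]
  atoms$z <- qp[, 3] + T$t[3]
  atoms
}
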