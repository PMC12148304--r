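# Pairwise geometry kernels shared by the expansion, clash and crosslink code.

cross_dist2 <- function(A, B) {
  # squared distances between rows of A (n x 3) and rows of B (m x 3)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

min_set_dist <- function(A, B, chunk = 2000L) {
  best <- Inf
  idx <- split(seq_len(nrow(A)), ceiling(seq_len(nrow(A)) / chunk))
  for (i in idx) best <- min(best, min(cross_dist2(A[i, , drop = FALSE], B)))
  sqrt(best)
}

has_pair_within <- function(A, B, d, chunk = 2000L) {
  d2 <- d^2
  idx <- split(seq_len(nrow(A)), ceiling(seq_len(nrow(A)) / chunk))
  for (i in idx) {
    if (any(cross_dist2(A[i, , drop = FALSE], B) <= d2)) return(TRUE)
  }
  FALSE
}

bbox_gap <- function(boxA, t, widths) {
  # lower bound on the distance between a point cloud and its translate by t
  g <- pmax(0, abs(t) - widths)
  sqrt(sum(g^2))
}

normalize_space_group <- function(symbol) {
  s <- toupper(gsub("[[:space:]]", "", symbol))
  if (!grepl("^[PABCIFRH][0-9A-Z/:-]*$", s)) {
    stop("unknown space group: ", symbol, call. = FALSE)
  }
  s
}

#' Enumerate symmetry copies within a contact distance
#'
#' Finds every lattice translation of the unit cell whose transformed copy of
#' the template has at least one atom within `d_c` of any atom of the
#' original. Larger contact distances include copies further from the origin
#' and hence produce larger fibrils. The triclinic P1 cell of collagen is
#' supported fully; for other space groups only the translational sub-lattice
#' is applied (with a warning).
#'
#' @param atoms Atom tibble of the template (Angstrom coordinates).
#' @param cell A [unit_cell()].
#' @param d_c Contact distance in Angstrom (non-negative). A copy is included
#'   when its minimal interatomic distance to the original is `<= d_c`.
#' @return List of [xform()] objects (identity always included), ordered
#'   lexicographically by lattice indices `(nx, ny, nz)`.
#' @details The candidate lattice range is bounded per dimension by
#'   `|n_i| <= sum_k |C^-1[i,k]| * (w_k + d_c)` where `w` are the widths of the
#'   atom cloud: any translation moving the cloud entirely beyond its own
#'   bounding box dilated by `d_c` cannot contain an included copy. A
#'   bounding-box distance bound prunes candidates before the exact any-atom
#'   check.
#' @export
enumerate_symmetry_copies <- function(atoms, cell, d_c) {
  stopifnot(d_c >= 0)
  sg <- normalize_space_group(cell$space_group)
  if (sg != "P1") {
    warning("space group ", cell$space_group,
            ": only the translational sub-lattice is applied")
  }
  Q <- as.matrix(atoms[, c("x", "y", "z")])
  C <- om_matrix(orientation_matrix(cell))
  Ci <- solve(C)
  w <- apply(Q, 2, function(v) diff(range(v)))
  L <- ceiling(abs(Ci) %*% (w + d_c))
  grid <- expand.grid(nz = -L[3]:L[3], ny = -L[2]:L[2], nx = -L[1]:L[1])
  grid <- grid[order(grid$nx, grid$ny, grid$nz), c("nx", "ny", "nz")]
  tmat <- as.matrix(grid) %*% t(C)
  lb <- sqrt(rowSums(pmax(abs(tmat) - rep(w, each = nrow(tmat)), 0)^2))
  keep <- which(lb <= d_c)
  out <- list()
  for (i in keep) {
    n <- as.integer(grid[i, ])
    if (all(n == 0L)) {
      out[[length(out) + 1L]] <- xform_identity()
      next
    }
    t <- tmat[i, ]
    if (has_pair_within(Q, sweep(Q, 2, t, "+"), d_c)) {
      out[[length(out) + 1L]] <- xform(t = t, lattice = n)
    }
  }
  out
}

has_copy_clash <- function(A, rA, B, rB, overlap_fraction, chunk = 1500L) {
  # TRUE when any inter-copy pair is closer than overlap_fraction * (ri + rj)
  maxthr <- overlap_fraction * (max(rA) + max(rB))
  wA <- apply(A, 2, range); wB <- apply(B, 2, range)
  gap <- pmax(0, pmax(wA[1, ] - wB[2, ], wB[1, ] - wA[2, ]))
  if (sqrt(sum(gap^2)) >= maxthr) return(FALSE)
  idx <- split(seq_len(nrow(A)), ceiling(seq_len(nrow(A)) / chunk))
  for (i in idx) {
    d2 <- cross_dist2(A[i, , drop = FALSE], B)
    thr <- outer(rA[i], rB, "+") * overlap_fraction
    if (any(d2 < thr^2)) return(TRUE)
  }
  FALSE
}

#' Remove sterically clashing copies
#'
#' Greedy whole-copy clash filter: molecules are visited in enumeration order
#' and retained only if no atom comes closer than
#' `overlap_fraction * (rw_i + rw_j)` (van der Waals radii) to any atom of an
#' already-retained molecule. The first (identity) molecule is never removed.
#'
#' @param system A [fibril_system()].
#' @param overlap_fraction Fraction of the summed van der Waals radii below
#'   which a pair counts as a clash (default 0.6).
#' @return The filtered [fibril_system()]; removed molecule ids are recorded
#'   in attribute `"removed"`.
#' @export
remove_clashes <- function(system, overlap_fraction = 0.6) {
  mols <- system$molecules
  stopifnot(length(mols) >= 1)
  # the identity copy is processed first so it can never be removed,
  # whatever its position in the enumeration order
  id_idx <- which(vapply(mols, function(m) {
    is_identity_xform(m$transform)
  }, logical(1)))[1]
  if (is.na(id_idx)) id_idx <- 1L
  mols <- c(mols[id_idx], mols[-id_idx])
  kept <- list(mols[[1]])
  removed <- integer()
  coords <- list(as.matrix(mols[[1]]$atoms[, c("x", "y", "z")]))
  radii <- list(mols[[1]]$atoms$vdw)
  for (m in mols[-1]) {
    A <- as.matrix(m$atoms[, c("x", "y", "z")])
    rA <- m$atoms$vdw
    clash <- FALSE
    for (j in seq_along(kept)) {
      if (has_copy_clash(A, rA, coords[[j]], radii[[j]], overlap_fraction)) {
        clash <- TRUE
        break
      }
    }
    if (clash) {
      removed <- c(removed, m$id)
    } else {
      kept[[length(kept) + 1L]] <- m
      coords[[length(coords) + 1L]] <- A
      radii[[length(radii) + 1L]] <- rA
    }
  }
  out <- fibril_system(kept, system$cell, seed = system$seed)
  attr(out, "removed") <- removed
  out
}

#' Expand a template into a fibril system
#'
#' Full crystal-contacts step: enumerate symmetry copies within the contact
#' distance, transform the template atoms and crosslink sites into each copy,
#' and remove sterically clashing copies.
#'
#' @param template Template PDB text/path, or the result of
#'   [parse_template()].
#' @param d_c Contact distance (Angstrom).
#' @param overlap_fraction Clash threshold passed to [remove_clashes()].
#' @param registry Crosslink library used to annotate sites
#'   (default [crosslink_registry()]).
#' @return A [fibril_system()] whose molecules carry transforms, lattice
#'   points and crosslink sites.
#' @export
expand_template <- function(template, d_c, overlap_fraction = 0.6,
                            registry = crosslink_registry()) {
  if (!is.list(template) || is.null(template$atoms)) {
    template <- parse_template(template)
  }
  atoms <- template$atoms
  cell <- template$cell
  sites <- detect_sites(atoms, registry)
  xfs <- enumerate_symmetry_copies(atoms, cell, d_c)
  mols <- purrr::imap(xfs, function(T, i) {
    s <- sites
    if (nrow(s) > 0) s <- apply_xform(s, T)
    new_molecule(i, apply_xform(atoms, T), transform = T,
                 lattice = T$lattice, sites = s)
  })
  remove_clashes(fibril_system(mols, cell), overlap_fraction)
}
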