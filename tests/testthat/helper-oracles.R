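# Independent oracles used to cross-check the implementation.

# Brute-force symmetry-copy enumeration over lattice indices in [-3, 3]^3:
# include every translation whose copy has an atom within d_c of the original.
oracle_symmetry_lattice <- function(atoms, cell, d_c) {
  Q <- as.matrix(atoms[, c("x", "y", "z")])
  C <- orientation_matrix(cell)
  grid <- expand.grid(nx = -3:3, ny = -3:3, nz = -3:3)
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    t <- as.numeric(unclass(C) %*% as.numeric(grid[i, ]))
    Qt <- sweep(Q, 2, t, "+")
    dmin <- sqrt(min(outer(rowSums(Q^2), rowSums(Qt^2), "+") -
                       2 * Q %*% t(Qt)))
    keep[i] <- dmin <= d_c
  }
  m <- as.matrix(grid[keep, , drop = FALSE])
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

xform_lattice_matrix <- function(xfs) {
  m <- do.call(rbind, lapply(xfs, function(x) x$lattice))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# O(n^2) all-pairs clash scan between molecules of a system; returns the
# number of violating inter-molecule atom pairs.
oracle_clash_pairs <- function(system, overlap_fraction = 0.6) {
  mols <- system$molecules
  bad <- 0L
  if (length(mols) < 2) return(bad)
  for (i in seq_len(length(mols) - 1)) {
    for (j in (i + 1):length(mols)) {
      A <- as.matrix(mols[[i]]$atoms[, c("x", "y", "z")])
      B <- as.matrix(mols[[j]]$atoms[, c("x", "y", "z")])
      rA <- mols[[i]]$atoms$vdw; rB <- mols[[j]]$atoms$vdw
      d <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
      thr <- outer(rA, rB, "+") * overlap_fraction
      bad <- bad + sum(d < thr)
    }
  }
  bad
}

# Exact 1-D k-means by dynamic programming (minimum within-cluster sum of
# squares over sorted points); returns sorted cluster means.
oracle_kmeans_1d <- function(z, k) {
  z <- sort(z)
  n <- length(z)
  cz <- cumsum(z); cz2 <- cumsum(z^2)
  sse <- function(i, j) {
    # within-SS of z[i..j]
    s <- cz[j] - if (i > 1) cz[i - 1] else 0
    s2 <- cz2[j] - if (i > 1) cz2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        for (i in q:j) {
          v <- D[q - 1, i - 1] + sse(i, j)
          if (v < D[q, j]) {
            D[q, j] <- v
            B[q, j] <- i
          }
        }
      }
    }
  }
  # recover boundaries
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  for (q in k:2) {
    i <- B[q, j]
    bounds[q] <- i - 1L
    j <- i - 1L
  }
  bounds[1] <- 0L
  centers <- vapply(1:k, function(q) {
    mean(z[(bounds[q] + 1):bounds[q + 1]])
  }, numeric(1))
  sort(centers)
}

# Random valid triclinic cell whose symmetry enumeration stays well inside
# the [-3,3]^3 oracle window for d_c <= 8.
random_cell <- function() {
  repeat {
    cl <- try(unit_cell(runif(1, 6, 15), runif(1, 6, 15), runif(1, 6, 15),
                        runif(1, 70, 110), runif(1, 70, 110),
                        runif(1, 70, 110)), silent = TRUE)
    if (!inherits(cl, "try-error") && is.finite(cell_volume(cl))) return(cl)
  }
}

# A lightweight molecule with one crosslink-site residue per terminus; for
# statistical tests that need many molecules cheaply. Sites are written
# directly (same schema detect_sites produces) to keep construction O(n).
light_site_molecule <- function(id, x = 0) {
  atoms <- fibrilforge:::new_atom_tbl(
    serial = 1:3, atom = c("CA", "NZ", "NZ"),
    resname = c("GLY", "L4Y", "L5Y"), chain = "A", resid = 1:3,
    x = x, y = 0, z = c(140, 0, 280), type = c("ATOM", "HETATM", "HETATM"))
  atoms$vdw <- vdw_radius(atoms$element)
  sites <- tibble::tibble(
    site_id = c("A2", "A3"), type = "HLKNL", terminus = c("N", "C"),
    chain = "A", resid = 2:3, resname = c("L4Y", "L5Y"), atom = "NZ",
    x = x, y = 0, z = c(0, 280))
  new_molecule(id, atoms, sites = sites)
}

light_site_system <- function(n, spacing = 100) {
  proto <- light_site_molecule(1)
  mols <- lapply(seq_len(n), function(i) {
    m <- proto
    m$id <- i
    m$atoms$x <- (i - 1) * spacing
    m$sites$x <- (i - 1) * spacing
    m
  })
  fibril_system(mols, unit_cell(spacing, spacing, 300))
}

# Plain-loop recomputation of the quadrant nearest-neighbor spacing metric
# (principal-axes frame, four quadrants, nearest neighbor per non-empty
# quadrant); independent of the package's vectorized implementation.
oracle_quadrant_spacings <- function(xy_nm) {
  xc <- sweep(xy_nm, 2, colMeans(xy_nm))
  ev <- eigen(stats::cov(xc), symmetric = TRUE)$vectors
  for (j in 1:2) {
    lead <- which(abs(ev[, j]) > 1e-12)[1]
    if (ev[lead, j] < 0) ev[, j] <- -ev[, j]
  }
  p <- xc %*% ev
  out <- numeric()
  for (i in seq_len(nrow(p))) {
    best <- rep(Inf, 4)
    for (j in seq_len(nrow(p))) {
      if (i == j) next
      dx <- p[j, 1] - p[i, 1]; dy <- p[j, 2] - p[i, 2]
      q <- if (dx >= 0 && dy > 0) 1 else if (dx < 0 && dy >= 0) 2 else
        if (dx <= 0 && dy < 0) 3 else 4
      dist <- sqrt(dx^2 + dy^2)
      if (dist < best[q]) best[q] <- dist
    }
    out <- c(out, best[is.finite(best)])
  }
  out
}
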