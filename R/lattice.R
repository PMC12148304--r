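#' Map a Cartesian translation to its Bravais lattice point
#'
#' Inverts the orientation matrix: `p = C^-1 t`. The result must be integer
#' (the quasicrystalline fibril lives on the discrete lattice); translations
#' off the lattice are rejected loudly rather than silently rounded.
#'
#' @param t Cartesian translation 3-vector (Angstrom).
#' @param C An [orientation_matrix()] or [unit_cell()].
#' @param tol Maximum deviation from an integer per component (default 1e-3).
#' @return Integer 3-vector `(nx, ny, nz)`.
#' @export
map_to_lattice <- function(t, C, tol = 1e-3) {
  p <- cart_to_frac(as.numeric(t), C)
  r <- round(p)
  if (any(abs(p - r) > tol)) {
    stop("translation off Bravais lattice: p = (",
         paste(sprintf("%.6f", p), collapse = ", "), ")", call. = FALSE)
  }
  as.integer(r)
}

#' Candidate lattice points in one layer
#'
#' For a given `nz` layer, spans the rectangle between the extreme occupied
#' `nx`, `ny` values (optionally padded by `delta[1:2]`) and returns the
#' unoccupied points: the layer's optimization space.
#'
#' @param system A [fibril_system()].
#' @param lz Integer layer index (`nz` value).
#' @param delta Integer 3-vector `(delta_x, delta_y, delta_z)`; the x/y
#'   components pad the candidate rectangle (default no padding).
#' @return Tibble of candidate points `nx`, `ny`, `nz` (possibly empty).
#' @export
layer_candidates <- function(system, lz, delta = c(0L, 0L, 0L)) {
  pts <- lattice_points(system)
  occ <- pts[pts$nz == lz, ]
  empty <- tibble::tibble(nx = integer(), ny = integer(), nz = integer())
  if (nrow(occ) == 0) return(empty)
  rect <- tidyr::expand_grid(
    nx = (min(occ$nx) - delta[1]):(max(occ$nx) + delta[1]),
    ny = (min(occ$ny) - delta[2]):(max(occ$ny) + delta[2]))
  rect$nz <- as.integer(lz)
  dplyr::anti_join(rect, occ, by = c("nx", "ny", "nz"))
}

selected_layers <- function(system, delta_z) {
  # Boundary nz-layers chosen for optimization: delta_z layers adjacent to
  # each extreme layer (the extremes themselves excluded), ordered from the
  # outermost selected layer inward, lower block first.
  if (delta_z <= 0) return(integer())
  nzs <- lattice_points(system)$nz
  lo <- min(nzs); hi <- max(nzs)
  lower <- seq(lo + 1L, by = 1L, length.out = delta_z)
  upper <- seq(hi - 1L, by = -1L, length.out = delta_z)
  layers <- c(lower[lower < hi], upper[upper > lo])
  layers[!duplicated(layers)]
}

#' Layer-by-layer lattice optimization
#'
#' Adds crosslinkable triple helices at fibril boundaries. The solution space
#' `delta = (delta_x, delta_y, delta_z)` selects `2 * delta_z` boundary
#' nz-layers; within each layer, unoccupied rectangle points are visited in
#' seeded random order. Each candidate `p'` is mapped to Cartesian space
#' (`t' = C p'`), a trial molecule is built by translating the reference
#' molecule, and it is accepted as molecule `M+1` iff (i) some
#' inter-crosslink atom pair between the trial and an existing molecule lies
#' within `contact_cutoff` and (ii) the trial introduces no steric clash. The
#' occupied set is updated after every acceptance; layers are processed from
#' the outermost selected layer inward, lower block first, until every
#' layer's candidate set is exhausted. Existing molecules are never removed.
#'
#' @param system A [fibril_system()] whose molecules carry crosslink sites.
#' @param delta Integer 3-vector solution-space bound; with
#'   `delta = c(0,0,0)` the system is returned unchanged.
#' @param contact_cutoff Inter-crosslink acceptance distance in Angstrom
#'   (default 3.0 = 0.3 nm, the noncovalent contact criterion).
#' @param overlap_fraction Clash threshold (see [remove_clashes()]).
#' @param seed Integer seed for the candidate visitation order.
#' @return The optimized system. Attribute `"opt_report"` is a tibble with
#'   one row per layer: `layer`, `candidates`, `accepted`,
#'   `rejected_distance`, `rejected_clash`.
#' @export
optimize_layers <- function(system, delta, contact_cutoff = 3.0,
                            overlap_fraction = 0.6, seed = 1L) {
  delta <- as.integer(delta)
  stopifnot(length(delta) == 3, all(delta >= 0))
  report <- tibble::tibble(layer = integer(), candidates = integer(),
                           accepted = integer(), rejected_distance = integer(),
                           rejected_clash = integer())
  if (delta[3] == 0 || n_molecules(system) == 0) {
    attr(system, "opt_report") <- report
    return(system)
  }
  ref <- system$molecules[[1]]
  if (nrow(ref$sites) == 0) {
    stop("reference molecule has no crosslink sites", call. = FALSE)
  }
  C <- om_matrix(system$orientation)
  ref_shift_base <- as.numeric(C %*% ref$lattice)
  layers <- selected_layers(system, delta[3])
  rng_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, length(layers)))
  for (li in seq_along(layers)) {
    lz <- layers[li]
    cands <- layer_candidates(system, lz, delta)
    n_cand <- nrow(cands)
    acc <- rejd <- rejc <- 0L
    if (n_cand > 0) {
      ord <- withr::with_seed(rng_seeds[li], sample.int(n_cand))
      for (i in ord) {
        p <- as.integer(unlist(cands[i, c("nx", "ny", "nz")]))
        shift <- as.numeric(C %*% p) - ref_shift_base
        trial_sites <- ref$sites
        trial_sites$x <- trial_sites$x + shift[1]
        trial_sites$y <- trial_sites$y + shift[2]
        trial_sites$z <- trial_sites$z + shift[3]
        S <- as.matrix(trial_sites[, c("x", "y", "z")])
        contact <- FALSE
        for (m in system$molecules) {
          if (nrow(m$sites) == 0) next
          if (has_pair_within(S, as.matrix(m$sites[, c("x", "y", "z")]),
                              contact_cutoff)) {
            contact <- TRUE
            break
          }
        }
        if (!contact) {
          rejd <- rejd + 1L
          next
        }
        trial_atoms <- ref$atoms
        trial_atoms$x <- trial_atoms$x + shift[1]
        trial_atoms$y <- trial_atoms$y + shift[2]
        trial_atoms$z <- trial_atoms$z + shift[3]
        A <- as.matrix(trial_atoms[, c("x", "y", "z")])
        clash <- FALSE
        for (m in system$molecules) {
          if (has_copy_clash(A, trial_atoms$vdw,
                             as.matrix(m$atoms[, c("x", "y", "z")]),
                             m$atoms$vdw, overlap_fraction)) {
            clash <- TRUE
            break
          }
        }
        if (clash) {
          rejc <- rejc + 1L
          next
        }
        new_id <- max(vapply(system$molecules, function(m) m$id, integer(1))) + 1L
        t_new <- as.numeric(C %*% p)
        system$molecules[[length(system$molecules) + 1L]] <-
          new_molecule(new_id, trial_atoms,
                       transform = xform(t = t_new, lattice = p),
                       lattice = p, sites = trial_sites)
        acc <- acc + 1L
      }
    }
    report <- dplyr::bind_rows(report, tibble::tibble(
      layer = lz, candidates = n_cand, accepted = acc,
      rejected_distance = rejd, rejected_clash = rejc))
  }
  attr(system, "opt_report") <- report
  system
}

#' Write an optimization report as JSON lines
#'
#' @param system A system returned by [optimize_layers()] (or the report
#'   tibble itself).
#' @param path Output file; one JSON object per layer.
#' @return Invisibly, the lines written.
#' @export
write_opt_report <- function(system, path) {
  report <- if (inherits(system, "fibril_system")) {
    attr(system, "opt_report")
  } else {
    system
  }
  stopifnot(is.data.frame(report))
  lines <- vapply(seq_len(nrow(report)), function(i) {
    jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(lines)
}

#' End-connectivity statistics
#'
#' Classifies every molecule by how many of its ends are crosslinked: an end
#' (N or C) counts as connected when any of its crosslink-site atoms lies
#' within `contact_cutoff` of another molecule's site atoms.
#'
#' @param system A [fibril_system()].
#' @param contact_cutoff Contact distance (Angstrom, default 3.0).
#' @return A tibble (class `connectivity_stats`) with `category`
#'   (`both_ends`, `one_end`, `unconnected`), `n` and `fraction`
#'   (fractions sum to 1).
#' @export
connectivity_stats <- function(system, contact_cutoff = 3.0) {
  M <- n_molecules(system)
  stopifnot(M >= 1)
  sites <- system_sites(system)
  n_ends <- integer(M)
  if (nrow(sites) > 0) {
    xyz <- as.matrix(sites[, c("x", "y", "z")])
    for (i in seq_len(M)) {
      m <- system$molecules[[i]]
      other <- sites$mol_id != m$id
      if (!any(other) || nrow(m$sites) == 0) next
      B <- xyz[other, , drop = FALSE]
      for (term in c("N", "C")) {
        idx <- m$sites$terminus == term
        if (!any(idx)) next
        A <- as.matrix(m$sites[idx, c("x", "y", "z")])
        if (has_pair_within(A, B, contact_cutoff)) {
          n_ends[i] <- n_ends[i] + 1L
        }
      }
    }
  }
  counts <- c(both_ends = sum(n_ends == 2), one_end = sum(n_ends == 1),
              unconnected = sum(n_ends == 0))
  out <- tibble::tibble(category = names(counts), n = as.integer(counts),
                        fraction = counts / M)
  class(out) <- c("connectivity_stats", class(out))
  out
}

#' Radial point density and packing uniformity
#'
#' Projects the lattice points into the transverse plane (perpendicular to
#' the fibril axis) and counts points per radial shell about the lattice
#' origin, normalized by shell area. The standard deviation of per-cell
#' occupancy over the layer rectangles is reported as the packing-uniformity
#' metric (lower is more uniform).
#'
#' @param system A [fibril_system()].
#' @param shell_width Radial shell width in nm (default 5).
#' @return A list (class `density_profile`) with `profile` (tibble: `r_mid`,
#'   `r_inner`, `r_outer` in nm, `n`, `density` per nm^2), `occupancy_sd` and
#'   `n_points`.
#' @export
density_profile <- function(system, shell_width = 5) {
  stopifnot(n_molecules(system) >= 1)
  pts <- lattice_points(system)
  C <- om_matrix(system$orientation)
  xyz <- as.matrix(pts[, c("nx", "ny", "nz")]) %*% t(C)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2) / 10  # nm, transverse distance
  edges <- seq(0, max(r) + shell_width, by = shell_width)
  bin <- cut(r, edges, include.lowest = TRUE, labels = FALSE)
  n <- tabulate(bin, nbins = length(edges) - 1)
  profile <- tibble::tibble(
    r_inner = edges[-length(edges)], r_outer = edges[-1],
    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
    n = as.integer(n),
    density = n / (pi * (edges[-1]^2 - edges[-length(edges)]^2)))
  occ_cells <- unlist(lapply(split(pts, pts$nz), function(layer) {
    rect <- tidyr::expand_grid(nx = min(layer$nx):max(layer$nx),
                               ny = min(layer$ny):max(layer$ny))
    as.integer(paste(rect$nx, rect$ny) %in% paste(layer$nx, layer$ny))
  }))
  structure(list(profile = profile,
                 occupancy_sd = if (length(occ_cells) > 1) stats::sd(occ_cells) else 0,
                 n_points = nrow(pts)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d lattice points, occupancy sd %.4f\n",
              x$n_points, x$occupancy_sd))
  print(x$profile)
  invisible(x)
}
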