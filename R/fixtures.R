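# Deterministic synthetic fixture generators. These emulate the geometric
# features the pipeline relies on — a Gly-X-Y triple helix with canonical
# axial rise, a triclinic cell whose expansion produces a designed molecular
# stagger (D-period), and crosslink-capable residues at both telopeptide
# ends — without attempting biochemical realism. All generators are pure
# functions of their parameters.

helix_frame <- function(theta) {
  radial <- c(cos(theta), sin(theta), 0)
  tangent <- c(-sin(theta), cos(theta), 0)
  list(r = radial, t = tangent, a = c(0, 0, 1))
}

#' Generate an idealized collagen triple helix
#'
#' Three chains wound about the z axis with a (Gly-Pro-Hyp)n repeat. C-alpha
#' atoms sit exactly on the parameterized helix, so the glycine C-alpha axial
#' spacing is exactly `3 * rise` by construction (2.86 Angstrom per residue,
#' i.e. 8.58 Angstrom per triplet, with the canonical default). Backbone N,
#' C and O atoms are placed at fixed offsets in the local helix frame.
#'
#' @param n_res Residues per chain (default 30).
#' @param rise Axial rise per residue in Angstrom (default 2.86).
#' @param twist Helical twist per residue in degrees (default -104.9,
#'   left-handed polyproline-II-like).
#' @param radius Supercoil radius in Angstrom (default 1.5).
#' @param phases Chain phase offsets in degrees.
#' @param stagger Inter-chain axial stagger in residues (default 1).
#' @return Atom tibble (chains A, B, C) with attribute `"params"`.
#' @export
make_triple_helix <- function(n_res = 30, rise = 2.86, twist = -104.9,
                              radius = 1.5, phases = c(0, 120, 240),
                              stagger = 1) {
  stopifnot(rise > 0, n_res >= 9, length(phases) == 3)
  repeat_res <- c("GLY", "PRO", "HYP")
  rows <- list()
  for (ci in 1:3) {
    ch <- c("A", "B", "C")[ci]
    z0 <- (ci - 1) * stagger * rise
    for (i in seq_len(n_res)) {
      theta <- deg2rad(phases[ci] + (i - 1) * twist)
      f <- helix_frame(theta)
      ca <- radius * f$r + c(0, 0, z0 + (i - 1) * rise)
      n <- ca + (-0.50 * f$r - 1.20 * f$t - 0.60 * f$a)
      cc <- ca + (-0.50 * f$r + 1.20 * f$t + 0.60 * f$a)
      o <- cc + 1.23 * (-0.80 * f$r + 0.35 * f$t - 0.49 * f$a)
      resn <- repeat_res[(i - 1) %% 3 + 1]
      rows[[length(rows) + 1L]] <- new_atom_tbl(
        serial = 0L, atom = c("N", "CA", "C", "O"),
        resname = resn, chain = ch, resid = i,
        x = c(n[1], ca[1], cc[1], o[1]), y = c(n[2], ca[2], cc[2], o[2]),
        z = c(n[3], ca[3], cc[3], o[3]))
    }
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$vdw <- vdw_radius(atoms$element)
  attr(atoms, "params") <- list(n_res = n_res, rise = rise, twist = twist,
                                radius = radius, stagger = stagger)
  atoms
}

#' Generate a synthetic triclinic fibril template (PDB text)
#'
#' A single coarse triple helix placed in a collagen-like triclinic cell
#' whose c vector is tilted so that symmetry expansion staggers copies by the
#' designed D-period along z while displacing them laterally by one pitch.
#' The molecule spans `k` periods plus one overlap
#' (`length = k * period + overlap`), and carries four crosslink-capable
#' residues: one at each telopeptide end and two helical partner residues
#' placed so that expansion brings telopeptide/helix pairs of neighboring
#' copies within crosslinking distance (2.5 Angstrom). Crosslink z positions
#' therefore fall on two bands per period separated by the designed
#' overlap/gap distances. This is a documented synthetic stand-in for a real
#' collagen template; the cell is not taken from any experimental structure.
#'
#' @param lateral_pitch Lateral cell pitch a = b in Angstrom (default 15).
#' @param period_nm Designed axial D-period in nm (default 67).
#' @param overlap_nm Designed overlap-band offset in nm (default 27; the gap
#'   is `period_nm - overlap_nm`).
#' @param length_nm Molecule length in nm; must equal
#'   `k * period_nm + overlap_nm` for an integer `k >= 1` (default 295,
#'   i.e. k = 4).
#' @param bead_nm Axial spacing of the coarse C-alpha beads in nm. The
#'   default divides the period exactly (`period_nm / 39`, about two
#'   triplets), so axially staggered copies sharing a lattice column have
#'   coinciding beads and register the steric clash a continuous molecule
#'   would.
#' @param crosslink Crosslink type for the site residues (a divalent type
#'   from the registry; default HLKNL).
#' @return PDB text (character vector of lines) with a CRYST1 record.
#' @export
make_template <- function(lateral_pitch = 15, period_nm = 67,
                          overlap_nm = 27, length_nm = 295,
                          bead_nm = period_nm / 39, crosslink = "HLKNL") {
  stopifnot(overlap_nm > 0, overlap_nm < period_nm)
  k <- (length_nm - overlap_nm) / period_nm
  if (abs(k - round(k)) > 1e-6 || round(k) < 1) {
    stop("molecule length inconsistent with c-axis: need length = ",
         "k * period + overlap for integer k >= 1", call. = FALSE)
  }
  k <- round(k)
  registry <- crosslink_registry()
  if (!crosslink %in% names(registry) ||
      registry[[crosslink]]$valence != "divalent") {
    stop("crosslink must name a divalent registry type", call. = FALSE)
  }
  res_codes <- registry[[crosslink]]$residues
  # Pick the cell on the PDB fixed-column grid (angles 2 decimals, lengths 3)
  # so the written CRYST1 reproduces the designed geometry essentially
  # exactly; the realized period czz then deviates from the nominal target by
  # well under 1%.
  beta <- round(acos(lateral_pitch / sqrt(lateral_pitch^2 +
                                            (period_nm * 10)^2)) * 180 / pi, 2)
  c_len <- round(lateral_pitch / cos(deg2rad(beta)), 3)
  cxz <- c_len * cos(deg2rad(beta))
  czz <- sqrt(c_len^2 - cxz^2)
  cell <- unit_cell(lateral_pitch, lateral_pitch, c_len,
                    alpha = 90, beta = beta, gamma = 90, space_group = "P 1")
  L <- k * czz + overlap_nm * 10
  # snap the bead spacing to an exact divisor of the realized period so that
  # period-staggered copies in the same lattice column have coinciding beads
  zb <- seq(0, L, by = czz / max(1, round(czz / (bead_nm * 10))))
  rows <- list()
  for (ci in 1:3) {
    ch <- c("A", "B", "C")[ci]
    theta <- deg2rad(c(0, 120, 240)[ci])
    rows[[ci]] <- new_atom_tbl(
      serial = 0L, atom = "CA", resname = "GLY", chain = ch,
      resid = seq_along(zb),
      x = 1.5 * cos(theta), y = 1.5 * sin(theta), z = zb)
  }
  x_arm <- lateral_pitch - 2.5
  ov <- overlap_nm * 10
  n_bead <- length(zb)
  # one telopeptide arm residue at each chain end plus two helical partner
  # residues one overlap in from the opposite end: expansion brings each
  # telopeptide arm within 2.5 A of the helical partner of the copy
  # staggered by one pitch laterally and k periods axially, so crosslink z
  # coordinates fall on the designed overlap/gap bands
  sites <- new_atom_tbl(
    serial = 0L, atom = "NZ",
    resname = c(res_codes[1], res_codes[2], res_codes[2], res_codes[1]),
    chain = "A", resid = n_bead + 1:4,
    x = c(-x_arm, 0, 0, x_arm), y = 0,
    z = c(0, ov, L - ov, L), type = "HETATM")
  atoms <- dplyr::bind_rows(c(rows, list(sites)))
  atoms$serial <- seq_len(nrow(atoms))
  write_pdb(atoms, path = NULL, cell = cell)
}

arm_sites <- function(valence, res_codes, pitch, z_t) {
  # crosslink arm residues at one terminus level; contacts close at
  # 2.5 Angstrom between x-neighbor copies one pitch apart
  x_in <- pitch / 2 - 1.25
  if (valence == "divalent") {
    tibble::tibble(resname = c(res_codes[1], res_codes[2]),
                   x = c(-x_in, x_in), y = 0, z = z_t,
                   side = c("left", "right"))
  } else {
    tibble::tibble(resname = c(res_codes[3], res_codes[1], res_codes[2]),
                   x = c(-x_in, x_in, x_in), y = c(0, 0, 1.5), z = z_t,
                   side = c("left", "right", "right"))
  }
}

#' Generate a pre-assembled staggered fibril system
#'
#' Builds a [fibril_system()] directly on a Bravais lattice, with fully
#' specified crosslink units, so crosslink and analysis operations are
#' testable without running symmetry expansion.
#'
#' Arrangements:
#' * `"row"` — `n` molecules along nx; crosslink arms at both telopeptide
#'   levels close with the x-neighbors, so every molecule in a row of >= 2 is
#'   crosslinked at both ends.
#' * `"grid"` — a `dims = c(lx, ly, lz)` block (minus `vacancies`), arms as
#'   in `"row"`; the standard input for layer-optimization tests.
#' * `"bands"` — `n` molecules stacked along nz with one crosslink residue at
#'   each of the two designed band positions (overlap offset within the
#'   period); no inter-molecular contacts. This is the designed-band fixture
#'   for D-band recovery: sites fall at z = 0, 27, 67, 94, ... nm by default.
#'
#' @param n Number of molecules (row/bands; default 5).
#' @param arrangement `"row"`, `"grid"` or `"bands"`.
#' @param dims Integer 3-vector of grid dimensions (grid only).
#' @param vacancies Data frame of lattice points (`nx`, `ny`, `nz`) to leave
#'   unoccupied (grid only).
#' @param type Crosslink type from the registry (default `"HLKNL"`; a
#'   trivalent type such as `"PYD"` builds three-membered junction units).
#' @param ends Which telopeptide levels carry arms: `"both"` (default) or
#'   `"N"`.
#' @param boundary_arms Keep arms that face no neighbor (default `TRUE` for
#'   divalent types, where dangling arms form no unit; forced `FALSE` for
#'   trivalent types so every unit is complete).
#' @param pitch Lateral lattice pitch in Angstrom (default 15 = 1.5 nm).
#' @param period_nm,overlap_nm Designed period and overlap (bands only).
#' @param mix,seed Optional class mix applied via [assign_mix()].
#' @return A [fibril_system()].
#' @export
make_fibril <- function(n = 5, arrangement = c("row", "grid", "bands"),
                        dims = c(3, 3, 3), vacancies = NULL, type = "HLKNL",
                        ends = c("both", "N"), boundary_arms = NULL,
                        pitch = 15, period_nm = 67, overlap_nm = 27,
                        mix = NULL, seed = 1L) {
  arrangement <- match.arg(arrangement)
  ends <- match.arg(ends)
  registry <- crosslink_registry()
  if (!type %in% names(registry)) stop("unknown crosslink type: ", type,
                                       call. = FALSE)
  tp <- registry[[type]]
  if (is.null(boundary_arms)) boundary_arms <- tp$valence == "divalent"
  if (tp$valence == "trivalent") boundary_arms <- FALSE
  mol_len <- if (arrangement == "bands") overlap_nm * 10 else 280
  c_axis <- if (arrangement == "bands") period_nm * 10 else 300
  cell <- unit_cell(pitch, pitch, c_axis)
  pts <- switch(arrangement,
    row = tibble::tibble(nx = seq_len(n) - 1L, ny = 0L, nz = 0L),
    bands = tibble::tibble(nx = 0L, ny = 0L, nz = seq_len(n) - 1L),
    grid = {
      g <- tidyr::expand_grid(nx = 0:(dims[1] - 1), ny = 0:(dims[2] - 1),
                              nz = 0:(dims[3] - 1))
      if (!is.null(vacancies)) {
        g <- dplyr::anti_join(g, tibble::as_tibble(vacancies),
                              by = c("nx", "ny", "nz"))
      }
      g
    })
  stopifnot(nrow(pts) >= 1)
  C <- om_matrix(orientation_matrix(cell))
  # base molecule: coarse triple-helix beads along z
  zb <- seq(0, mol_len, by = 17.16)
  beads <- dplyr::bind_rows(lapply(1:3, function(ci) {
    theta <- deg2rad(c(0, 120, 240)[ci])
    new_atom_tbl(serial = 0L, atom = "CA", resname = "GLY",
                 chain = c("A", "B", "C")[ci], resid = seq_along(zb),
                 x = 1.5 * cos(theta), y = 1.5 * sin(theta), z = zb)
  }))
  n_bead <- length(zb)
  arms_for <- function(has_left, has_right) {
    if (arrangement == "bands") {
      s <- tibble::tibble(resname = tp$residues[c(1, 2)],
                          x = 0, y = 0, z = c(0, mol_len), side = "none")
    } else {
      levels <- if (ends == "both") c(0, mol_len) else 0
      s <- dplyr::bind_rows(lapply(levels, function(zt) {
        arm_sites(tp$valence, tp$residues, pitch, zt)
      }))
      if (!boundary_arms) {
        drop <- (!has_left & s$side == "left") | (!has_right & s$side == "right")
        s <- s[!drop, ]
      }
    }
    s
  }
  mols <- vector("list", nrow(pts))
  occ <- paste(pts$nx, pts$ny, pts$nz)
  for (i in seq_len(nrow(pts))) {
    p <- as.integer(unlist(pts[i, c("nx", "ny", "nz")]))
    t <- as.numeric(C %*% p)
    arm_tbl <- arms_for(paste(p[1] - 1, p[2], p[3]) %in% occ,
                        paste(p[1] + 1, p[2], p[3]) %in% occ)
    site_atoms <- if (nrow(arm_tbl) > 0) {
      new_atom_tbl(serial = 0L, atom = "NZ", resname = arm_tbl$resname,
                   chain = "A", resid = n_bead + seq_len(nrow(arm_tbl)),
                   x = arm_tbl$x, y = arm_tbl$y, z = arm_tbl$z,
                   type = "HETATM")
    } else NULL
    atoms <- dplyr::bind_rows(beads, site_atoms)
    atoms$serial <- seq_len(nrow(atoms))
    atoms <- apply_xform(atoms, xform(t = t, lattice = p))
    atoms$vdw <- vdw_radius(atoms$element)
    sites <- detect_sites(atoms, registry)
    mols[[i]] <- new_molecule(i, atoms, transform = xform(t = t, lattice = p),
                              lattice = p, sites = sites)
  }
  system <- fibril_system(mols, cell, seed = seed)
  if (!is.null(mix)) system <- assign_mix(system, mix, seed = seed)
  system
}

#' Build a system of single-point molecules
#'
#' Places one single-atom molecule at each given Cartesian position or
#' Bravais lattice point — a minimal fixture for the spacing, radius and
#' density metrics.
#'
#' @param xyz Numeric n x 3 matrix (or data frame) of Cartesian positions in
#'   Angstrom; or `NULL` when `lattice` is given.
#' @param lattice Data frame of integer lattice points (`nx`, `ny`, `nz`).
#' @param cell [unit_cell()] used to map lattice points (default 15 Angstrom
#'   cubic-ish collagen pitch cell).
#' @return A [fibril_system()].
#' @export
make_point_fibril <- function(xyz = NULL, lattice = NULL,
                              cell = unit_cell(15, 15, 300)) {
  stopifnot(xor(is.null(xyz), is.null(lattice)))
  if (!is.null(lattice)) {
    lattice <- tibble::as_tibble(lattice)
    xyz <- frac_to_cart(as.matrix(lattice[, c("nx", "ny", "nz")]), cell)
  } else {
    xyz <- as.matrix(as.data.frame(xyz))
    lattice <- tibble::tibble(nx = 0L, ny = 0L, nz = 0L)[rep(1, nrow(xyz)), ]
  }
  mols <- lapply(seq_len(nrow(xyz)), function(i) {
    atoms <- new_atom_tbl(serial = 1L, atom = "CA", resname = "GLY",
                          chain = "A", resid = 1L,
                          x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3])
    atoms$vdw <- vdw_radius(atoms$element)
    new_molecule(i, atoms,
                 transform = xform(t = as.numeric(xyz[i, ]),
                                   lattice = as.integer(unlist(lattice[i, ]))),
                 lattice = as.integer(unlist(lattice[i, ])))
  })
  fibril_system(mols, cell)
}
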