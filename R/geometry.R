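# Internal-coordinate atom placement (NeRF) and idealized side-chain builder.
# Used for lysine replacement of removed crosslinks and for threading
# substitutions. Geometry is idealized (fixed bonds/angles, trans dihedrals,
# +-120 degrees at branches); ring closure is not enforced for cyclic side
# chains, and no rotamer or energy optimization is performed.

place_atom <- function(a, b, c, bond, angle, dihedral) {
  # position d such that |cd| = bond, angle(b,c,d) = angle, dih(a,b,c,d) = dihedral
  ang <- deg2rad(angle); dih <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) {
    # colinear frame: pick any perpendicular
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- pracma_cross(ref, bc)
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Side-chain heavy-atom topology: for each residue, rows of
# (atom, parents a-b-c, bond length, angle, dihedral). Parents reference
# previously placed atoms by name (N, CA, C always available).
side_chain_topology <- function(resname) {
  L <- function(...) {
    m <- matrix(c(...), ncol = 6, byrow = TRUE)
    data.frame(atom = m[, 1], a = m[, 2], b = m[, 3], c = m[, 4],
               bond = as.numeric(m[, 5]), angle = 111,
               dihedral = as.numeric(m[, 6]), stringsAsFactors = FALSE)
  }
  cb <- c("CB", "N", "C", "CA", "1.53", "122.5")  # branch off the backbone frame
  chains <- list(
    GLY = NULL,
    ALA = L(cb),
    SER = L(cb, "OG", "N", "CA", "CB", "1.42", "180"),
    CYS = L(cb, "SG", "N", "CA", "CB", "1.81", "180"),
    THR = L(cb, "OG1", "N", "CA", "CB", "1.42", "180",
            "CG2", "N", "CA", "CB", "1.53", "-60"),
    VAL = L(cb, "CG1", "N", "CA", "CB", "1.53", "180",
            "CG2", "N", "CA", "CB", "1.53", "-60"),
    LEU = L(cb, "CG", "N", "CA", "CB", "1.53", "180",
            "CD1", "CA", "CB", "CG", "1.53", "180",
            "CD2", "CA", "CB", "CG", "1.53", "-60"),
    ILE = L(cb, "CG1", "N", "CA", "CB", "1.53", "180",
            "CG2", "N", "CA", "CB", "1.53", "-60",
            "CD1", "CA", "CB", "CG1", "1.53", "180"),
    MET = L(cb, "CG", "N", "CA", "CB", "1.53", "180",
            "SD", "CA", "CB", "CG", "1.81", "180",
            "CE", "CB", "CG", "SD", "1.79", "180"),
    PRO = L(cb, "CG", "N", "CA", "CB", "1.50", "30",
            "CD", "CA", "CB", "CG", "1.50", "-35"),
    HYP = L(cb, "CG", "N", "CA", "CB", "1.50", "30",
            "CD", "CA", "CB", "CG", "1.50", "-35",
            "OD1", "CB", "CG", "CD", "1.42", "120"),
    PHE = L(cb, "CG", "N", "CA", "CB", "1.51", "180",
            "CD1", "CA", "CB", "CG", "1.39", "90",
            "CD2", "CA", "CB", "CG", "1.39", "-90",
            "CE1", "CB", "CG", "CD1", "1.39", "180",
            "CE2", "CB", "CG", "CD2", "1.39", "180",
            "CZ", "CG", "CD1", "CE1", "1.39", "0"),
    TYR = L(cb, "CG", "N", "CA", "CB", "1.51", "180",
            "CD1", "CA", "CB", "CG", "1.39", "90",
            "CD2", "CA", "CB", "CG", "1.39", "-90",
            "CE1", "CB", "CG", "CD1", "1.39", "180",
            "CE2", "CB", "CG", "CD2", "1.39", "180",
            "CZ", "CG", "CD1", "CE1", "1.39", "0",
            "OH", "CD1", "CE1", "CZ", "1.38", "180"),
    TRP = L(cb, "CG", "N", "CA", "CB", "1.50", "180",
            "CD1", "CA", "CB", "CG", "1.37", "90",
            "CD2", "CA", "CB", "CG", "1.43", "-90",
            "NE1", "CB", "CG", "CD1", "1.38", "180",
            "CE2", "CB", "CG", "CD2", "1.40", "180",
            "CE3", "CG", "CD2", "CE2", "1.40", "180",
            "CZ2", "CD2", "CE2", "NE1", "1.40", "180",
            "CZ3", "CD2", "CE3", "CZ2", "1.39", "0",
            "CH2", "CE3", "CZ3", "CZ2", "1.39", "0"),
    ASP = L(cb, "CG", "N", "CA", "CB", "1.52", "180",
            "OD1", "CA", "CB", "CG", "1.25", "120",
            "OD2", "CA", "CB", "CG", "1.25", "-60"),
    GLU = L(cb, "CG", "N", "CA", "CB", "1.53", "180",
            "CD", "CA", "CB", "CG", "1.52", "180",
            "OE1", "CB", "CG", "CD", "1.25", "120",
            "OE2", "CB", "CG", "CD", "1.25", "-60"),
    ASN = L(cb, "CG", "N", "CA", "CB", "1.52", "180",
            "OD1", "CA", "CB", "CG", "1.23", "120",
            "ND2", "CA", "CB", "CG", "1.33", "-60"),
    GLN = L(cb, "CG", "N", "CA", "CB", "1.53", "180",
            "CD", "CA", "CB", "CG", "1.52", "180",
            "OE1", "CB", "CG", "CD", "1.23", "120",
            "NE2", "CB", "CG", "CD", "1.33", "-60"),
    LYS = L(cb, "CG", "N", "CA", "CB", "1.53", "180",
            "CD", "CA", "CB", "CG", "1.53", "180",
            "CE", "CB", "CG", "CD", "1.53", "180",
            "NZ", "CG", "CD", "CE", "1.49", "180"),
    ARG = L(cb, "CG", "N", "CA", "CB", "1.53", "180",
            "CD", "CA", "CB", "CG", "1.53", "180",
            "NE", "CB", "CG", "CD", "1.46", "180",
            "CZ", "CG", "CD", "NE", "1.33", "180",
            "NH1", "CD", "NE", "CZ", "1.33", "120",
            "NH2", "CD", "NE", "CZ", "1.33", "-60"),
    HIS = L(cb, "CG", "N", "CA", "CB", "1.50", "180",
            "ND1", "CA", "CB", "CG", "1.38", "90",
            "CD2", "CA", "CB", "CG", "1.36", "-90",
            "CE1", "CB", "CG", "ND1", "1.32", "180",
            "NE2", "CB", "CG", "CD2", "1.37", "180")
  )
  chains[[toupper(resname)]]
}

#' Heavy side-chain atoms of a residue type
#' @param resname Three-letter residue code.
#' @return Character vector of side-chain heavy-atom names (empty for GLY).
#' @keywords internal
side_chain_atoms <- function(resname) {
  topo <- side_chain_topology(resname)
  if (is.null(topo)) character() else topo$atom
}

# Build idealized side-chain coordinates for `resname` anchored on backbone
# positions (named list with N, CA, C as 3-vectors). Returns a tibble with
# atom, x, y, z (heavy atoms only), or NULL for glycine/unknown residues.
build_side_chain <- function(resname, backbone) {
  topo <- side_chain_topology(resname)
  if (is.null(topo)) return(NULL)
  pos <- backbone
  for (i in seq_len(nrow(topo))) {
    row <- topo[i, ]
    pos[[row$atom]] <- place_atom(pos[[row$a]], pos[[row$b]], pos[[row$c]],
                                  row$bond, row$angle, row$dihedral)
  }
  built <- topo$atom
  tibble::tibble(atom = built,
                 x = vapply(built, function(a) pos[[a]][1], numeric(1)),
                 y = vapply(built, function(a) pos[[a]][2], numeric(1)),
                 z = vapply(built, function(a) pos[[a]][3], numeric(1)))
}

# Replace one residue's side chain (and name) in an atom tibble, preserving
# backbone atoms N, CA, C, O. Residues lacking a complete N/CA/C backbone are
# renamed only, with coordinates untouched.
mutate_residue <- function(atoms, chain, resid, new_resname) {
  sel <- atoms$chain == chain & atoms$resid == resid
  if (!any(sel)) stop("residue ", chain, ":", resid, " not found", call. = FALSE)
  res <- atoms[sel, ]
  bb_names <- c("N", "CA", "C", "O")
  have <- bb_names %in% res$atom
  atoms$resname[sel] <- new_resname
  if (!all(have[1:3])) {
    return(atoms)  # no backbone anchor: rename in place
  }
  bb <- lapply(c("N", "CA", "C"), function(a) {
    v <- res[res$atom == a, ][1, ]
    c(v$x, v$y, v$z)
  })
  names(bb) <- c("N", "CA", "C")
  side <- build_side_chain(new_resname, bb)
  keep_atoms <- atoms[sel & atoms$atom %in% bb_names, ]
  if (!is.null(side)) {
    tmpl <- keep_atoms[rep(1, nrow(side)), ]
    tmpl$atom <- side$atom
    tmpl$x <- side$x; tmpl$y <- side$y; tmpl$z <- side$z
    tmpl$element <- guess_element(side$atom)
    if ("vdw" %in% names(tmpl)) tmpl$vdw <- vdw_radius(tmpl$element)
    keep_atoms <- dplyr::bind_rows(keep_atoms, tmpl)
  }
  keep_atoms$resname <- new_resname
  out <- dplyr::bind_rows(atoms[!sel, ], keep_atoms)
  out <- out[order(match(paste(out$chain, out$resid), unique(paste(atoms$chain, atoms$resid))),
                   method = "radix"), ]
  out$serial <- seq_len(nrow(out))
  out
}
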