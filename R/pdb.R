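#' Van der Waals radii
#'
#' Built-in element to radius map (Bondi radii, Angstrom) used by the steric
#' clash filter. Unknown elements default to 1.7 Angstrom.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii (Angstrom).
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  r <- tab[toupper(trimws(element))]
  r[is.na(r)] <- 1.70
  unname(r)
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(nm, 1, 1)
  el[grepl("^(CL|BR|SE)", nm)] <- substr(nm[grepl("^(CL|BR|SE)", nm)], 1, 2)
  el[grepl("^[0-9]", el)] <- substr(sub("^[0-9]+", "", nm[grepl("^[0-9]", el)]), 1, 1)
  el
}

new_atom_tbl <- function(serial, atom, resname, chain, resid, x, y, z,
                         element = NULL, segid = "", type = "ATOM") {
  element <- if (is.null(element)) guess_element(atom) else element
  tibble::tibble(
    serial = as.integer(serial), atom = as.character(atom),
    resname = as.character(resname), chain = as.character(chain),
    resid = as.integer(resid),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    element = as.character(element), segid = as.character(segid),
    type = as.character(type)
  )
}

parse_cryst1 <- function(lines) {
  cl <- lines[startsWith(lines, "CRYST1")]
  if (length(cl) == 0) return(NULL)
  l <- cl[1]
  unit_cell(
    a = as.numeric(substr(l, 7, 15)),
    b = as.numeric(substr(l, 16, 24)),
    c = as.numeric(substr(l, 25, 33)),
    alpha = as.numeric(substr(l, 34, 40)),
    beta = as.numeric(substr(l, 41, 47)),
    gamma = as.numeric(substr(l, 48, 54)),
    space_group = trimws(substr(l, 56, 66))
  )
}

format_cryst1 <- function(cell) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
          cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
          cell$space_group, 1L)
}

# bio3d widens the serial field for >99999 atoms, shifting later columns.
# Realign such lines so fixed-column parsing stays valid.
realign_wide_serials <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  wide <- rec & !grepl("^.{6}[ 0-9]{5}[^0-9]", lines) &
    grepl("^.{6} *[0-9]{6,}", lines)
  if (!any(wide)) return(lines)
  fix <- function(l) {
    m <- regexec("^(ATOM  |HETATM)( *)([0-9]{6,})(.*)$", l)[[1]]
    if (m[1] == -1) return(l)
    parts <- regmatches(l, list(m))[[1]]
    paste0(parts[2], "*****", parts[5])
  }
  lines[wide] <- vapply(lines[wide], fix, character(1), USE.NAMES = FALSE)
  lines
}

#' Read a PDB structure into an atom tibble
#'
#' Parses ATOM/HETATM records (via bio3d) and the CRYST1 record carrying the
#' unit-cell parameters and space group. Coordinates are in Angstrom.
#'
#' @param x Path to a PDB file, or PDB text (a string containing newlines, or
#'   a character vector of lines).
#' @param require_cell If `TRUE`, a missing CRYST1 record is an error
#'   ("no crystallographic information"); otherwise the cell is `NULL`.
#' @return A tibble of atoms (columns `serial`, `atom`, `resname`, `chain`,
#'   `resid`, `x`, `y`, `z`, `element`, `segid`, `type`) with the parsed
#'   [unit_cell()] (or `NULL`) stored in attribute `"cell"`.
#' @seealso [write_pdb()], [parse_template()]
#' @export
read_pdb <- function(x, require_cell = FALSE) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]] else x
  }
  cell <- parse_cryst1(lines)
  if (require_cell && is.null(cell)) {
    stop("no crystallographic information (missing CRYST1 record)", call. = FALSE)
  }
  lines <- realign_wide_serials(lines)
  if (!any(grepl("^(ATOM|HETATM)", lines))) stop("empty structure", call. = FALSE)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  a <- pdb$atom
  serial <- suppressWarnings(as.integer(a$eleno))
  if (anyNA(serial)) serial <- seq_len(nrow(a))
  chain <- a$chain; chain[is.na(chain)] <- " "
  segid <- a$segid; segid[is.na(segid)] <- ""
  elesy <- a$elesy
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- guess_element(a$elety[miss])
  atoms <- new_atom_tbl(serial, a$elety, a$resid, chain, a$resno,
                        a$x, a$y, a$z, element = elesy, segid = segid,
                        type = a$type)
  attr(atoms, "cell") <- cell
  atoms
}

#' Write an atom tibble to PDB
#'
#' Writes ATOM/HETATM records through bio3d, prepending a CRYST1 record when a
#' cell is supplied. Structures beyond 99,999 atoms are written in a
#' wide-serial dialect (serial field widened) with a warning.
#'
#' @param atoms Atom tibble as returned by [read_pdb()].
#' @param path Output file path. If `NULL`, the PDB text is returned as a
#'   character vector of lines.
#' @param cell Optional [unit_cell()]; defaults to `attr(atoms, "cell")`.
#' @return Invisibly, the lines written (or the lines themselves when
#'   `path = NULL`).
#' @export
write_pdb <- function(atoms, path = NULL, cell = attr(atoms, "cell")) {
  stopifnot(nrow(atoms) > 0)
  if (nrow(atoms) > 99999) {
    warning("more than 99,999 atoms: writing wide-serial PDB dialect")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  type <- if ("type" %in% names(atoms)) atoms$type else "ATOM"
  segid <- if ("segid" %in% names(atoms)) atoms$segid else ""
  bio3d::write.pdb(
    file = tf, type = type,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$resid, resid = atoms$resname, eleno = atoms$serial,
    elety = atoms$atom, chain = atoms$chain, segid = segid,
    elesy = atoms$element, print.segid = any(nzchar(segid))
  )
  lines <- readLines(tf, warn = FALSE)
  if (!is.null(cell)) lines <- c(format_cryst1(cell), lines)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a collagen triple-helix template
#'
#' Reads a template PDB that must carry crystallographic information (CRYST1)
#' and at least one atom; this is the entry point of the fibril pipeline.
#'
#' @inheritParams read_pdb
#' @return A list with `atoms` (tibble, with a `vdw` radius column added),
#'   `cell` (a [unit_cell()]), and `chains` (atom tibbles split by chain, in
#'   order of first appearance).
#' @export
parse_template <- function(x) {
  atoms <- read_pdb(x, require_cell = TRUE)
  atoms$vdw <- vdw_radius(atoms$element)
  list(atoms = atoms,
       cell = attr(atoms, "cell"),
       chains = split(atoms, factor(atoms$chain, levels = unique(atoms$chain))))
}
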