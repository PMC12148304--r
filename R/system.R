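#' Molecule and fibril-system containers
#'
#' A fibril system is an ensemble of triple-helix copies ("molecules"), each
#' carrying its atom table, Euclidean transform, Bravais lattice point and
#' crosslink sites, together with the shared unit cell and orientation matrix.
#'
#' @param id Integer model id (unique within a system).
#' @param atoms Atom tibble (see [read_pdb()]); a `vdw` column is added when
#'   absent.
#' @param transform The [xform()] that generated this copy.
#' @param lattice Integer 3-vector: the Bravais lattice point.
#' @param sites Crosslink-site tibble (one row per reactive atom; columns
#'   `site_id`, `type`, `terminus`, `chain`, `resid`, `resname`, `atom`,
#'   `x`, `y`, `z`), or `NULL` for none.
#' @return `new_molecule()` returns a `fibril_mol`; `fibril_system()` a
#'   `fibril_system`.
#' @export
new_molecule <- function(id, atoms, transform = xform_identity(),
                         lattice = c(0L, 0L, 0L), sites = NULL) {
  if (!"vdw" %in% names(atoms)) atoms$vdw <- vdw_radius(atoms$element)
  if (is.null(sites)) sites <- empty_sites()
  structure(list(id = as.integer(id), atoms = atoms, transform = transform,
                 lattice = as.integer(lattice), sites = sites),
            class = "fibril_mol")
}

empty_sites <- function() {
  tibble::tibble(site_id = character(), type = character(),
                 terminus = character(), chain = character(),
                 resid = integer(), resname = character(), atom = character(),
                 x = numeric(), y = numeric(), z = numeric())
}

#' @param molecules List of `fibril_mol` objects.
#' @param cell Shared [unit_cell()].
#' @param seed Optional RNG seed recorded as provenance.
#' @rdname new_molecule
#' @export
fibril_system <- function(molecules, cell, seed = NULL) {
  ids <- vapply(molecules, function(m) m$id, integer(1))
  if (anyDuplicated(ids)) stop("molecule ids must be unique", call. = FALSE)
  structure(list(molecules = molecules, cell = cell,
                 orientation = orientation_matrix(cell), seed = seed),
            class = "fibril_system")
}

#' @export
print.fibril_system <- function(x, ...) {
  ns <- sum(vapply(x$molecules, function(m) nrow(m$sites), integer(1)))
  cat(sprintf("<fibril_system> %d molecules, %d atoms, %d crosslink site atoms\n",
              length(x$molecules),
              sum(vapply(x$molecules, function(m) nrow(m$atoms), integer(1))),
              ns))
  print(x$cell)
  invisible(x)
}

#' Number of molecules in a system
#' @param system A [fibril_system()].
#' @return Integer count.
#' @export
n_molecules <- function(system) length(system$molecules)

#' Lattice points of a system
#' @param system A [fibril_system()].
#' @return Tibble with `mol_id`, `nx`, `ny`, `nz`.
#' @export
lattice_points <- function(system) {
  purrr::map_dfr(system$molecules, function(m) {
    tibble::tibble(mol_id = m$id, nx = m$lattice[1], ny = m$lattice[2],
                   nz = m$lattice[3])
  })
}

#' All crosslink site atoms of a system
#' @param system A [fibril_system()].
#' @return Tibble of site atoms with a leading `mol_id` column.
#' @export
system_sites <- function(system) {
  purrr::map_dfr(system$molecules, function(m) {
    if (nrow(m$sites) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(mol_id = rep(m$id, nrow(m$sites))), m$sites)
  })
}

#' All atoms of a system
#' @param system A [fibril_system()].
#' @return Atom tibble with a leading `mol_id` column.
#' @export
system_atoms <- function(system) {
  purrr::map_dfr(system$molecules, function(m) {
    dplyr::bind_cols(tibble::tibble(mol_id = rep(m$id, nrow(m$atoms))), m$atoms)
  })
}
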