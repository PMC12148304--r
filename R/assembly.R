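# Fibril assembly: merge symmetry copies into one structure, cut to length,
# cap termini. The fibril axis convention is the laboratory z axis (the
# projection of the unit-cell c direction under the orientation matrix).

chain_id_pool <- c(LETTERS, letters, 0:9)

#' Merge the molecules of a system into one structure
#'
#' Concatenates all transformed copies into a single atom table with
#' contiguous serials. PDB chain identifiers exhaust at 62 symbols, so each
#' molecule receives a unique segment identifier (`M001`, ...) and a cyclic
#' chain id; the sidecar manifest maps molecules to (segid, chains) so the
#' merge can be inverted.
#'
#' @param system A [fibril_system()].
#' @return An `assembly`: list with `atoms` (tibble), `manifest` (tibble:
#'   `mol_id`, `segid`, `chain_orig`, `chain_out`) and `cell`.
#' @export
merge_copies <- function(system) {
  stopifnot(n_molecules(system) >= 1)
  pool_n <- length(chain_id_pool)
  counter <- 0L
  pieces <- list(); manifest <- list()
  for (m in system$molecules) {
    a <- m$atoms
    segid <- sprintf("M%03d", m$id)
    chains <- unique(a$chain)
    new_ids <- chain_id_pool[(counter + seq_along(chains) - 1L) %% pool_n + 1L]
    counter <- counter + length(chains)
    a$segid <- segid
    a$chain <- new_ids[match(a$chain, chains)]
    pieces[[length(pieces) + 1L]] <- a
    manifest[[length(manifest) + 1L]] <- tibble::tibble(
      mol_id = m$id, segid = segid, chain_orig = chains, chain_out = new_ids)
  }
  atoms <- dplyr::bind_rows(pieces)
  atoms$serial <- seq_len(nrow(atoms))
  attr(atoms, "cell") <- system$cell
  structure(list(atoms = atoms, manifest = dplyr::bind_rows(manifest),
                 cell = system$cell),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d atoms, %d molecules\n", nrow(x$atoms),
              length(unique(x$manifest$mol_id))))
  invisible(x)
}

#' Split a merged assembly back into molecules
#'
#' Inverts [merge_copies()] using the manifest: atoms are regrouped by segid
#' and original chain identifiers are restored.
#'
#' @param assembly An `assembly` (atoms may have been re-read from PDB; they
#'   are matched by segid).
#' @param manifest Manifest tibble; defaults to the assembly's own.
#' @return Named list of atom tibbles, one per molecule id.
#' @export
split_molecules <- function(assembly, manifest = assembly$manifest) {
  atoms <- if (is.data.frame(assembly)) assembly else assembly$atoms
  lapply(split(manifest, manifest$mol_id), function(mf) {
    a <- atoms[atoms$segid == mf$segid[1], ]
    a$chain <- mf$chain_orig[match(a$chain, mf$chain_out)]
    a
  })
}

#' Cut a structure to a target fibril length
#'
#' Removes every residue whose C-alpha lies outside the axial window
#' `[z0, z0 + length]`; cuts happen only at residue boundaries, and any chain
#' fragment left with fewer than 3 residues is dropped entirely.
#'
#' @param assembly An `assembly` or atom tibble.
#' @param length_nm Target length in nm (positive; the pipeline supports up
#'   to 335 nm, a full triple-helix length).
#' @param z0 Window anchor in Angstrom; defaults to the minimal axial
#'   coordinate of the structure.
#' @return The trimmed object (same shape as the input).
#' @export
cut_to_length <- function(assembly, length_nm, z0 = NULL) {
  stopifnot(length_nm > 0)
  atoms <- if (is.data.frame(assembly)) assembly else assembly$atoms
  ca <- atoms[atoms$atom == "CA", ]
  if (is.null(z0)) z0 <- min(atoms$z)
  zmax <- z0 + length_nm * 10
  key <- function(d) paste(d$segid, d$chain, d$resid)
  keep_keys <- key(ca[ca$z >= z0 & ca$z <= zmax, ])
  k <- key(atoms)
  has_ca <- k %in% key(ca)
  # residues with a CA follow their CA; residues without one (crosslink arms,
  # caps) follow their own atom positions
  sel <- (has_ca & k %in% keep_keys) |
    (!has_ca & atoms$z >= z0 & atoms$z <= zmax)
  atoms2 <- atoms[sel, ]
  if (nrow(atoms2) == 0) stop("empty fibril", call. = FALSE)
  counts <- atoms2 |>
    dplyr::distinct(.data$segid, .data$chain, .data$resid) |>
    dplyr::count(.data$segid, .data$chain)
  ok <- counts[counts$n >= 3, c("segid", "chain")]
  atoms2 <- dplyr::semi_join(atoms2, ok, by = c("segid", "chain"))
  if (nrow(atoms2) == 0) stop("empty fibril", call. = FALSE)
  atoms2 <- atoms2[order(match(atoms2$segid, unique(atoms$segid)),
                         match(atoms2$chain, unique(atoms$chain)),
                         atoms2$resid), ]
  atoms2$serial <- seq_len(nrow(atoms2))
  attr(atoms2, "cell") <- attr(atoms, "cell")
  if (is.data.frame(assembly)) return(atoms2)
  assembly$atoms <- atoms2
  assembly
}

cap_atom_names <- list(
  ACE = c("CH3", "HH31", "HH32", "HH33", "C", "O"),
  NME = c("N", "H", "CH3", "HH31", "HH32", "HH33")
)

build_ace <- function(Npos, CApos, Cpos) {
  Cc <- place_atom(Cpos, CApos, Npos, 1.33, 120, 180)
  O <- place_atom(CApos, Npos, Cc, 1.23, 121, 0)
  CH3 <- place_atom(CApos, Npos, Cc, 1.51, 116, 180)
  H1 <- place_atom(Npos, Cc, CH3, 1.09, 109.5, 60)
  H2 <- place_atom(Npos, Cc, CH3, 1.09, 109.5, 180)
  H3 <- place_atom(Npos, Cc, CH3, 1.09, 109.5, -60)
  rbind(CH3 = CH3, HH31 = H1, HH32 = H2, HH33 = H3, C = Cc, O = O)
}

build_nme <- function(Npos, CApos, Cpos) {
  Nn <- place_atom(Npos, CApos, Cpos, 1.33, 116, 180)
  H <- place_atom(CApos, Cpos, Nn, 1.01, 119, 0)
  CH3 <- place_atom(CApos, Cpos, Nn, 1.45, 122, 180)
  H1 <- place_atom(Cpos, Nn, CH3, 1.09, 109.5, 60)
  H2 <- place_atom(Cpos, Nn, CH3, 1.09, 109.5, 180)
  H3 <- place_atom(Cpos, Nn, CH3, 1.09, 109.5, -60)
  rbind(N = Nn, H = H, CH3 = CH3, HH31 = H1, HH32 = H2, HH33 = H3)
}

#' Cap chain termini with neutral groups
#'
#' Adds an acetyl (ACE) residue before each chain N-terminus and an
#' N-methylamide (NME) residue after each C-terminus, at idealized amide
#' geometry, so cut fibrils carry no artificial terminal charges. Chains with
#' incomplete backbone at a terminus are flagged (attribute `"uncapped"`) and
#' left uncapped.
#'
#' @param assembly An `assembly` or atom tibble.
#' @return The capped object; each cap adds 6 atoms.
#' @export
cap_termini <- function(assembly) {
  atoms <- if (is.data.frame(assembly)) assembly else assembly$atoms
  out <- list(); flagged <- character()
  groups <- split(atoms, paste(atoms$segid, atoms$chain, sep = "\r"))
  for (g in groups) {
    g <- g[order(g$resid), ]
    resids <- unique(g$resid)
    first <- g[g$resid == resids[1], ]
    last <- g[g$resid == resids[length(resids)], ]
    get3 <- function(res) {
      if (!all(c("N", "CA", "C") %in% res$atom)) return(NULL)
      lapply(c("N", "CA", "C"), function(a) {
        v <- res[res$atom == a, ][1, ]
        c(v$x, v$y, v$z)
      })
    }
    bb1 <- get3(first); bb2 <- get3(last)
    mkcap <- function(coords, resname, resid, tmpl) {
      tb <- tmpl[rep(1, nrow(coords)), ]
      tb$atom <- rownames(coords)
      tb$resname <- resname
      tb$resid <- resid
      tb$x <- coords[, 1]; tb$y <- coords[, 2]; tb$z <- coords[, 3]
      tb$element <- guess_element(tb$atom)
      if ("vdw" %in% names(tb)) tb$vdw <- vdw_radius(tb$element)
      tb$type <- "ATOM"
      tb
    }
    capped <- g
    if (is.null(bb1) || is.null(bb2)) {
      flagged <- c(flagged, paste0(g$segid[1], ":", g$chain[1]))
    } else {
      ace <- mkcap(build_ace(bb1[[1]], bb1[[2]], bb1[[3]]), "ACE",
                   resids[1] - 1L, first[1, ])
      nme <- mkcap(build_nme(bb2[[1]], bb2[[2]], bb2[[3]]), "NME",
                   resids[length(resids)] + 1L, last[1, ])
      capped <- dplyr::bind_rows(ace, g, nme)
    }
    out[[length(out) + 1L]] <- capped
  }
  atoms2 <- dplyr::bind_rows(out)
  atoms2$serial <- seq_len(nrow(atoms2))
  attr(atoms2, "cell") <- attr(atoms, "cell")
  attr(atoms2, "uncapped") <- flagged
  if (is.data.frame(assembly)) return(atoms2)
  assembly$atoms <- atoms2
  attr(assembly, "uncapped") <- flagged
  assembly
}

#' Build a crosslinked fibril from a template
#'
#' The end-to-end pipeline: parse the template, expand symmetry copies within
#' the contact distance, filter clashes, optimize boundary layers on the
#' Bravais lattice, apply crosslink engineering (type mixing, random
#' replacement with lysine), merge, cut to length and cap termini.
#'
#' @param template Template PDB (text, path, or [parse_template()] output).
#' @param contact_distance Contact distance `d_c` in Angstrom.
#' @param length_nm Target fibril length in nm (<= 335, a full molecule).
#' @param delta Solution-space bound for [optimize_layers()]
#'   (default `c(0, 0, 2)`).
#' @param mix Optional named class weights for [assign_mix()].
#' @param replace_rate Crosslink removal rate for [remove_crosslinks()]
#'   (default 0).
#' @param seed Integer seed governing all randomized steps.
#' @param overlap_fraction Clash threshold.
#' @return A list with `assembly`, `system` (the optimized
#'   [fibril_system()]), and `reports` (optimization, mix, removal,
#'   connectivity).
#' @export
build_fibril <- function(template, contact_distance, length_nm,
                         delta = c(0, 0, 2), mix = NULL, replace_rate = 0,
                         seed = 1L, overlap_fraction = 0.6) {
  stopifnot(length_nm > 0, length_nm <= 335)
  system <- expand_template(template, contact_distance,
                            overlap_fraction = overlap_fraction)
  system <- optimize_layers(system, delta, seed = seed,
                            overlap_fraction = overlap_fraction)
  if (!is.null(mix)) system <- assign_mix(system, mix, seed = seed)
  if (replace_rate > 0) system <- remove_crosslinks(system, replace_rate,
                                                    seed = seed)
  asm <- merge_copies(system)
  asm <- cut_to_length(asm, length_nm)
  asm <- cap_termini(asm)
  list(assembly = asm, system = system,
       reports = list(optimization = attr(system, "opt_report"),
                      mix = attr(system, "mix_report"),
                      removal = attr(system, "removal_report"),
                      connectivity = connectivity_stats(system)))
}
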