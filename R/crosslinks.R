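#' Crosslink type registry
#'
#' Loads the versioned crosslink library (YAML) mapping each type name to its
#' valence, member residue codes and reactive side-chain atoms. Divalent types
#' join exactly two residues, trivalent types three; the file is validated on
#' load. Users can supply an extended copy of the bundled file to add their
#' own crosslink chemistries.
#'
#' @param path Path to a library YAML; defaults to the bundled file.
#' @return A named list of crosslink types (class `crosslink_registry`); each
#'   entry has `name`, `valence`, `residues`, `reactive_atoms`.
#' @export
crosslink_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crosslink_library.yml",
                        package = "fibrilforge", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  types <- purrr::imap(raw$types, function(tp, nm) {
    n_req <- switch(tp$valence, divalent = 2L, trivalent = 3L,
                    stop("crosslink type ", nm, ": valence must be divalent or trivalent",
                         call. = FALSE))
    if (length(tp$residues) != n_req) {
      stop("crosslink type ", nm, ": ", tp$valence, " types join exactly ",
           n_req, " residues", call. = FALSE)
    }
    missing_atoms <- setdiff(tp$residues, names(tp$reactive_atoms))
    if (length(missing_atoms) > 0) {
      stop("crosslink type ", nm, ": no reactive atoms for ",
           paste(missing_atoms, collapse = ", "), call. = FALSE)
    }
    list(name = nm, valence = tp$valence,
         residues = as.character(tp$residues),
         reactive_atoms = tp$reactive_atoms)
  })
  structure(types, class = "crosslink_registry",
            version = raw$version, path = path)
}

registry_residue_map <- function(registry) {
  purrr::map_dfr(registry, function(tp) {
    purrr::map_dfr(tp$residues, function(rn) {
      tibble::tibble(type = tp$name, valence = tp$valence, resname = rn,
                     atom = as.character(tp$reactive_atoms[[rn]]))
    })
  })
}

#' Detect crosslink sites in an atom table
#'
#' Scans for residues whose name matches a registry crosslink residue code and
#' collects their reactive atoms. The terminus annotation (N or C) is assigned
#' by axial position: site residues in the lower half of the molecule's z
#' extent belong to the N end.
#'
#' @param atoms Atom tibble.
#' @param registry A [crosslink_registry()].
#' @return Site tibble (one row per reactive atom): `site_id`, `type`,
#'   `terminus`, `chain`, `resid`, `resname`, `atom`, `x`, `y`, `z`.
#' @export
detect_sites <- function(atoms, registry = crosslink_registry()) {
  rmap <- registry_residue_map(registry) |>
    dplyr::rename(xl_type = "type")
  hits <- dplyr::inner_join(atoms, rmap, by = c("resname", "atom"))
  if (nrow(hits) == 0) return(empty_sites())
  zmid <- (min(atoms$z) + max(atoms$z)) / 2
  hits |>
    dplyr::mutate(site_id = paste0(.data$chain, .data$resid),
                  terminus = ifelse(.data$z < zmid, "N", "C"),
                  type = .data$xl_type) |>
    dplyr::select("site_id", "type", "terminus", "chain", "resid",
                  "resname", "atom", "x", "y", "z")
}

#' Crosslink site pairs within a cutoff
#'
#' Reports all pairs of crosslink sites from two molecules whose minimal
#' reactive-atom distance is below `cutoff`; symmetric in its arguments.
#'
#' @param mol_a,mol_b `fibril_mol` objects (see [new_molecule()]).
#' @param cutoff Contact cutoff in Angstrom (default 3.0, the noncovalent
#'   interaction distance used throughout the pipeline).
#' @return Tibble with `site_a`, `site_b`, `distance` (Angstrom).
#' @export
detect_links <- function(mol_a, mol_b, cutoff = 3.0) {
  sa <- mol_a$sites; sb <- mol_b$sites
  empty <- tibble::tibble(site_a = character(), site_b = character(),
                          distance = numeric())
  if (nrow(sa) == 0 || nrow(sb) == 0) return(empty)
  d <- sqrt(cross_dist2(as.matrix(sa[, c("x", "y", "z")]),
                        as.matrix(sb[, c("x", "y", "z")])))
  pairs <- tidyr::expand_grid(i = seq_len(nrow(sa)), j = seq_len(nrow(sb)))
  pairs$site_a <- sa$site_id[pairs$i]
  pairs$site_b <- sb$site_id[pairs$j]
  pairs$distance <- d[cbind(pairs$i, pairs$j)]
  pairs |>
    dplyr::group_by(.data$site_a, .data$site_b) |>
    dplyr::summarise(distance = min(.data$distance), .groups = "drop") |>
    dplyr::filter(.data$distance < cutoff)
}

#' Identify crosslink units in a system
#'
#' A crosslink unit is a maximal group of crosslink residues whose reactive
#' atoms are mutually connected at the contact cutoff (connected components of
#' the residue proximity graph). Unit type is inferred from the member residue
#' codes; valence from the member count (2 = divalent, 3 = trivalent).
#'
#' @param system A [fibril_system()].
#' @param cutoff Contact cutoff (Angstrom).
#' @return Tibble with one row per member residue: `unit`, `type`, `valence`,
#'   `n_members`, `mol_id`, `chain`, `resid`, `resname`.
#' @export
crosslink_units <- function(system, cutoff = 3.0) {
  s <- system_sites(system)
  empty <- tibble::tibble(unit = integer(), type = character(),
                          valence = character(), n_members = integer(),
                          mol_id = integer(), chain = character(),
                          resid = integer(), resname = character())
  if (nrow(s) == 0) return(empty)
  s$res_key <- paste(s$mol_id, s$chain, s$resid, sep = "|")
  keys <- unique(s$res_key)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  d <- sqrt(cross_dist2(xyz, xyz))
  close <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  edges <- unique(data.frame(
    from = match(s$res_key[close[, 1]], keys),
    to = match(s$res_key[close[, 2]], keys)))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seq_along(keys)))
  comp <- igraph::components(g)$membership
  members <- s |>
    dplyr::distinct(.data$res_key, .data$mol_id, .data$chain, .data$resid,
                    .data$resname) |>
    dplyr::mutate(unit = as.integer(comp[match(.data$res_key, keys)]))
  # isolated residues are reactive but unbonded: not units
  members <- members |>
    dplyr::group_by(.data$unit) |>
    dplyr::mutate(n_members = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_members >= 2)
  if (nrow(members) == 0) return(empty)
  rmap <- registry_residue_map(crosslink_registry()) |>
    dplyr::distinct(.data$type, .data$resname)
  unit_type <- members |>
    dplyr::left_join(rmap, by = "resname") |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(type = if (dplyr::n_distinct(.data$type) == 1)
      .data$type[1] else NA_character_, .groups = "drop")
  members |>
    dplyr::left_join(unit_type, by = "unit") |>
    dplyr::mutate(valence = dplyr::case_when(
      .data$n_members == 2 ~ "divalent",
      .data$n_members == 3 ~ "trivalent",
      TRUE ~ "other")) |>
    dplyr::select("unit", "type", "valence", "n_members", "mol_id",
                  "chain", "resid", "resname") |>
    dplyr::arrange(.data$unit, .data$mol_id, .data$chain, .data$resid)
}

parse_mix_class <- function(class, registry) {
  parts <- strsplit(class, "[-_]")[[1]]
  if (length(parts) != 2) {
    stop("class not in crosslink library: ", class, call. = FALSE)
  }
  alias <- function(p) {
    if (p %in% names(registry)) return(p)
    val <- c(div = "divalent", tri = "trivalent")[tolower(p)]
    if (!is.na(val)) {
      hit <- names(registry)[vapply(registry, function(tp) tp$valence == val,
                                    logical(1))]
      if (length(hit) > 0) return(hit[1])
    }
    stop("class not in crosslink library: ", class, call. = FALSE)
  }
  c(N = alias(parts[1]), C = alias(parts[2]))
}

#' Assign crosslink classes to molecules by ratio
#'
#' Randomly assigns each molecule a crosslink class — a pair of crosslink
#' types for its N- and C-terminal telopeptide regions, e.g. `"PYD-HLKNL"` or
#' the aliases `"div-tri"` — with the supplied probabilities, then relabels
#' each terminus's site residues to the chosen type's residue codes. The four
#' equal-ratio classes div-div, tri-div, div-tri, tri-tri reproduce the mixed
#' divalent/trivalent fibril setup.
#'
#' @param system A [fibril_system()].
#' @param mix Named numeric vector of class weights (normalized internally),
#'   e.g. `c("PYD-PYD" = 0.5, "HLKNL-HLKNL" = 0.5)`.
#' @param seed Integer seed; assignment is reproducible under it.
#' @param registry A [crosslink_registry()].
#' @return The system with per-molecule `class` fields and relabeled sites;
#'   realized class counts are in attribute `"mix_report"`.
#' @export
assign_mix <- function(system, mix, seed = 1L,
                       registry = crosslink_registry()) {
  if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
    stop("mix weights must be named by class", call. = FALSE)
  }
  if (any(mix < 0) || sum(mix) <= 0) {
    stop("mix weights must be non-negative and sum to > 0", call. = FALSE)
  }
  classes <- lapply(names(mix), parse_mix_class, registry = registry)
  names(classes) <- names(mix)
  prob <- mix / sum(mix)
  M <- n_molecules(system)
  assigned <- withr::with_seed(seed,
    sample(names(mix), M, replace = TRUE, prob = prob))
  system$molecules <- purrr::map2(system$molecules, assigned, function(m, cl) {
    m$class <- cl
    types <- classes[[cl]]
    for (term in c("N", "C")) {
      tp <- registry[[types[[term]]]]
      idx <- which(m$sites$terminus == term)
      if (length(idx) == 0) next
      res_keys <- unique(paste(m$sites$chain[idx], m$sites$resid[idx]))
      new_names <- rep(tp$residues, length.out = length(res_keys))
      for (k in seq_along(res_keys)) {
        sel <- idx[paste(m$sites$chain[idx], m$sites$resid[idx]) == res_keys[k]]
        m$sites$resname[sel] <- new_names[k]
        m$sites$type[sel] <- tp$name
        asel <- m$atoms$chain == m$sites$chain[sel[1]] &
          m$atoms$resid == m$sites$resid[sel[1]]
        m$atoms$resname[asel] <- new_names[k]
      }
    }
    m
  })
  counts <- as.integer(table(factor(assigned, levels = names(mix))))
  report <- tibble::tibble(class = names(mix), n = counts,
                           frequency = counts / M)
  attr(system, "mix_report") <- report
  system
}

#' Randomly replace crosslinks with lysine
#'
#' Removes crosslink units at a user-defined rate, mutating every member
#' residue of each selected unit to lysine (backbone preserved, side chain
#' rebuilt at idealized geometry). By default exactly `round(rate * K)` of the
#' `K` units are selected uniformly without replacement, so the remaining
#' crosslink fraction is `1 - rate` to within `1/K`.
#'
#' @param system A [fibril_system()].
#' @param rate Removal rate in \[0, 1\].
#' @param seed Integer seed.
#' @param mode `"exact"` (deterministic count, default) or `"bernoulli"`
#'   (independent per-unit removal with probability `rate`).
#' @param cutoff Contact cutoff used to identify units (Angstrom).
#' @return The modified system; attribute `"removal_report"` holds unit
#'   counts and the realized remaining fraction.
#' @export
remove_crosslinks <- function(system, rate, seed = 1L,
                              mode = c("exact", "bernoulli"), cutoff = 3.0) {
  mode <- match.arg(mode)
  if (!is.finite(rate) || rate < 0 || rate > 1) {
    stop("rate must lie in [0, 1]", call. = FALSE)
  }
  units <- crosslink_units(system, cutoff = cutoff)
  K <- length(unique(units$unit))
  if (K == 0 || rate == 0) {
    attr(system, "removal_report") <- tibble::tibble(
      n_units = K, removed = 0L, remaining = K,
      remaining_fraction = if (K > 0) 1 else NA_real_)
    return(system)
  }
  unit_ids <- sort(unique(units$unit))
  removed_ids <- withr::with_seed(seed, {
    if (mode == "exact") {
      n_rm <- round(rate * K)
      if (n_rm > 0) sample(unit_ids, n_rm) else integer()
    } else {
      unit_ids[stats::runif(K) < rate]
    }
  })
  victims <- units[units$unit %in% removed_ids, ]
  mol_idx <- match(victims$mol_id,
                   vapply(system$molecules, function(m) m$id, integer(1)))
  for (i in seq_len(nrow(victims))) {
    m <- system$molecules[[mol_idx[i]]]
    m$atoms <- mutate_residue(m$atoms, victims$chain[i], victims$resid[i], "LYS")
    drop <- m$sites$chain == victims$chain[i] & m$sites$resid == victims$resid[i]
    m$sites <- m$sites[!drop, ]
    system$molecules[[mol_idx[i]]] <- m
  }
  attr(system, "removal_report") <- tibble::tibble(
    n_units = K, removed = length(removed_ids),
    remaining = K - length(removed_ids),
    remaining_fraction = (K - length(removed_ids)) / K)
  system
}
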