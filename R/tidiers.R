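#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fibril system
#'
#' One row per molecule: id, lattice point, atom/site counts and class.
#'
#' @param x A [fibril_system()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fibril_system
#' @export
tidy.fibril_system <- function(x, ...) {
  purrr::map_dfr(x$molecules, function(m) {
    tibble::tibble(mol_id = m$id, nx = m$lattice[1], ny = m$lattice[2],
                   nz = m$lattice[3], n_atoms = nrow(m$atoms),
                   n_site_atoms = nrow(m$sites),
                   class = if (is.null(m$class)) NA_character_ else m$class)
  })
}

#' Glance at a fibril system
#'
#' @param x A [fibril_system()].
#' @param ... Unused.
#' @return A one-row tibble: molecule/atom/site counts and end-connectivity
#'   fractions.
#' @method glance fibril_system
#' @export
glance.fibril_system <- function(x, ...) {
  conn <- connectivity_stats(x)
  tibble::tibble(
    n_molecules = n_molecules(x),
    n_atoms = sum(vapply(x$molecules, function(m) nrow(m$atoms), integer(1))),
    n_site_atoms = sum(vapply(x$molecules, function(m) nrow(m$sites), integer(1))),
    both_ends = conn$fraction[conn$category == "both_ends"],
    one_end = conn$fraction[conn$category == "one_end"],
    unconnected = conn$fraction[conn$category == "unconnected"])
}

#' Tidy a D-band result
#'
#' @param x A `dband_result` from [dband_periodicity()].
#' @param ... Unused.
#' @return Tibble of adjacent-band distances with class and flanking centers.
#' @method tidy dband_result
#' @export
tidy.dband_result <- function(x, ...) {
  k <- length(x$centers)
  if (k < 2) return(tibble::tibble(center_lo = numeric(), center_hi = numeric(),
                                   distance = numeric(), class = character()))
  tibble::tibble(center_lo = x$centers[-k], center_hi = x$centers[-1],
                 distance = x$distances$distance, class = x$distances$class)
}

#' Glance at a D-band result
#'
#' @param x A `dband_result`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `overlap_nm`, `gap_nm`, `d_period_nm`.
#' @method glance dband_result
#' @export
glance.dband_result <- function(x, ...) {
  tibble::tibble(k = x$k, overlap_nm = x$overlap_nm, gap_nm = x$gap_nm,
                 d_period_nm = x$d_period_nm)
}

#' Tidy an alignment result
#'
#' @param x An `alignment_result` from [align_to_template()].
#' @param ... Unused.
#' @return Long tibble: `chain`, `position`, `template`, `target`, `helical`,
#'   `state`.
#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  purrr::imap_dfr(x$chains, function(a, nm) {
    dplyr::bind_cols(tibble::tibble(chain = rep(nm, nrow(a)),
                                    position = seq_len(nrow(a))), a)
  })
}

#' Glance at an alignment result
#'
#' @param x An `alignment_result`.
#' @param ... Unused.
#' @return One-row tibble with per-chain and overall percent identity.
#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) {
  tibble::tibble(identity_chain1 = x$identity[1],
                 identity_chain2 = x$identity[2],
                 identity_chain3 = x$identity[3],
                 overall_identity = x$overall_identity)
}
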