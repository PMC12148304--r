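# Gly-X-Y-aware sequence handling: template alignment with a frame-preserving
# constraint, backbone-preserving threading, and the axial-rise metric.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", O = "HYP")
AA1 <- stats::setNames(names(AA3), AA3)

aa_to1 <- function(res3) {
  out <- AA1[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_to3 <- function(res1) {
  out <- AA3[toupper(res1)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Triple-helix sequence
#'
#' Holds the three chain sequences of a collagen molecule (one-letter codes;
#' `O` denotes hydroxyproline) together with the declared triple-helical
#' region in which the Gly-X-Y frame must be preserved.
#'
#' @param chains Named list or character vector of three chain sequences.
#' @param helical_region Integer `c(start, end)` (1-based, inclusive) of the
#'   helical region, shared across chains; its length must be a positive
#'   multiple of 3. Defaults to the full chain length.
#' @return Object of class `triple_helix_sequence`.
#' @export
triple_helix_sequence <- function(chains, helical_region = NULL) {
  chains <- as.list(chains)
  if (length(chains) != 3) stop("exactly three chains required", call. = FALSE)
  if (is.null(names(chains)) || any(!nzchar(names(chains)))) {
    names(chains) <- c("A", "B", "C")
  }
  chains <- lapply(chains, function(s) toupper(gsub("[[:space:]]", "", s)))
  lens <- vapply(chains, nchar, integer(1))
  if (any(lens < 9)) stop("each chain must have at least 9 residues", call. = FALSE)
  if (is.null(helical_region)) helical_region <- c(1L, min(lens))
  hr <- as.integer(helical_region)
  if (hr[2] < hr[1] + 2) stop("helical region shorter than one triplet", call. = FALSE)
  structure(list(chains = chains, helical_region = hr),
            class = "triple_helix_sequence")
}

#' Validate the Gly-X-Y repeat
#'
#' Scans frame-aligned triplets of the declared helical region and reports
#' the fraction with glycine in first position, plus the violating triplets.
#'
#' @param sequence A chain sequence (one-letter string) or a
#'   [triple_helix_sequence()] (all chains are checked).
#' @param helical_region `c(start, end)`; required for plain strings, taken
#'   from the object otherwise.
#' @return For a single chain, a list (class `gxy_report`) with `n_triplets`,
#'   `compliance`, `violations` (triplet indices) and `first_violation`; for
#'   a triple helix, a named list of such reports.
#' @export
validate_gxy <- function(sequence, helical_region = NULL) {
  if (inherits(sequence, "triple_helix_sequence")) {
    return(lapply(sequence$chains, validate_gxy,
                  helical_region = sequence$helical_region))
  }
  s <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(s) == 0) stop("empty sequence", call. = FALSE)
  if (is.null(helical_region)) helical_region <- c(1L, nchar(s))
  hs <- helical_region[1]; he <- min(helical_region[2], nchar(s))
  n_trip <- (he - hs + 1) %/% 3
  if (n_trip < 1) stop("helical region shorter than one triplet", call. = FALSE)
  first_pos <- hs + 3 * (seq_len(n_trip) - 1)
  gly <- substring(s, first_pos, first_pos) == "G"
  violations <- which(!gly)
  structure(list(n_triplets = n_trip, compliance = mean(gly),
                 violations = violations,
                 first_violation = if (length(violations)) violations[1] else NA_integer_),
            class = "gxy_report")
}

#' @export
print.gxy_report <- function(x, ...) {
  cat(sprintf("<gxy_report> %d triplets, compliance %.3f", x$n_triplets,
              x$compliance))
  if (!is.na(x$first_violation)) {
    cat(", first violation at triplet", x$first_violation)
  }
  cat("\n")
  invisible(x)
}

# --- constrained global alignment -------------------------------------------

# Units: single residues in the telopeptides, whole triplets in the helical
# region. Deleting a helical unit removes exactly one triplet (frame kept);
# insertions between two helical units are forbidden.
template_units <- function(seq, hs, he) {
  n <- nchar(seq)
  res <- strsplit(seq, "")[[1]]
  units <- list(); helical <- logical()
  i <- 1L
  while (i <= n) {
    if (i >= hs && i + 2 <= he) {
      units[[length(units) + 1L]] <- res[i:(i + 2)]
      helical <- c(helical, TRUE)
      i <- i + 3L
    } else {
      units[[length(units) + 1L]] <- res[i]
      helical <- c(helical, i >= hs && i <= he)
      i <- i + 1L
    }
  }
  list(units = units, helical = helical)
}

align_chain <- function(tseq, qseq, hs, he, match = 2, mismatch = -1,
                        gap_open = 5, gap_extend = 1) {
  tu <- template_units(tseq, hs, he)
  units <- tu$units; helical <- tu$helical
  q <- strsplit(qseq, "")[[1]]
  nU <- length(units); nQ <- length(q)
  ulen <- lengths(units)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, nU + 1, nQ + 1)
  M[1, 1] <- 0
  ins_ok <- function(i) i == 0 || i == nU || !(helical[i] && helical[i + 1])
  gap_of <- function(L) gap_open + gap_extend * L
  # X: template unit deleted (gap in target); Y: target residue inserted
  for (i in 0:nU) {
    for (j in 0:nQ) {
      if (i == 0 && j == 0) next
      if (i > 0) {
        L <- ulen[i]
        prev_best <- max(M[i, j + 1], Y[i, j + 1])
        X[i + 1, j + 1] <- max(prev_best - gap_of(L), X[i, j + 1] - gap_extend * L)
        if (j >= L) {
          sub <- sum(ifelse(units[[i]] == q[(j - L + 1):j], match, mismatch))
          M[i + 1, j + 1] <- max(M[i, j - L + 1], X[i, j - L + 1],
                                 Y[i, j - L + 1]) + sub
        }
      }
      if (j > 0 && ins_ok(i)) {
        Y[i + 1, j + 1] <- max(max(M[i + 1, j], X[i + 1, j]) - gap_of(1),
                               Y[i + 1, j] - gap_extend)
      }
    }
  }
  # traceback
  i <- nU; j <- nQ
  state <- which.max(c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1]))
  cols <- list()
  while (i > 0 || j > 0) {
    if (state == 1 && i > 0) {
      L <- ulen[i]
      sub <- sum(ifelse(units[[i]] == q[(j - L + 1):j], match, mismatch))
      prev <- c(M[i, j - L + 1], X[i, j - L + 1], Y[i, j - L + 1])
      from <- which.max(prev)
      tgt <- q[(j - L + 1):j]
      cols[[length(cols) + 1L]] <- data.frame(
        template = rev(units[[i]]), target = rev(tgt),
        helical = helical[i], stringsAsFactors = FALSE)
      i <- i - 1L; j <- j - L; state <- from
    } else if (state == 2) {
      L <- ulen[i]
      opts <- c(max(M[i, j + 1], Y[i, j + 1]) - gap_of(L),
                X[i, j + 1] - gap_extend * L)
      from <- if (abs(X[i + 1, j + 1] - opts[2]) < 1e-9 && i > 1) 2L else 1L
      cols[[length(cols) + 1L]] <- data.frame(
        template = rev(units[[i]]), target = rep("-", L),
        helical = helical[i], stringsAsFactors = FALSE)
      i <- i - 1L
      if (from == 1L) {
        state <- if (M[i + 1, j + 1] >= Y[i + 1, j + 1]) 1L else 3L
      }
    } else {
      opts <- c(max(M[i + 1, j], X[i + 1, j]) - gap_of(1),
                Y[i + 1, j] - gap_extend)
      from <- if (abs(Y[i + 1, j + 1] - opts[2]) < 1e-9 && j > 1) 2L else 1L
      cols[[length(cols) + 1L]] <- data.frame(
        template = "-", target = q[j], helical = FALSE,
        stringsAsFactors = FALSE)
      j <- j - 1L
      if (from == 1L) {
        state <- if (M[i + 1, j + 1] >= X[i + 1, j + 1]) 1L else 2L
      }
    }
  }
  ali <- do.call(rbind, rev(lapply(cols, function(d) d[rev(seq_len(nrow(d))), ])))
  ali <- tibble::as_tibble(ali)
  ali$state <- dplyr::case_when(
    ali$template == "-" ~ "insertion",
    ali$target == "-" ~ "deletion",
    ali$template == ali$target ~ "match",
    TRUE ~ "mismatch")
  ali
}

#' Align a target sequence to the triple-helix template
#'
#' Global alignment of three target chains against the template with a
#' Gly-anchored constraint: inside the declared helical region, gaps are only
#' inserted as whole triplets (preserving the Gly-X-Y frame) and target
#' insertions are forbidden; the telopeptides align unconstrained under
#' affine gap penalties.
#'
#' @param template A [triple_helix_sequence()].
#' @param target Character vector (or list) of three target chain sequences,
#'   matched to template chains by position.
#' @param identity_floor Percent identity below which a distant-homolog
#'   warning is emitted (default 30).
#' @return Object of class `alignment_result`: per-chain alignment tibbles
#'   (`template`, `target`, `helical`, `state`), per-chain and overall
#'   percent identity, and the template helical region.
#' @export
align_to_template <- function(template, target, identity_floor = 30) {
  stopifnot(inherits(template, "triple_helix_sequence"))
  target <- as.list(target)
  if (length(target) != 3) stop("three target chains required", call. = FALSE)
  target <- lapply(target, function(s) toupper(gsub("[[:space:]]", "", s)))
  hr <- template$helical_region
  alis <- purrr::map2(template$chains, target, function(ts, qs) {
    align_chain(ts, qs, hr[1], hr[2])
  })
  ident <- vapply(alis, function(a) 100 * mean(a$state == "match"), numeric(1))
  overall <- 100 * sum(vapply(alis, function(a) sum(a$state == "match"),
                              numeric(1))) /
    sum(vapply(alis, nrow, integer(1)))
  if (overall < identity_floor) {
    warning(sprintf("distant homolog; inspect model (identity %.1f%% < %g%%)",
                    overall, identity_floor))
  }
  structure(list(chains = alis, identity = ident,
                 overall_identity = overall, helical_region = hr),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> overall identity %.1f%% (chains: %s)\n",
              x$overall_identity,
              paste(sprintf("%.1f", x$identity), collapse = ", ")))
  invisible(x)
}

#' Thread a target sequence onto the template backbone
#'
#' Substitutes residues without altering the backbone: for every aligned
#' position the backbone atoms (N, CA, C, O) are copied verbatim from the
#' template, side chains of substituted residues are rebuilt at idealized
#' geometry, deleted positions are removed, and insertions inside the helical
#' region are rejected (telopeptide insertions are skipped with a warning —
#' there is no template backbone to place them on).
#'
#' @param structure Atom tibble of the template triple helix (or a list with
#'   an `atoms` element). Chains are matched to alignment chains in order of
#'   first appearance.
#' @param alignment An [alignment_result()][align_to_template()].
#' @return The mutated atom tibble; per-position actions are recorded in
#'   attribute `"threading_report"` (tibble: `chain`, `resid`,
#'   `template_aa`, `target_aa`, `action`).
#' @export
thread_sequence <- function(structure, alignment) {
  atoms <- if (is.list(structure) && !is.data.frame(structure)) structure$atoms else structure
  stopifnot(inherits(alignment, "alignment_result"))
  chains <- unique(atoms$chain)
  if (length(chains) != 3) stop("template structure must have three chains", call. = FALSE)
  out <- list(); report <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    ali <- alignment$chains[[ci]]
    catoms <- atoms[atoms$chain == ch, ]
    resids <- unique(catoms$resid)
    ti <- 0L
    ins_flags <- ali$template == "-"
    # helical insertion = both flanking template columns helical
    for (k in which(ins_flags)) {
      before <- k - 1; after <- k + 1
      while (after <= nrow(ali) && ali$template[after] == "-") after <- after + 1
      hel_before <- before >= 1 && ali$helical[before]
      hel_after <- after <= nrow(ali) && ali$helical[after]
      if (hel_before && hel_after) {
        stop("unsupported indel; re-align (insertion in helical region)",
             call. = FALSE)
      }
    }
    for (k in seq_len(nrow(ali))) {
      if (ali$template[k] == "-") {
        warning("telopeptide insertion skipped (no template backbone)")
        report[[length(report) + 1L]] <- tibble::tibble(
          chain = ch, resid = NA_integer_, template_aa = "-",
          target_aa = ali$target[k], action = "skipped_insertion")
        next
      }
      ti <- ti + 1L
      rid <- resids[ti]
      if (ali$target[k] == "-") {
        report[[length(report) + 1L]] <- tibble::tibble(
          chain = ch, resid = rid, template_aa = ali$template[k],
          target_aa = "-", action = "deleted")
        next
      }
      res <- catoms[catoms$resid == rid, ]
      if (ali$state[k] != "match") {
        res <- mutate_residue(res, ch, rid, aa_to3(ali$target[k]))
      }
      out[[length(out) + 1L]] <- res
      report[[length(report) + 1L]] <- tibble::tibble(
        chain = ch, resid = rid, template_aa = ali$template[k],
        target_aa = ali$target[k],
        action = if (ali$state[k] == "match") "kept" else "substituted")
    }
  }
  res <- dplyr::bind_rows(out)
  res$serial <- seq_len(nrow(res))
  attr(res, "cell") <- attr(atoms, "cell")
  attr(res, "threading_report") <- dplyr::bind_rows(report)
  res
}

#' Mean axial rise per Gly-X-Y triplet
#'
#' The along-axis distance between consecutive glycine C-alpha atoms in each
#' chain, averaged over chains. The helix axis is the first principal
#' component of all C-alpha positions (robust to slight supercoiling). For a
#' canonical collagen triple helix the expected value is about 8.6 Angstrom
#' per triplet.
#'
#' @param structure Atom tibble (or list with `atoms`).
#' @return Mean rise per triplet (Angstrom); per-chain means in attribute
#'   `"per_chain"`.
#' @export
axial_rise <- function(structure) {
  atoms <- if (is.list(structure) && !is.data.frame(structure)) structure$atoms else structure
  ca <- atoms[atoms$atom == "CA", ]
  if (nrow(ca) < 6) stop("fewer than two triplets of CA atoms", call. = FALSE)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  axis <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)$rotation[, 1]
  per_chain <- vapply(split(ca, ca$chain), function(cc) {
    gly <- cc[cc$resname == "GLY", ]
    gly <- gly[order(gly$resid), ]
    if (nrow(gly) < 2) return(NA_real_)
    proj <- as.matrix(gly[, c("x", "y", "z")]) %*% axis
    mean(abs(diff(as.numeric(proj))))
  }, numeric(1))
  if (all(is.na(per_chain))) stop("fewer than two glycine CA per chain", call. = FALSE)
  out <- mean(per_chain, na.rm = TRUE)
  attr(out, "per_chain") <- per_chain
  out
}
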