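test_that("registry enforces valence bookkeeping", {
  reg <- crosslink_registry()
  expect_true(all(c("HLKNL", "PYD") %in% names(reg)))
  expect_length(reg$HLKNL$residues, 2)
  expect_length(reg$PYD$residues, 3)
  bad <- tempfile(fileext = ".yml")
  writeLines(c("version: 1", "types:", "  BAD:", "    valence: divalent",
               "    residues: [X1, X2, X3]",
               "    reactive_atoms: {X1: [NZ], X2: [NZ], X3: [NZ]}"), bad)
  expect_error(crosslink_registry(bad), "exactly 2 residues")
})

test_that("detect_links is symmetric and obeys the cutoff", {
  mk <- function(id, x, z) {
    a <- fibrilforge:::new_atom_tbl(1L, "NZ", "L4Y", "A", 1L, x, 0, z,
                                    type = "HETATM")
    a$vdw <- vdw_radius(a$element)
    new_molecule(id, a, sites = detect_sites(a))
  }
  near <- detect_links(mk(1, 0, 0), mk(2, 2.9, 0))
  expect_equal(nrow(near), 1)
  expect_equal(near$distance, 2.9)
  expect_equal(nrow(detect_links(mk(1, 0, 0), mk(2, 3.1, 0))), 0)
  # symmetry and brute-force agreement on random site clouds
  set.seed(13)
  for (i in 1:5) {
    a1 <- fibrilforge:::new_atom_tbl(1:6, "NZ", "L4Y", "A", 1:6,
                                     runif(6, 0, 10), runif(6, 0, 10),
                                     runif(6, 0, 10), type = "HETATM")
    a2 <- fibrilforge:::new_atom_tbl(1:6, "NZ", "L5Y", "A", 1:6,
                                     runif(6, 0, 10), runif(6, 0, 10),
                                     runif(6, 0, 10), type = "HETATM")
    m1 <- new_molecule(1, a1, sites = detect_sites(a1))
    m2 <- new_molecule(2, a2, sites = detect_sites(a2))
    ab <- detect_links(m1, m2, cutoff = 4)
    ba <- detect_links(m2, m1, cutoff = 4)
    expect_equal(nrow(ab), nrow(ba))
    expect_equal(sort(ab$distance), sort(ba$distance))
    d <- sqrt(fibrilforge:::cross_dist2(as.matrix(a1[, c("x", "y", "z")]),
                                        as.matrix(a2[, c("x", "y", "z")])))
    expect_equal(nrow(ab), sum(d < 4))
  }
})

test_that("crosslink units have correct membership and valence", {
  div <- crosslink_units(make_fibril(n = 4, arrangement = "row"))
  expect_equal(unique(div$n_members), 2L)
  expect_equal(unique(div$valence), "divalent")
  expect_equal(unique(div$type), "HLKNL")
  expect_equal(length(unique(div$unit)), 6)  # 3 junctions x 2 telopeptide levels
  tri <- crosslink_units(make_fibril(n = 6, arrangement = "row", type = "PYD"))
  expect_equal(unique(tri$n_members), 3L)
  expect_equal(unique(tri$valence), "trivalent")
  expect_equal(unique(tri$type), "PYD")
  expect_equal(length(unique(tri$unit)), 10)
})

test_that("mix assignment follows the requested ratios", {
  sys <- light_site_system(40)
  all_div <- assign_mix(sys, c("HLKNL-HLKNL" = 1), seed = 2)
  expect_equal(attr(all_div, "mix_report")$frequency, 1)
  expect_true(all(vapply(all_div$molecules,
                         function(m) m$class == "HLKNL-HLKNL", logical(1))))
  # four classes in equal proportion, 10,000 molecules: binomial 3 sigma
  big <- light_site_system(10000)
  mixed <- assign_mix(big, c("div-div" = 1, "tri-div" = 1, "div-tri" = 1,
                             "tri-tri" = 1), seed = 8)
  rep <- attr(mixed, "mix_report")
  sigma <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(rep$frequency - 0.25) < 3 * sigma))
  # 50% PYD + 50% HLKNL
  half <- assign_mix(big, c("PYD-PYD" = 0.5, "HLKNL-HLKNL" = 0.5), seed = 9)
  f <- attr(half, "mix_report")$frequency[1]
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 10000))
  # reproducibility under the seed
  again <- assign_mix(big, c("PYD-PYD" = 0.5, "HLKNL-HLKNL" = 0.5), seed = 9)
  expect_identical(attr(again, "mix_report"), attr(half, "mix_report"))
  expect_error(assign_mix(sys, c("NOPE-NOPE" = 1)), "not in crosslink library")
})

test_that("crosslink removal is exact, unit-complete and lysine-rebuilding", {
  pyd <- make_fibril(n = 6, arrangement = "row", type = "PYD")
  expect_equal(attr(remove_crosslinks(pyd, 0), "removal_report")$remaining, 10)
  rem <- remove_crosslinks(pyd, 0.3, seed = 3)
  rep <- attr(rem, "removal_report")
  expect_equal(rep$removed, 3)
  expect_equal(rep$remaining_fraction, 0.7)
  u <- crosslink_units(rem)
  expect_equal(length(unique(u$unit)), 7)
  expect_equal(unique(u$n_members), 3L)  # surviving units stay complete
  # replaced residues became lysine
  atoms <- system_atoms(rem)
  expect_equal(sum(atoms$resname == "LYS"), 9)  # 3 units x 3 members
  # full removal: everything unconnected
  gone <- remove_crosslinks(pyd, 1, seed = 3)
  cs <- connectivity_stats(gone)
  expect_equal(cs$fraction[cs$category == "unconnected"], 1,
               ignore_attr = TRUE)
  expect_error(remove_crosslinks(pyd, 1.2), "rate")
})

test_that("removal only touches the selected crosslink residues", {
  div <- make_fibril(n = 4, arrangement = "row")
  rem <- remove_crosslinks(div, 0.5, seed = 6)
  a0 <- system_atoms(div); a1 <- system_atoms(rem)
  # arm residues have no backbone: the lysine swap renames in place,
  # so atom counts are conserved everywhere
  expect_equal(nrow(a1), nrow(a0))
  changed <- a1$resname != a0$resname
  expect_true(all(a0$resname[changed] %in% c("L4Y", "L5Y")))
  expect_true(all(a1$resname[changed] == "LYS"))
  expect_equal(a1$x, a0$x)
})

test_that("backbone-anchored lysine rebuild preserves the backbone", {
  h <- make_triple_helix(n_res = 9)
  mut <- fibrilforge:::mutate_residue(h, "A", 5, "LYS")
  res <- mut[mut$chain == "A" & mut$resid == 5, ]
  expect_setequal(res$atom, c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"))
  for (a in c("N", "CA", "C", "O")) {
    old <- h[h$chain == "A" & h$resid == 5 & h$atom == a, c("x", "y", "z")]
    new <- res[res$atom == a, c("x", "y", "z")]
    expect_equal(new, old, ignore_attr = TRUE)
  }
  # idealized bond lengths along the rebuilt chain
  get <- function(at) as.numeric(res[res$atom == at, c("x", "y", "z")])
  expect_equal(sqrt(sum((get("CG") - get("CB"))^2)), 1.53, tolerance = 1e-6)
  expect_equal(sqrt(sum((get("NZ") - get("CE"))^2)), 1.49, tolerance = 1e-6)
})
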