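single_atom <- function() {
  a <- fibrilforge:::new_atom_tbl(1L, "CA", "GLY", "A", 1L, 0, 0, 0)
  a$vdw <- vdw_radius(a$element)
  a
}

test_that("transforms apply, compose and invert correctly", {
  h <- make_triple_helix(n_res = 9)
  expect_equal(apply_xform(h, xform_identity()), h)
  moved <- apply_xform(h, xform(t = c(5, 0, 0)))
  expect_equal(moved$x, h$x + 5)
  expect_equal(moved[, c("atom", "resname", "chain", "resid")],
               h[, c("atom", "resname", "chain", "resid")])
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  T <- xform(R, c(1, -2, 3))
  back <- apply_xform(apply_xform(h, T), xform_inverse(T))
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(h[, c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("copy enumeration matches hand counts on the cubic cell", {
  a <- single_atom()
  cl <- unit_cell(10, 10, 10)
  expect_length(enumerate_symmetry_copies(a, cl, 1), 1)   # below nearest image
  xs <- enumerate_symmetry_copies(a, cl, 10)              # 6 axial neighbors
  expect_length(xs, 7)
  expect_true(any(vapply(xs, function(x) all(x$lattice == 0), logical(1))))
  # corners at sqrt(300) only enter beyond that distance
  expect_length(enumerate_symmetry_copies(a, cl, sqrt(300) + 1e-6), 27)
})

test_that("copy enumeration equals brute force on random cells", {
  set.seed(11)
  for (i in 1:25) {
    cl <- random_cell()
    a <- single_atom()
    if (i %% 2 == 0) {
      # small 3-atom cloud
      a <- dplyr::bind_rows(a, a, a)
      a$x <- a$x + c(0, 1.5, -0.7); a$y <- a$y + c(0, 0.5, 1.1)
      a$serial <- 1:3
    }
    d_c <- runif(1, 0.5, 8)
    got <- xform_lattice_matrix(enumerate_symmetry_copies(a, cl, d_c))
    want <- oracle_symmetry_lattice(a, cl, d_c)
    expect_equal(unname(got), unname(want))
  }
})

test_that("copy set is monotone in the contact distance", {
  set.seed(3)
  a <- single_atom()
  for (i in 1:10) {
    cl <- random_cell()
    d1 <- runif(1, 1, 5); d2 <- d1 + runif(1, 0.5, 3)
    k1 <- apply(xform_lattice_matrix(enumerate_symmetry_copies(a, cl, d1)),
                1, paste, collapse = ",")
    k2 <- apply(xform_lattice_matrix(enumerate_symmetry_copies(a, cl, d2)),
                1, paste, collapse = ",")
    expect_true(all(k1 %in% k2))
  }
})

test_that("non-P1 space groups warn; garbage symbols error", {
  a <- single_atom()
  cl <- unit_cell(10, 10, 10, space_group = "P 21 21 21")
  expect_warning(enumerate_symmetry_copies(a, cl, 1), "translational")
  cl2 <- unit_cell(10, 10, 10, space_group = "???")
  expect_error(enumerate_symmetry_copies(a, cl2, 1), "unknown space group")
})

test_that("clash filter keeps distant copies and removes superposed ones", {
  h <- make_triple_helix(n_res = 9)
  far <- new_molecule(2, apply_xform(h, xform(t = c(100, 0, 0))))
  sys <- fibril_system(list(new_molecule(1, h), far), unit_cell(10, 10, 10))
  expect_equal(n_molecules(remove_clashes(sys)), 2)
  dup <- new_molecule(2, h)
  sys2 <- fibril_system(list(new_molecule(1, h), dup), unit_cell(10, 10, 10))
  filtered <- remove_clashes(sys2)
  expect_equal(n_molecules(filtered), 1)
  expect_equal(filtered$molecules[[1]]$id, 1)  # identity copy never removed
})

test_that("clash filter leaves zero violating pairs on randomized systems", {
  set.seed(19)
  for (i in 1:20) {
    n_mol <- sample(3:6, 1)
    mols <- lapply(seq_len(n_mol), function(j) {
      a <- make_triple_helix(n_res = 9)
      shift <- runif(3, -6, 6)
      new_molecule(j, apply_xform(a, xform(t = shift)))
    })
    sys <- fibril_system(mols, unit_cell(20, 20, 40))
    filtered <- remove_clashes(sys)
    expect_equal(oracle_clash_pairs(filtered), 0L)
    # greedy contract: re-adding any removed molecule creates a clash
    removed <- attr(filtered, "removed")
    for (id in removed) {
      m <- mols[[id]]
      trial <- fibril_system(c(filtered$molecules, list(m)),
                             unit_cell(20, 20, 40))
      expect_gt(oracle_clash_pairs(trial), 0L)
    }
  }
})
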