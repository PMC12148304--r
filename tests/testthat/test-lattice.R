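test_that("lattice mapping inverts C on random cells and rejects off-lattice", {
  set.seed(5)
  for (i in 1:100) {
    cl <- random_cell()
    C <- orientation_matrix(cl)
    n <- sample(-5:5, 3, replace = TRUE)
    expect_identical(map_to_lattice(frac_to_cart(n, C), C), as.integer(n))
  }
  C <- orientation_matrix(unit_cell(10, 10, 10))
  expect_identical(map_to_lattice(c(0, 0, 0), C), c(0L, 0L, 0L))
  expect_identical(map_to_lattice(frac_to_cart(c(1, 2, 3), C), C), 1:3)
  expect_error(map_to_lattice(c(3.3, 0, 0), C), "off Bravais lattice")
})

test_that("layer candidates span the occupied rectangle minus occupied points", {
  sys <- make_point_fibril(lattice = data.frame(nx = c(0, 2), ny = c(0, 2),
                                                nz = 0))
  cand <- layer_candidates(sys, 0)
  expect_equal(nrow(cand), 7)  # 3x3 rectangle minus 2 occupied
  expect_false(any(paste(cand$nx, cand$ny) %in% c("0 0", "2 2")))
  # fully occupied rectangle
  full <- make_point_fibril(lattice = expand.grid(nx = 0:1, ny = 0:1, nz = 0))
  expect_equal(nrow(layer_candidates(full, 0)), 0)
  # single point: 1x1 rectangle minus itself
  single <- make_point_fibril(lattice = data.frame(nx = 0, ny = 0, nz = 0))
  expect_equal(nrow(layer_candidates(single, 0)), 0)
  # empty layer
  expect_equal(nrow(layer_candidates(single, 5)), 0)
})

test_that("optimization fills exactly the designed vacancy, any seed", {
  vac <- data.frame(nx = 1, ny = 1, nz = 1)
  sys <- make_fibril(arrangement = "grid", dims = c(3, 3, 4), vacancies = vac)
  expect_equal(n_molecules(sys), 35)
  for (seed in c(1, 99, 2024)) {
    opt <- optimize_layers(sys, c(0, 0, 2), seed = seed)
    expect_equal(n_molecules(opt), 36)
    lp <- lattice_points(opt)
    expect_true(any(lp$nx == 1 & lp$ny == 1 & lp$nz == 1))
    rep <- attr(opt, "opt_report")
    expect_equal(sum(rep$accepted), 1)
  }
})

test_that("optimization is conservative: delta 0 no-op, M non-decreasing, contacts verified", {
  vac <- data.frame(nx = c(1, 0), ny = c(1, 2), nz = c(1, 2))
  sys <- make_fibril(arrangement = "grid", dims = c(3, 3, 4), vacancies = vac)
  same <- optimize_layers(sys, c(0, 0, 0))
  expect_equal(n_molecules(same), n_molecules(sys))
  opt <- optimize_layers(sys, c(0, 0, 2), seed = 4)
  expect_gte(n_molecules(opt), n_molecules(sys))
  # originals intact
  expect_equal(lattice_points(opt)[seq_len(n_molecules(sys)), ],
               lattice_points(sys))
  # every accepted molecule satisfies the 3 A inter-crosslink criterion
  ids_old <- vapply(sys$molecules, function(m) m$id, integer(1))
  for (m in opt$molecules) {
    if (m$id %in% ids_old) next
    dmin <- Inf
    for (o in opt$molecules) {
      if (o$id == m$id || nrow(o$sites) == 0) next
      d <- min(sqrt(fibrilforge:::cross_dist2(
        as.matrix(m$sites[, c("x", "y", "z")]),
        as.matrix(o$sites[, c("x", "y", "z")]))))
      dmin <- min(dmin, d)
    }
    expect_lt(dmin, 3.0)
  }
  # no clash introduced
  expect_equal(oracle_clash_pairs(opt), 0L)
})

test_that("optimization never decreases connectivity", {
  vac <- data.frame(nx = 1, ny = 1, nz = 1)
  sys <- make_fibril(arrangement = "grid", dims = c(3, 3, 4), vacancies = vac)
  before <- connectivity_stats(sys)
  after <- connectivity_stats(optimize_layers(sys, c(0, 0, 2), seed = 1))
  conn_frac <- function(cs) sum(cs$fraction[cs$category != "unconnected"])
  expect_gte(conn_frac(after), conn_frac(before))
})

test_that("connectivity fractions classify designed fixtures", {
  one <- connectivity_stats(make_fibril(n = 1, arrangement = "row"))
  expect_equal(one$fraction, c(0, 0, 1), ignore_attr = TRUE)
  pair <- connectivity_stats(make_fibril(n = 2, arrangement = "row",
                                         ends = "N"))
  expect_equal(pair$fraction, c(0, 1, 0), ignore_attr = TRUE)
  linked <- connectivity_stats(make_fibril(n = 6, arrangement = "row"))
  expect_equal(linked$fraction, c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(sum(linked$fraction), 1, tolerance = 1e-9)
})

test_that("density profile is flat for uniform grids and sees designed excess", {
  grid <- make_fibril(arrangement = "grid", dims = c(5, 5, 2))
  dp <- density_profile(grid)
  expect_equal(dp$occupancy_sd, 0)
  # designed 2x central density: on a 10 A lattice, full occupancy inside
  # 10 nm of the origin, checkerboard (half) occupancy in the 10-20 nm ring
  pts <- tidyr::expand_grid(nx = -20:20, ny = -20:20, nz = 0L)
  r <- sqrt(pts$nx^2 + pts$ny^2)  # lattice units = nm here
  pts <- pts[r <= 10 | (r <= 20 & (pts$nx + pts$ny) %% 2 == 0), ]
  sysd <- make_point_fibril(lattice = pts, cell = unit_cell(10, 10, 10))
  prof <- density_profile(sysd, shell_width = 10)$profile
  rho_in <- sum(prof$n[prof$r_outer <= 10]) / (pi * 10^2)
  rho_out <- sum(prof$n[prof$r_inner >= 10 & prof$r_outer <= 20]) /
    (pi * (20^2 - 10^2))
  expect_equal(rho_in / rho_out, 2, tolerance = 0.15)
})

test_that("filling vacancies reduces the occupancy standard deviation", {
  vac <- data.frame(nx = 1, ny = 1, nz = 1)
  sys <- make_fibril(arrangement = "grid", dims = c(3, 3, 4), vacancies = vac)
  opt <- optimize_layers(sys, c(0, 0, 2), seed = 1)
  expect_lt(density_profile(opt)$occupancy_sd,
            density_profile(sys)$occupancy_sd)
})
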