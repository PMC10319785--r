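# Synthetic molecule generation and the projected-area CCS oracle.

test_that("molecule generation honours the spec and is seeded", {
  spec <- synthetic_spec(n_molecules = 25, heavy_atom_range = c(3, 10),
                         seed = 55)
  mols <- generate_molecules(spec)
  expect_length(mols, 25)
  heavy <- vapply(mols, function(m) sum(m$atoms$element != "H"), integer(1))
  expect_true(all(heavy >= 3 & heavy <= 10))
  expect_true(all(vapply(mols, function(m) !is.null(m$conformer),
                         logical(1))))
  mols2 <- generate_molecules(spec)
  expect_identical(names(mols), names(mols2))
})

test_that("single-sphere projected area is pi r^2", {
  for (r in c(1, 1.7)) {
    a <- oracle_ccs(matrix(0, 1, 3), r, oracle_config(probe = 0, seed = 2))
    expect_equal(a, pi * r^2, tolerance = 5e-3)
  }
  # probe addition enlarges the disk radius
  a <- oracle_ccs(matrix(0, 1, 3), 1, oracle_config(probe = 1, seed = 2))
  expect_equal(a, pi * 4, tolerance = 5e-3)
})

test_that("coincident atoms project as one disk", {
  conf <- matrix(0, 2, 3)
  a <- oracle_ccs(conf, c(1.5, 1.5), oracle_config(probe = 0, seed = 3))
  expect_equal(a, pi * 1.5^2, tolerance = 5e-3)
})

test_that("two far-separated atoms bracket between one and two disks", {
  # oracle-of-the-oracle: high-resolution deterministic grid quadrature of
  # the union of two projected disks, averaged over the same orientations
  conf <- rbind(c(0, 0, 0), c(8, 0, 0))
  r <- 1.2
  a <- oracle_ccs(conf, c(r, r), oracle_config(probe = 0, seed = 4))
  expect_gt(a, pi * r^2)
  expect_lte(a, 2 * pi * r^2 * 1.005)
  # closed-form check: disks at distance d >= 2r never overlap unless the
  # projection axis is within asin(2r/d) of the bond axis; integrate the
  # exact union area over projection directions numerically
  exact_union <- function(d, r) {
    # area of union of two disks of radius r at centre distance s
    pair <- function(s) {
      if (s >= 2 * r) return(2 * pi * r^2)
      2 * pi * r^2 - 2 * r^2 * acos(s / (2 * r)) +
        s / 2 * sqrt(4 * r^2 - s^2)
    }
    # uniform directions: projected distance s = d * sin(theta), theta the
    # angle between the axis and the projection direction
    f <- function(theta) vapply(d * sin(theta), pair, numeric(1)) *
      sin(theta)
    stats::integrate(f, 0, pi / 2)$value
  }
  want <- exact_union(8, r)
  expect_equal(a, want, tolerance = 0.01)
})

test_that("oracle is rotation invariant within Monte-Carlo error", {
  ds <- fx_dataset()
  vdw <- setNames(element_table()$vdw_radius, element_table()$element)
  cfg <- oracle_config(n_rotations = 256, seed = 6)
  for (m in ds$molecules[c(2, 9, 17)]) {
    radii <- unname(vdw[m$atoms$element])
    base <- oracle_ccs(m$conformer, radii, cfg)
    for (R in random_rotations(2, seed = 13)) {
      rot <- rotate_conformer(m$conformer, R)
      expect_lt(abs(oracle_ccs(rot, radii, cfg) - base) / base, 0.01)
    }
  }
})

test_that("adding a far atom strictly increases the projected area", {
  set.seed(77)
  cfg <- oracle_config(n_rotations = 64, grid = 32, seed = 8)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    conf <- matrix(rnorm(3 * n, sd = 1.5), n, 3)
    radii <- runif(n, 1.0, 2.0)
    base <- oracle_ccs(conf, radii, cfg)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    far <- colMeans(conf) + dir * (max(dist(conf)) + 30)
    bigger <- oracle_ccs(rbind(conf, far), c(radii, 1.5), cfg)
    expect_gt(bigger, base)
  }
})

test_that("datasets have 3 adduct records per molecule with coherent labels", {
  ds <- make_dataset(synthetic_spec(n_molecules = 10, seed = 31),
                     oracle_config(n_rotations = 64, grid = 32, seed = 31))
  expect_equal(nrow(ds$records), 30)
  expect_equal(as.integer(table(ds$records$adduct)), rep(10L, 3))
  # same-molecule ordering: +Na above +H above -H by the offset construction
  wide <- reshape(ds$records[, c("smiles", "adduct", "ccs_true")],
                  idvar = "smiles", timevar = "adduct", direction = "wide")
  expect_true(all(wide$`ccs_true.[M+Na]+` > wide$`ccs_true.[M+H]+`))
  expect_true(all(wide$`ccs_true.[M-H]-` < wide$`ccs_true.[M+H]+`))
  # m/z from mass and adduct shift
  m1 <- ds$molecules[[ds$records$smiles[1]]]
  expect_equal(ds$records$mz[1],
               sum(m1$atoms$mass) + adduct_mass_shift(ds$records$adduct[1]))
  # determinism
  ds2 <- make_dataset(synthetic_spec(n_molecules = 10, seed = 31),
                      oracle_config(n_rotations = 64, grid = 32, seed = 31))
  expect_identical(ds$records$ccs, ds2$records$ccs)
})

test_that("synthetic CCS is strongly correlated with m/z", {
  r <- fx_dataset()$records
  expect_gt(cor(r$ccs, r$mz), 0.8)
})
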