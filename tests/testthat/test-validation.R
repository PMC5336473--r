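test_that("rscc matches the Pearson formula and its limits", {
  spec <- grid_spec(c(4, 4, 4), c(4, 4, 4))
  a <- bumpy_grid(spec, seed = 2)
  mask <- array(TRUE, spec$shape)
  expect_equal(rscc(a, a, mask), 1.0)
  neg <- voxel_grid(-a$values, spec)
  expect_equal(rscc(a, neg, mask), -1.0)

  # four masked voxel pairs against the hand-computed Pearson value
  m4 <- array(FALSE, spec$shape); m4[1:4, 1, 1] <- TRUE
  x <- voxel_grid(array(0, spec$shape), spec); x$values[1:4, 1, 1] <- c(1, 2, 3, 4)
  y <- voxel_grid(array(0, spec$shape), spec); y$values[1:4, 1, 1] <- c(1, 2, 4, 4)
  hand <- function(u, v) {
    n <- length(u)
    (n * sum(u * v) - sum(u) * sum(v)) /
      sqrt((n * sum(u^2) - sum(u)^2) * (n * sum(v^2) - sum(v)^2))
  }
  expect_equal(rscc(x, y, m4), hand(c(1, 2, 3, 4), c(1, 2, 4, 4)))

  expect_error(rscc(a, voxel_grid(array(1, spec$shape), spec), mask),
               "degenerate")
  expect_error(rscc(a, a, array(FALSE, spec$shape)), "empty")
})

test_that("rscc is invariant under positive affine transforms", {
  spec <- grid_spec(c(8, 8, 8), c(8, 8, 8))
  a <- bumpy_grid(spec, seed = 4)
  b <- bumpy_grid(spec, seed = 6)
  mask <- a$values > 0
  base <- rscc(a, b, mask)
  expect_equal(rscc(voxel_grid(2.5 * a$values + 7, spec), b, mask), base,
               tolerance = 1e-9)
  expect_equal(rscc(a, voxel_grid(0.1 * b$values - 3, spec), mask), base,
               tolerance = 1e-9)
})

test_that("RSZO/OCC samples the sigma map at atom centres", {
  spec <- grid_spec(c(16, 16, 16), c(8, 8, 8))
  em <- voxel_grid(array(2, spec$shape), spec, unit_label = "sigma")
  # constant 2 sigma has zero variance; bypass sigma_scale by construction
  lig <- ligand_model("xA", atom_records("C", matrix(stats::runif(9, 2, 6), 3)),
                      refined_occupancy = 0.5)
  expect_equal(rszo_over_occ(em, lig), 4.0)
  flat0 <- voxel_grid(array(0, spec$shape), spec, unit_label = "sigma")
  expect_equal(rszo_over_occ(flat0, lig), 0.0)
  raw <- voxel_grid(array(2, spec$shape), spec)
  expect_error(rszo_over_occ(raw, lig), "sigma")
})

test_that("a well-placed ligand outscores the same model displaced by 5 A", {
  st <- test_structure()
  spec <- st$spec
  q <- 0.5
  obs <- simulate_dataset(st, occupancy = q, site = 1)
  E <- compute_event_map(obs, st$rho_ground, 1 - q)
  Es <- sigma_scale(E)
  lig_atoms <- st$sites[[1]]$ligand
  good <- ligand_model("xA", lig_atoms, refined_occupancy = q)
  moved_atoms <- lig_atoms
  moved_atoms$x <- moved_atoms$x + 5
  bad <- ligand_model("xA", moved_atoms, refined_occupancy = q)
  expect_gt(rszo_over_occ(Es, good), rszo_over_occ(Es, bad))
})

test_that("the surroundings B-factor ratio uses the contact shell", {
  lig <- ligand_model("xA", atom_records("C", rbind(c(0, 0, 0), c(1.4, 0, 0)),
                                         b = 40), refined_occupancy = 1)
  env <- atom_records("O", rbind(c(2, 0, 0), c(0, 3, 0), c(30, 30, 30)),
                      b = c(20, 20, 999))
  expect_equal(surroundings_b_ratio(lig, env, radius = 4), 2.0)
  same_b <- atom_records("O", rbind(c(2, 0, 0), c(0, 3, 0)), b = 40)
  expect_equal(surroundings_b_ratio(lig, same_b, radius = 4), 1.0)
  # hand-constructed mixed selection: atoms at 2 and 3.5 A are in range,
  # the one at 8 A is not
  env2 <- atom_records("O", rbind(c(2, 0, 0), c(0, 3.5, 0), c(8, 0, 0)),
                       b = c(10, 30, 500))
  expect_equal(surroundings_b_ratio(lig, env2, radius = 4), 40 / mean(c(10, 30)))
  far <- atom_records("O", matrix(c(20, 20, 20), 1), b = 20)
  expect_error(surroundings_b_ratio(lig, far, radius = 4), "within")
})

test_that("occupancy-sum checks accept complementary ensemble states", {
  expect_true(check_occupancy_sum(c(0.22, 0.78)))      # ligand + unbound pair
  expect_true(check_occupancy_sum(c(1.0)))
  expect_false(check_occupancy_sum(c(0.5, 0.3), tolerance = 0.01))
  expect_true(check_occupancy_sum(c(0.78, 0.22)))      # order-invariant
  states <- list(list(label = "bound", occupancy = 0.4),
                 list(label = "unbound", occupancy = 0.6))
  expect_true(check_occupancy_sum(states))
  expect_error(check_occupancy_sum(numeric(0)), "no states")
})

test_that("hit rates reproduce the screen arithmetic", {
  expect_identical(hit_rate(24, 226), 10.6)
  expect_identical(hit_rate(2, 226), 0.9)
  expect_identical(hit_rate(0, 100), 0)
  expect_error(hit_rate(5, 0), "n_screened")
  expect_error(hit_rate(11, 10), "<=")
  # monotone in the hit count, bounded in [0, 100]
  rates <- vapply(0:50, hit_rate, numeric(1), n_screened = 50)
  expect_true(all(diff(rates) >= 0))
  expect_true(all(rates >= 0 & rates <= 100))
})

test_that("screen summaries tabulate counts, histogram and quartiles", {
  spec <- grid_spec(c(4, 4, 4), c(4, 4, 4))
  mk_ds <- function(id, res) crystal_dataset(id, bumpy_grid(spec, seed = 1),
                                             resolution = res, r_work = 0.13,
                                             r_free = 0.17)
  ds <- Map(mk_ds, paste0("x", 1:4), c(1, 2, 3, 4))
  s0 <- summarize_screen(ds, list())
  expect_equal(s0$n_ligands, 0)
  expect_equal(sum(s0$occupancy_histogram$count), 0)
  # type-7 quartiles of {1,2,3,4}
  expect_equal(unname(s0$stat_quartiles["resolution", ]),
               c(1, 1.75, 2.5, 3.25, 4))

  at <- atom_records("C", matrix(c(1, 1, 1), 1))
  ds226 <- Map(mk_ds, sprintf("x%03d", 1:226), rep(1.5, 226))
  lig_ids <- rep(sprintf("x%03d", 1:24), length.out = 37)
  occs <- rep(c(0.22, 0.45, 0.66, 0.78), length.out = 37)
  ligs <- Map(function(id, o) ligand_model(id, at, o), lig_ids, occs)
  s <- summarize_screen(ds226, ligs)
  expect_equal(s$n_ligands, 37)
  expect_equal(s$n_hit_datasets, 24)
  expect_equal(s$hit_rate_percent, 10.6)
  expect_equal(sum(s$occupancy_histogram$count), 37)
})
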