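test_that("grid_spec validates its inputs", {
  expect_s3_class(grid_spec(c(8, 8, 8), c(10, 10, 10)), "grid_spec")
  expect_error(grid_spec(c(1, 8, 8), c(10, 10, 10)), ">= 2")
  expect_error(grid_spec(c(8, 8, 8), c(-1, 10, 10)), "positive")
  expect_error(grid_spec(c(8, 8, 8), c(10, 10, 10), c(90, 190, 90)), "180")
  expect_equal(voxel_spacing(grid_spec(c(10, 20, 40), c(10, 10, 10))),
               c(1, 0.5, 0.25))
})

test_that("map write/read round trip preserves shape, cell and values", {
  g <- bumpy_grid(grid_spec(c(12, 10, 14), c(9, 7.5, 11.25)))
  p <- tempfile(fileext = ".ccp4")
  write_density_map(g, p)
  g2 <- read_density_map(p)
  expect_equal(g2$spec$shape, g$spec$shape)
  expect_equal(g2$spec$cell_lengths, g$spec$cell_lengths, tolerance = 1e-6)
  expect_lt(max(abs(g2$values - g$values)), 1e-6)
  unlink(p)
})

test_that("maps interoperate with an independent reader/writer", {
  p <- tempfile(fileext = ".ccp4")
  gemmi_write_constant_map(p, c(8, 10, 12), c(8, 10, 12), 2.5)
  g <- read_density_map(p)
  expect_equal(g$spec$shape, c(8L, 10L, 12L))
  expect_true(all(abs(g$values - 2.5) < 1e-6))
  unlink(p)

  g <- bumpy_grid(grid_spec(c(6, 8, 10), c(6.5, 8.25, 10.75)))
  p2 <- tempfile(fileext = ".ccp4")
  write_density_map(g, p2)
  probe <- gemmi_probe_map(p2)
  expect_equal(probe[1:3], g$spec$cell_lengths, tolerance = 1e-5)
  expect_equal(probe[4:6], as.numeric(g$spec$shape))
  expect_equal(probe[7], g$values[2, 3, 4], tolerance = 1e-6)
  unlink(p2)
})

test_that("malformed map files raise errors naming the problem", {
  expect_error(read_density_map(tempfile()), "no such file")
  p <- tempfile(fileext = ".ccp4")
  writeBin(raw(100), p)
  expect_error(read_density_map(p), "truncated")
  g <- bumpy_grid(grid_spec(c(8, 8, 8), c(8, 8, 8)))
  write_density_map(g, p)
  # truncate the data section: header promises 512 voxels
  raw_all <- readBin(p, "raw", file.info(p)$size)
  writeBin(raw_all[1:(1024 + 4 * 100)], p)
  expect_error(read_density_map(p), "truncated")
  unlink(p)
})

test_that("resampling is exact on its own spec and on trilinear fields", {
  g <- bumpy_grid()
  same <- resample_onto(g, g$spec)
  expect_lt(max(abs(same$values - g$values)), 1e-9)

  spec <- grid_spec(c(8, 8, 8), c(10, 10, 10))
  const <- voxel_grid(array(3.25, spec$shape), spec)
  finer <- grid_spec(c(13, 11, 9), c(10, 10, 10))
  expect_lt(max(abs(resample_onto(const, finer)$values - 3.25)), 1e-12)

  # a field linear in fractional coordinates (periodic sawtooth avoided by
  # testing only interior target points through interpolate_trilinear)
  n <- spec$shape
  fx <- (seq_len(n[1]) - 1) / n[1]
  lin <- voxel_grid(array(outer(outer(2 * fx, 3 * fx, `+`), 0.5 * fx, `+`),
                          n), spec)
  pts <- with_test_seed(1, matrix(stats::runif(300, 0.05, 0.85), ncol = 3))
  got <- interpolate_trilinear(lin, pts)
  want <- 2 * pts[, 1] + 3 * pts[, 2] + 0.5 * pts[, 3]
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("resampling refuses non-isomorphous cells", {
  g <- bumpy_grid(grid_spec(c(8, 8, 8), c(10, 10, 10)))
  other <- grid_spec(c(8, 8, 8), c(10.5, 10, 10))   # 5% off
  expect_error(resample_onto(g, other), "isomorphous")
  near <- grid_spec(c(8, 8, 8), c(10.1, 10, 10))    # 1% off: fine
  expect_s3_class(resample_onto(g, near), "voxel_grid")
})

test_that("sigma scaling normalizes, is idempotent, and matches the formula", {
  g <- bumpy_grid()
  s <- sigma_scale(g)
  expect_lt(abs(mean(s$values)), 1e-9)
  expect_lt(abs(stats::sd(s$values) - 1), 1e-9)
  expect_identical(s$unit_label, "sigma")
  s2 <- sigma_scale(s)
  expect_lt(max(abs(s2$values - s$values)), 1e-9)

  spec <- grid_spec(c(2, 2, 2), c(2, 2, 2))
  hand <- voxel_grid(array(c(0, 0, 0, 4, 0, 0, 0, 0), c(2, 2, 2)), spec)
  s3 <- sigma_scale(hand)
  expect_equal(as.numeric(s3$values),
               (c(0, 0, 0, 4, 0, 0, 0, 0) - 0.5) / stats::sd(c(0, 0, 0, 4, 0, 0, 0, 0)))

  flat <- voxel_grid(array(1, c(4, 4, 4)), grid_spec(c(4, 4, 4), c(4, 4, 4)))
  expect_error(sigma_scale(flat), "degenerate")

  # masked scaling: statistics over the mask only
  mask <- array(FALSE, dim(g$values)); mask[1:8, , ] <- TRUE
  sm <- sigma_scale(g, mask)
  expect_lt(abs(mean(sm$values[mask])), 1e-9)
  expect_lt(abs(stats::sd(sm$values[mask]) - 1), 1e-9)
})

test_that("sphere masks match the exhaustive-distance oracle", {
  spec <- grid_spec(c(16, 16, 16), c(8, 8, 8))
  # single atom on a voxel centre with radius half the spacing: one voxel
  at <- atom_records("C", matrix(c(2, 2, 2), 1))
  expect_equal(sum(sphere_mask(at, 0.25, spec)), 1L)
  # radius spanning the whole cell: everything
  expect_true(all(sphere_mask(at, 8, spec)))
  # empty atom table: empty mask, no error
  expect_false(any(sphere_mask(at[0, ], 1, spec)))
  # random atoms (some near the boundary to exercise wrapping)
  pos <- with_test_seed(7, matrix(stats::runif(15, -1, 9), ncol = 3))
  atoms <- atom_records("O", pos)
  expect_identical(sphere_mask(atoms, 1.3, spec),
                   brute_sphere_mask(atoms, 1.3, spec))
})

test_that("mask dilation agrees with a sphere-mask construction", {
  spec <- grid_spec(c(16, 16, 16), c(8, 8, 8))
  at <- atom_records("C", matrix(c(1, 4, 7.5), 1))
  seed_mask <- sphere_mask(at, 0.25, spec)   # the atom's voxel
  # dilating a single voxel by r = sphere of r around that voxel centre
  expect_identical(dilate_mask(seed_mask, 2, spec),
                   brute_sphere_mask(atom_records("C", matrix(c(1, 4, 7.5), 1)),
                                     2, spec))
})

test_that("non-orthogonal cells get consistent coordinate transforms", {
  spec <- grid_spec(c(8, 8, 8), c(10, 12, 14), c(85, 95, 100))
  A <- frac_to_cart_matrix(spec)
  expect_equal(A %*% cart_to_frac_matrix(spec) %*% c(1, 2, 3), cbind(c(1, 2, 3)))
  # cell volume via the metric equals det(A)
  expect_equal(det(A), voxel_volume(spec) * prod(spec$shape))
})

test_that("PDB files populate atom records", {
  n <- 5
  xyz <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 1.5, 2.5, 3.5, 9, 9, 9),
                ncol = 3, byrow = TRUE)
  p <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = p, xyz = as.numeric(t(xyz)),
                   type = rep("HETATM", n),
                   elety = paste0(c("C", "C", "N", "O", "S"), seq_len(n)),
                   elesy = c("C", "C", "N", "O", "S"),
                   b = c(10, 20, 30, 40, 50), o = rep(0.75, n),
                   resid = rep("LIG", n), resno = rep(1, n),
                   chain = rep("A", n), eleno = seq_len(n))
  at <- read_structure(p)
  expect_s3_class(at, "atom_records")
  expect_equal(nrow(at), n)
  expect_equal(at$element, c("C", "C", "N", "O", "S"))
  expect_equal(as.matrix(at[, c("x", "y", "z")]), xyz, ignore_attr = TRUE,
               tolerance = 1e-3)
  expect_equal(at$b, c(10, 20, 30, 40, 50))
  expect_true(all(at$occ == 0.75))
  expect_equal(element_number(at$element), c(6L, 6L, 7L, 8L, 16L))
  unlink(p)
})
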