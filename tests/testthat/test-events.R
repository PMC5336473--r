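# Insert a Gaussian bump of the given peak height into a z-like field.
insert_blob <- function(vals, spec, centre, peak, width = 1.2) {
  n <- spec$shape
  A <- frac_to_cart_matrix(spec)
  fr <- cbind(rep((seq_len(n[1]) - 1) / n[1], times = n[2] * n[3]),
              rep(rep((seq_len(n[2]) - 1) / n[2], each = n[1]), times = n[3]),
              rep((seq_len(n[3]) - 1) / n[3], each = n[1] * n[2]))
  df <- sweep(fr, 2, solve(A) %*% centre)
  df <- df - round(df)
  d2 <- rowSums((df %*% t(A))^2)
  vals + array(peak * exp(-d2 / (2 * width^2)), n)
}

test_that("event detection matches a brute-force flood fill", {
  spec <- grid_spec(c(24, 24, 24), c(12, 12, 12))
  z <- array(0, spec$shape)
  expect_length(find_events(voxel_grid(z, spec)), 0)

  # one blob with peak z = 8 on a null background
  z1 <- insert_blob(array(with_test_seed(3, stats::rnorm(prod(spec$shape), 0, 0.5)),
                          spec$shape), spec, c(6, 6, 6), peak = 8)
  evs <- find_events(voxel_grid(z1, spec), threshold = 2.5, min_volume = 1)
  expect_length(evs, 1)
  expect_lt(sqrt(sum((evs[[1]]$centroid - c(6, 6, 6))^2)), 0.5)
  expect_gte(evs[[1]]$peak_z, 2.5)

  # oracle agreement on membership (including a boundary-wrapping blob)
  z2 <- insert_blob(z, spec, c(0.3, 11.6, 6), peak = 6)
  z2 <- insert_blob(z2, spec, c(6, 2, 9), peak = 5)
  got <- find_events(voxel_grid(z2, spec), threshold = 2.5, min_volume = 0)
  want <- brute_components(z2, 2.5, spec)
  expect_length(got, length(want))
  key <- function(m) paste(sort(m[, 1] + 100 * m[, 2] + 10000 * m[, 3]),
                           collapse = ",")
  expect_setequal(vapply(got, function(e) key(e$voxel_indices), character(1)),
                  vapply(want, key, character(1)))
})

test_that("two distant blobs give two events, ordered by peak z", {
  spec <- grid_spec(c(48, 48, 48), c(28, 28, 28))
  z <- insert_blob(array(0, spec$shape), spec, c(4, 4, 4), peak = 6)
  z <- insert_blob(z, spec, c(18, 18, 18), peak = 9)   # 24 A apart
  evs <- find_events(voxel_grid(z, spec), threshold = 2.5, min_volume = 1)
  expect_length(evs, 2)
  expect_gt(evs[[1]]$peak_z, evs[[2]]$peak_z)
  expect_lt(sqrt(sum((evs[[1]]$centroid - c(18, 18, 18))^2)), 0.5)
})

test_that("cluster count is unchanged by sub-threshold noise", {
  spec <- grid_spec(c(24, 24, 24), c(12, 12, 12))
  z <- insert_blob(array(0, spec$shape), spec, c(3, 3, 3), peak = 8)
  z <- insert_blob(z, spec, c(9, 9, 9), peak = 7)
  base <- find_events(voxel_grid(z, spec), threshold = 2.5, min_volume = 1)
  noisy <- z + array(with_test_seed(5, stats::runif(prod(spec$shape), 0, 1.2)),
                     spec$shape)   # everywhere below threshold/2
  after <- find_events(voxel_grid(noisy, spec), threshold = 2.5, min_volume = 1)
  expect_length(after, length(base))
})

test_that("min_volume and the detection mask filter components", {
  spec <- grid_spec(c(24, 24, 24), c(12, 12, 12))
  z <- insert_blob(array(0, spec$shape), spec, c(6, 6, 6), peak = 4, width = 0.6)
  all_ev <- find_events(voxel_grid(z, spec), threshold = 2.5, min_volume = 0)
  expect_length(all_ev, 1)
  vol <- all_ev[[1]]$volume
  expect_length(find_events(voxel_grid(z, spec), threshold = 2.5,
                            min_volume = vol + 1), 0)
  off_mask <- array(TRUE, spec$shape)
  off_mask[1:16, , ] <- FALSE   # blob at x = 6 A lives in the masked-out region
  expect_length(find_events(voxel_grid(z, spec), threshold = 2.5,
                            min_volume = 0, mask = off_mask), 0)
})

test_that("event maps satisfy the reconstruction identity", {
  st <- test_structure()
  obs <- simulate_dataset(st, occupancy = 0.4, site = 1)
  mu <- st$rho_ground
  for (b in c(0, 0.5, 0.9, 0.92)) {
    E <- compute_event_map(obs, mu, b)
    expect_lt(max(abs((1 - b) * E$values + b * mu$values - obs$values)), 1e-10)
  }
  expect_error(compute_event_map(obs, mu, 1), "bdc")
  expect_error(compute_event_map(obs, mu, 1.3), "bdc")
  # bdc = 0: the event map is the observation
  expect_equal(compute_event_map(obs, mu, 0)$values, obs$values)
  # obs identical to the mean: E = mu for any valid bdc
  E2 <- compute_event_map(mu, mu, 0.7)
  expect_lt(max(abs(E2$values - mu$values)), 1e-10)
  # exact mixture at bdc = 1 - q recovers the bound state
  q <- 0.35
  mix <- voxel_grid((1 - q) * mu$values + q * st$rho_bound[[1]]$values, st$spec)
  E3 <- compute_event_map(mix, mu, 1 - q)
  expect_lt(max(abs(E3$values - st$rho_bound[[1]]$values)), 1e-10)
})

test_that("the BDC scan recovers mixture occupancies", {
  st <- test_structure()
  spec <- st$spec
  mu <- st$rho_ground
  lig <- atoms_to_density(st$sites[[1]]$ligand, spec)
  emask <- dilate_mask(sphere_mask(st$sites[[1]]$ligand, 1.5, spec), 3, spec)
  rmask <- sphere_mask(st$ground_atoms, 2.5, spec) & !emask
  for (q in c(0.2, 0.5, 0.8)) {
    obs <- voxel_grid((1 - q) * mu$values + q * lig$values, spec)
    b <- estimate_bdc(obs, mu, emask, rmask)
    expect_lt(abs((1 - as.numeric(b)) - q), 0.05)
    expect_false(attr(b, "flat_objective"))
  }
})

test_that("degenerate BDC inputs are flagged", {
  st <- test_structure()
  spec <- st$spec
  mu <- st$rho_ground
  emask <- dilate_mask(sphere_mask(st$sites[[1]]$ligand, 1.5, spec), 3, spec)
  rmask <- sphere_mask(st$ground_atoms, 2.5, spec) & !emask
  expect_error(estimate_bdc(mu, mu, array(FALSE, spec$shape), rmask), "empty")
  expect_error(estimate_bdc(mu, mu, emask, emask), "disjoint")
  # obs identical to the mean: the scan cannot discriminate
  expect_warning(estimate_bdc(mu, mu, emask, rmask), "flat")
  # a mask where the mean map is constant is degenerate
  flat_mu <- voxel_grid(array(1, spec$shape), spec)
  expect_error(suppressWarnings(estimate_bdc(mu, flat_mu, emask, rmask)),
               "degenerate")
})

test_that("site grouping is single linkage under periodic distance", {
  spec <- grid_spec(c(24, 24, 24), c(24, 24, 24))
  mk <- function(centroid, id = "xA")
    structure(list(dataset_id = id, voxel_indices = cbind(1L, 1L, 1L),
                   centroid = centroid, peak_z = 3, volume = 10,
                   bdc = NA_real_, occupancy_estimate = NA_real_),
              class = "density_event")
  one <- group_into_sites(list(mk(c(3, 3, 3))), cutoff = 5, spec = spec)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$event_refs), 1)

  three <- group_into_sites(list(mk(c(3, 3, 3)), mk(c(5, 3, 3), "xB"),
                                 mk(c(3, 9, 9), "xC")), cutoff = 3, spec = spec)
  expect_equal(vapply(three, function(s) nrow(s$event_refs), integer(1)),
               c(2L, 1L))

  # 37 events at 3 distinct loci across 24 datasets, against the union-find
  # oracle; jitter is small relative to the merge cutoff
  loci <- rbind(c(4, 4, 4), c(14, 6, 12), c(7, 18, 5))
  assign_loci <- rep_len(1:3, 37)
  pts <- with_test_seed(13,
    loci[assign_loci, ] + matrix(stats::runif(37 * 3, -0.8, 0.8), ncol = 3))
  evs <- lapply(seq_len(37), function(i)
    mk(pts[i, ], sprintf("x%03d", (i %% 24) + 1)))
  sites <- group_into_sites(evs, cutoff = 5, spec = spec)
  expect_length(sites, 3)
  oracle <- brute_single_linkage(pts, 5, spec)
  expect_equal(length(unique(oracle)), 3)
  got_sizes <- sort(vapply(sites, function(s) nrow(s$event_refs), integer(1)))
  expect_equal(got_sizes, sort(as.integer(table(oracle))))
  # every member centroid is within the cutoff of its site centroid
  for (s in sites) {
    for (e in s$event_refs$event)
      expect_lt(pandensity:::periodic_distance(evs[[e]]$centroid, s$centroid,
                                               spec), 5)
  }
})
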