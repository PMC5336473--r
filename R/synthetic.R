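#' Gaussian-atom electron density on a voxel grid
#'
#' Computes a model density as a sum of isotropic Gaussians, one per atom:
#' \deqn{\rho(x) = \sum_i occ_i \, Z_i \, (2\pi s_i^2)^{-3/2}
#'       \exp(-|x - x_i|^2 / (2 s_i^2)), \quad s_i^2 = B_i / (8\pi^2)}
#' with amplitude proportional to the atomic number \eqn{Z_i} and width set
#' by the isotropic B-factor. Periodic images are included; each Gaussian is
#' truncated at 4 standard deviations (better than 0.2% of its integral).
#' The density is linear in occupancy and additive over atoms, which is all
#' the downstream statistics rely on; full scattering-factor sums are
#' deliberately not used.
#'
#' @param atoms an [atom_records()] table.
#' @param spec a [grid_spec()].
#' @return a [voxel_grid()] in arbitrary density units (e/A^3-like).
#' @export
atoms_to_density <- function(atoms, spec) {
  if (is.null(atoms) || nrow(atoms) == 0L)
    stop("atoms_to_density: empty atom table", call. = FALSE)
  if (any(atoms$b <= 0))
    stop("atoms_to_density: zero or negative B-factor (Gaussian width undefined)",
         call. = FALSE)
  n <- spec$shape
  A <- frac_to_cart_matrix(spec)
  Ainv <- solve(A)
  rho <- array(0, dim = n)
  z <- element_number(atoms$element)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  fr_atoms <- pos %*% t(Ainv)
  s2 <- atoms$b / (8 * pi^2)
  s <- sqrt(s2)
  amp <- atoms$occ * z * (2 * pi * s2)^(-1.5)
  cutoff <- 4 * s
  dfrac_unit <- sqrt(rowSums(Ainv^2))   # frac half-width per A, per axis
  for (i in seq_len(nrow(pos))) {
    fa <- fr_atoms[i, ]
    dfrac <- cutoff[i] * dfrac_unit
    gx <- floor((fa[1] - dfrac[1]) * n[1]):ceiling((fa[1] + dfrac[1]) * n[1])
    gy <- floor((fa[2] - dfrac[2]) * n[2]):ceiling((fa[2] + dfrac[2]) * n[2])
    gz <- floor((fa[3] - dfrac[3]) * n[3]):ceiling((fa[3] + dfrac[3]) * n[3])
    d1 <- rep(gx / n[1] - fa[1], times = length(gy) * length(gz))
    d2 <- rep(rep(gy / n[2] - fa[2], each = length(gx)), times = length(gz))
    d3 <- rep(gz / n[3] - fa[3], each = length(gx) * length(gy))
    dc2 <- rowSums((cbind(d1, d2, d3) %*% t(A))^2)
    keep <- dc2 <= cutoff[i]^2
    if (!any(keep)) next
    ix <- rep(gx %% n[1], times = length(gy) * length(gz))[keep]
    iy <- rep(rep(gy %% n[2], each = length(gx)), times = length(gz))[keep]
    iz <- rep(gz %% n[3], each = length(gx) * length(gy))[keep]
    idx <- 1 + ix + n[1] * (iy + n[2] * iz)
    contrib <- amp[i] * exp(-dc2[keep] / (2 * s2[i]))
    # accumulate; duplicated idx can occur when the box wraps a small cell
    acc <- rowsum(contrib, idx)
    rho[as.integer(rownames(acc))] <- rho[as.integer(rownames(acc))] + acc[, 1]
  }
  voxel_grid(rho, spec, unit_label = "raw")
}

#' Synthetic crystal structure with binding sites
#'
#' Defines the two crystal states the generator superposes: a ground-state
#' atom set (protein plus any ordered solvent) and, per binding site, a
#' bound state in which a ligand is present, site solvent atoms are expelled
#' (`displaced`) and protein atoms may adopt new positions (`moved`,
#' emulating a binding-stabilized conformational change). Ground and
#' bound-state densities are precomputed on construction.
#'
#' @param ground_atoms an [atom_records()] table for the unbound crystal.
#' @param spec a [grid_spec()].
#' @param sites list of binding sites; each is a list with elements
#'   `ligand` (an [atom_records()] table, may be empty for a null site),
#'   `displaced` (integer indices into `ground_atoms` absent in the bound
#'   state) and optional `moved` (data frame with columns `index`, `x`, `y`,
#'   `z` giving new positions for ground atoms).
#' @return an object of class `structure_spec` with precomputed fields
#'   `rho_ground`, `rho_bound` (one grid per site), `ligand_centroids` and
#'   `ligand_peak` (the maximum of the ligand-only densities, used to anchor
#'   relative noise levels).
#' @export
structure_spec <- function(ground_atoms, spec, sites = list()) {
  stopifnot(inherits(ground_atoms, "data.frame"), inherits(spec, "grid_spec"))
  for (s in sites) {
    if (!is.null(s$displaced) &&
        (any(s$displaced < 1) || any(s$displaced > nrow(ground_atoms))))
      stop("structure_spec: displaced indices out of range", call. = FALSE)
    if (!is.null(s$moved) &&
        (any(s$moved$index < 1) || any(s$moved$index > nrow(ground_atoms))))
      stop("structure_spec: moved indices out of range", call. = FALSE)
  }
  obj <- list(ground_atoms = ground_atoms, spec = spec, sites = sites)
  obj$rho_ground <- atoms_to_density(ground_atoms, spec)
  obj$rho_bound <- list()
  obj$ligand_centroids <- list()
  peak <- 0
  for (k in seq_along(sites)) {
    bound <- bound_state_atoms(obj, k)
    obj$rho_bound[[k]] <- atoms_to_density(bound, spec)
    lig <- sites[[k]]$ligand
    if (!is.null(lig) && nrow(lig) > 0) {
      obj$ligand_centroids[[k]] <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
      peak <- max(peak, max(atoms_to_density(lig, spec)$values))
    }
  }
  obj$ligand_peak <- peak
  class(obj) <- "structure_spec"
  obj
}

#' Atom table of the bound state at one site
#'
#' @param structure a [structure_spec()].
#' @param site site index.
#' @return an [atom_records()] table: ground atoms minus displaced ones,
#'   with moved atoms repositioned, plus the site's ligand.
#' @export
bound_state_atoms <- function(structure, site = 1) {
  s <- structure$sites[[site]]
  at <- structure$ground_atoms
  if (!is.null(s$moved) && nrow(s$moved) > 0) {
    at[s$moved$index, c("x", "y", "z")] <- s$moved[, c("x", "y", "z")]
  }
  if (!is.null(s$displaced) && length(s$displaced) > 0)
    at <- at[-s$displaced, , drop = FALSE]
  if (!is.null(s$ligand) && nrow(s$ligand) > 0)
    at <- rbind(at, s$ligand)
  class(at) <- c("atom_records", "data.frame")
  at
}

# Deterministic pseudo-protein: atoms packed into a sphere with a minimum
# contact distance, plus carved pockets. Internal helper for demo_structure.
pack_protein_atoms <- function(n_atoms, centre, radius, min_dist, seed) {
  with_seed(seed, {
    pos <- matrix(NA_real_, nrow = n_atoms, ncol = 3)
    got <- 0L
    tries <- 0L
    while (got < n_atoms && tries < n_atoms * 400L) {
      tries <- tries + 1L
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      p <- centre + radius * u
      if (got > 0) {
        d2 <- colSums((t(pos[seq_len(got), , drop = FALSE]) - p)^2)
        if (min(d2) < min_dist^2) next
      }
      got <- got + 1L
      pos[got, ] <- p
    }
    pos[seq_len(got), , drop = FALSE]
  })
}

# A 12-atom fragment-like ligand: 6-membered ring plus substituents, rotated
# by a deterministic orientation and translated to `centre`.
make_ligand_atoms <- function(centre, seed, b = 20) {
  with_seed(seed, {
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- cbind(1.3 * cos(ang), 1.3 * sin(ang), 0)
    subs <- cbind(2.0 * cos(ang[c(1, 3, 5)]), 2.0 * sin(ang[c(1, 3, 5)]),
                  c(0.4, -0.4, 0.4))
    apex <- rbind(c(0, 0, 1.1), c(0.6, 0.6, -1.1), c(-0.8, 0.3, 1.0))
    xyz <- rbind(ring, subs, apex)
    # random rotation (QR of a Gaussian matrix)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    xyz <- xyz %*% Q
    xyz <- sweep(xyz, 2, centre, `+`)
    elem <- c(rep("C", 6), "N", "O", "O", "C", "C", "N")
    atom_records(elem, xyz, b = b, occ = 1, residue = "LIG")
  })
}

#' Standard synthetic crystal fixture
#'
#' Builds a deterministic desk-scale crystal form: a 32 Angstrom cubic P1
#' cell sampled on a 64^3 grid (0.5 Angstrom spacing) containing a ~300-atom
#' pseudo-protein globule with `n_sites` carved binding pockets. Each
#' pocket's bound state places a 12-atom fragment-like ligand in the pocket
#' void and swings the pocket-lining protein atoms nearest the site outward
#' by ~2 Angstrom -- a binding-stabilized local conformational change, so
#' that a binding event both adds density (the ligand) and removes
#' ground-state density (the old side-chain positions), as in a real soak.
#' Site 1 can optionally exhibit a larger ~20-atom rearrangement emulating
#' the movement of a whole terminal helix.
#'
#' The same fixture is returned on every call (the construction is
#' internally seeded): it plays the role of the single shared crystal form
#' that a fragment screen re-measures many times. Hits are spread across
#' the pockets, mimicking the many-sites pattern of real screens and
#' keeping the per-voxel contamination of the ground-state model low.
#'
#' @param n_sites number of binding pockets (default 6).
#' @param grid_points grid points per axis (default 64).
#' @param cell_edge cubic cell edge in Angstrom (default 32).
#' @param conformational_change if `TRUE`, site 1's bound state moves the 20
#'   protein atoms nearest the pocket instead of the default 6.
#' @return a [structure_spec()].
#' @export
demo_structure <- function(n_sites = 6, grid_points = 64, cell_edge = 32,
                           conformational_change = FALSE) {
  spec <- grid_spec(rep(grid_points, 3), rep(cell_edge, 3))
  centre <- rep(cell_edge / 2, 3)
  prot_radius <- 0.36 * cell_edge
  pos <- pack_protein_atoms(320, centre, prot_radius, 1.5, seed = 871001L)
  # fixed pocket directions: vertices of an octahedron plus cube diagonals
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                c(1, 1, 1) / sqrt(3), c(-1, -1, 1) / sqrt(3))
  if (n_sites > nrow(dirs))
    stop("demo_structure: at most ", nrow(dirs), " sites supported", call. = FALSE)
  site_centres <- sweep(0.72 * prot_radius * dirs[seq_len(n_sites), , drop = FALSE],
                        2, centre, `+`)
  # carve pocket voids out of the globule
  keep <- rep(TRUE, nrow(pos))
  for (k in seq_len(n_sites)) {
    d2 <- colSums((t(pos) - site_centres[k, ])^2)
    keep <- keep & d2 > 3.4^2
  }
  pos <- pos[keep, , drop = FALSE]
  elem <- with_seed(871002L, sample(c("C", "N", "O", "S"), nrow(pos),
                                    replace = TRUE, prob = c(0.64, 0.17, 0.16, 0.03)))
  bfac <- with_seed(871003L, stats::runif(nrow(pos), 15, 30))
  ground <- atom_records(elem, pos, b = bfac, occ = 1, residue = "PRO")

  sites <- lapply(seq_len(n_sites), function(k) {
    n_move <- if (conformational_change && k == 1L) 20L else 6L
    d2 <- colSums((t(pos) - site_centres[k, ])^2)
    near <- order(d2)[seq_len(min(n_move, nrow(pos)))]
    out_dir <- t(t(pos[near, , drop = FALSE]) - site_centres[k, ])
    out_dir <- out_dir / sqrt(rowSums(out_dir^2))
    moved <- data.frame(index = near,
                        pos[near, , drop = FALSE] + 2.0 * out_dir)
    names(moved) <- c("index", "x", "y", "z")
    list(ligand = make_ligand_atoms(site_centres[k, ], seed = 871010L + k),
         displaced = integer(0),
         moved = moved)
  })
  structure_spec(ground, spec, sites)
}

#' Simulate one dataset's density map
#'
#' The observed map of a crystal in which a fraction `occupancy` of unit
#' cells is in the bound state of `site`:
#' `scale * ((1 - occupancy) * rho_ground + occupancy * rho_bound) + noise`,
#' with iid Gaussian voxel noise of standard deviation `noise_sd`.
#' Deterministic for a fixed `seed`.
#'
#' @param structure a [structure_spec()].
#' @param occupancy bound-state occupancy in `[0, 1]`.
#' @param noise_sd per-voxel noise standard deviation (map units).
#' @param scale overall map scale factor.
#' @param seed integer seed for the noise draw (required if `noise_sd > 0`).
#' @param site which binding site's bound state to use.
#' @return a [voxel_grid()].
#' @export
simulate_dataset <- function(structure, occupancy, noise_sd = 0, scale = 1,
                             seed = NULL, site = 1) {
  stopifnot(inherits(structure, "structure_spec"))
  if (occupancy < 0 || occupancy > 1)
    stop("simulate_dataset: occupancy must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("simulate_dataset: noise_sd must be >= 0", call. = FALSE)
  vals <- (1 - occupancy) * structure$rho_ground$values
  if (occupancy > 0) {
    if (site < 1 || site > length(structure$rho_bound))
      stop("simulate_dataset: no such site: ", site, call. = FALSE)
    vals <- vals + occupancy * structure$rho_bound[[site]]$values
  } else if (occupancy == 0) {
    # nothing to add: the unbound crystal
  }
  vals <- scale * vals
  if (noise_sd > 0) {
    if (is.null(seed)) stop("simulate_dataset: seed required when noise_sd > 0",
                            call. = FALSE)
    vals <- vals + with_seed(seed, stats::rnorm(length(vals), 0, noise_sd))
  }
  voxel_grid(array(vals, dim = structure$spec$shape), structure$spec, "raw")
}

#' Screen-level simulation parameters
#'
#' Defaults mirror the screen scenario the pipeline is designed for: 226
#' soaked crystals of one crystal form with 24 true binders, binding with
#' occupancies drawn uniformly from `[0.3, 0.9]`, per-voxel noise of 10% of
#' the ligand's peak density, and a small per-dataset scale jitter standing
#' in for residual scaling differences between datasets.
#'
#' @param n_datasets number of datasets in the screen.
#' @param hit_fraction fraction of datasets that contain a bound ligand.
#' @param occupancy_range length-2 range from which hit occupancies are
#'   drawn uniformly.
#' @param noise_sd per-voxel noise sd in map units; `NULL` (default) resolves
#'   at simulation time to 10% of the structure's ligand peak density.
#' @param per_dataset_scale_jitter sd of the multiplicative scale factor
#'   around 1 applied per dataset.
#' @param seed integer seed controlling hit assignment, occupancies, scales
#'   and noise.
#' @return an object of class `screen_spec`.
#' @export
screen_spec <- function(n_datasets = 226, hit_fraction = 24 / 226,
                        occupancy_range = c(0.3, 0.9), noise_sd = NULL,
                        per_dataset_scale_jitter = 0.02, seed = 1) {
  if (n_datasets < 1) stop("screen_spec: n_datasets must be >= 1", call. = FALSE)
  if (hit_fraction < 0 || hit_fraction > 1)
    stop("screen_spec: hit_fraction must lie in [0, 1]", call. = FALSE)
  if (length(occupancy_range) != 2 || occupancy_range[1] > occupancy_range[2] ||
      occupancy_range[1] <= 0 || occupancy_range[2] > 1)
    stop("screen_spec: occupancy_range must be (low, high) within (0, 1]", call. = FALSE)
  structure(list(n_datasets = as.integer(n_datasets),
                 hit_fraction = hit_fraction,
                 occupancy_range = as.numeric(occupancy_range),
                 noise_sd = noise_sd,
                 per_dataset_scale_jitter = per_dataset_scale_jitter,
                 seed = as.integer(seed)),
            class = "screen_spec")
}

#' Simulate a full synthetic fragment screen
#'
#' Generates `n_datasets` density maps of the same crystal form. The first
#' `round(hit_fraction * n_datasets)` positions of a seeded shuffle become
#' hits; hits are assigned to the structure's binding sites in rotation and
#' receive occupancies drawn uniformly from `occupancy_range`; all other
#' datasets are unbound. Each dataset's noise field is drawn from the
#' sub-seed `seed + dataset index`, so any single dataset can be regenerated
#' independently. Dataset metadata (resolution, R factors) is drawn from
#' ranges typical of a well-behaved fragment-screen crystal system.
#'
#' @param structure a [structure_spec()] with at least one binding site (or
#'   none, for a pure null screen).
#' @param screen a [screen_spec()].
#' @return a list of class `synthetic_screen` with elements `datasets`
#'   (list of [crystal_dataset()]), `truth` (data frame: `id`, `is_hit`,
#'   `true_occupancy`, `site`, ligand centroid `cx`, `cy`, `cz`),
#'   `structure` and `screen`.
#' @export
simulate_screen <- function(structure, screen) {
  stopifnot(inherits(structure, "structure_spec"), inherits(screen, "screen_spec"))
  n <- screen$n_datasets
  n_hits <- round(screen$hit_fraction * n)
  if (n_hits > 0 && length(structure$sites) == 0)
    stop("simulate_screen: structure has no binding sites but hit_fraction > 0",
         call. = FALSE)
  noise_sd <- screen$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0.1 * structure$ligand_peak
  meta <- with_seed(screen$seed, {
    ord <- sample.int(n)
    hit_idx <- sort(ord[seq_len(n_hits)])
    is_hit <- seq_len(n) %in% hit_idx
    site <- integer(n)
    site[hit_idx] <- rep_len(seq_along(structure$sites), n_hits)
    occ <- numeric(n)
    occ[hit_idx] <- stats::runif(n_hits, screen$occupancy_range[1],
                                 screen$occupancy_range[2])
    scl <- pmax(0.5, 1 + stats::rnorm(n, 0, screen$per_dataset_scale_jitter))
    list(is_hit = is_hit, site = site, occ = occ, scale = scl,
         resolution = round(stats::runif(n, 1.14, 1.97), 2),
         r_work = round(stats::runif(n, 0.125, 0.162), 3),
         r_free_gap = round(stats::runif(n, 0.025, 0.055), 3))
  })
  ids <- sprintf("x%03d", seq_len(n))
  datasets <- vector("list", n)
  cent <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    g <- simulate_dataset(structure,
                          occupancy = meta$occ[i],
                          noise_sd = noise_sd,
                          scale = meta$scale[i],
                          seed = screen$seed + i,
                          site = if (meta$is_hit[i]) meta$site[i] else 1)
    datasets[[i]] <- crystal_dataset(ids[i], g,
                                     resolution = meta$resolution[i],
                                     r_work = meta$r_work[i],
                                     r_free = meta$r_work[i] + meta$r_free_gap[i],
                                     spacegroup = "P 1")
    if (meta$is_hit[i])
      cent[i, ] <- structure$ligand_centroids[[meta$site[i]]]
  }
  truth <- data.frame(id = ids, is_hit = meta$is_hit,
                      true_occupancy = meta$occ, site = meta$site,
                      cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
                      stringsAsFactors = FALSE)
  out <- list(datasets = datasets, truth = truth,
              structure = structure, screen = screen, noise_sd = noise_sd)
  class(out) <- "synthetic_screen"
  out
}

#' Write a simulated screen to a directory tree
#'
#' Lays out the screen exactly as the analysis entry points consume it:
#' one `dataset_<id>/` directory per dataset holding `map.ccp4` and
#' `meta.json`, plus `truth.csv` and `screen_spec.json` at the top level.
#'
#' @param sim a [simulate_screen()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_screen <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in sim$datasets) {
    dd <- file.path(dir, paste0("dataset_", d$id))
    dir.create(dd, showWarnings = FALSE)
    write_density_map(d$grid, file.path(dd, "map.ccp4"))
    jsonlite::write_json(list(id = d$id, resolution = d$resolution,
                              r_work = d$r_work, r_free = d$r_free,
                              spacegroup = d$spacegroup),
                         file.path(dd, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- sim$screen
  sp$noise_sd <- sim$noise_sd
  jsonlite::write_json(unclass(sp), file.path(dir, "screen_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a screen directory into a list of datasets
#'
#' Discovers `dataset_*/map.ccp4` subdirectories (optionally with
#' `meta.json` metadata) and loads them.
#'
#' @param dir screen directory as produced by [write_screen()].
#' @return list of [crystal_dataset()].
#' @export
read_screen <- function(dir) {
  dds <- sort(list.dirs(dir, recursive = FALSE))
  dds <- dds[grepl("^dataset_", basename(dds))]
  if (length(dds) == 0)
    stop("read_screen: no dataset_* subdirectories under ", dir, call. = FALSE)
  lapply(dds, function(dd) {
    id <- sub("^dataset_", "", basename(dd))
    g <- read_density_map(file.path(dd, "map.ccp4"))
    meta <- list(resolution = NA_real_, r_work = NA_real_, r_free = NA_real_,
                 spacegroup = "P 1")
    mf <- file.path(dd, "meta.json")
    if (file.exists(mf)) {
      m <- jsonlite::read_json(mf, simplifyVector = TRUE)
      meta[names(m)[names(m) %in% names(meta)]] <- m[names(m) %in% names(meta)]
    }
    crystal_dataset(id, g, resolution = meta$resolution, r_work = meta$r_work,
                    r_free = meta$r_free, spacegroup = meta$spacegroup)
  })
}
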