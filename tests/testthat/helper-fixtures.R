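# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Desk-scale crystal for unit tests: 24 A cell, 48^3 grid, two pockets.
test_structure <- function() memo("test_structure",
  demo_structure(n_sites = 2, grid_points = 48, cell_edge = 24))

# The standard fixture used by the acceptance-level checks.
accept_structure <- function() memo("accept_structure", demo_structure())

# A small deterministic density field with some structure.
bumpy_grid <- function(spec = grid_spec(c(16, 16, 16), c(8, 8, 8)), seed = 42) {
  vals <- with_test_seed(seed, array(stats::rnorm(prod(spec$shape)), spec$shape))
  voxel_grid(vals, spec)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Oracle: exhaustive per-voxel minimum-image distance check for sphere masks.
brute_sphere_mask <- function(atoms, radius, spec) {
  n <- spec$shape
  A <- frac_to_cart_matrix(spec)
  Ainv <- solve(A)
  fr_atoms <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(Ainv)
  mask <- array(FALSE, n)
  for (iz in seq_len(n[3])) for (iy in seq_len(n[2])) for (ix in seq_len(n[1])) {
    fv <- c((ix - 1) / n[1], (iy - 1) / n[2], (iz - 1) / n[3])
    df <- sweep(fr_atoms, 2, fv)
    df <- df - round(df)
    d2 <- rowSums((df %*% t(A))^2)
    mask[ix, iy, iz] <- any(d2 <= radius^2)
  }
  mask
}

# Oracle: breadth-first flood fill of z >= threshold voxels, 26-neighbour,
# periodic; returns a list of integer matrices of 1-based voxel indices.
brute_components <- function(zvals, threshold, spec) {
  n <- spec$shape
  above <- which(zvals >= threshold)
  if (length(above) == 0) return(list())
  lab <- integer(length(zvals))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  comp <- list()
  for (start in above) {
    if (lab[start] > 0) next
    id <- length(comp) + 1L
    queue <- start
    lab[start] <- id
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      v0 <- v - 1L
      cx <- v0 %% n[1]; cy <- (v0 %/% n[1]) %% n[2]; cz <- v0 %/% (n[1] * n[2])
      for (k in seq_len(nrow(offs))) {
        w <- 1L + (cx + offs[k, 1]) %% n[1] +
          n[1] * ((cy + offs[k, 2]) %% n[2] + n[2] * ((cz + offs[k, 3]) %% n[3]))
        if (zvals[w] >= threshold && lab[w] == 0L) {
          lab[w] <- id
          queue <- c(queue, w)
        }
      }
    }
    v0 <- members - 1L
    comp[[id]] <- cbind(ix = v0 %% n[1] + 1L,
                        iy = (v0 %/% n[1]) %% n[2] + 1L,
                        iz = v0 %/% (n[1] * n[2]) + 1L)
  }
  comp
}

# Oracle: single-linkage grouping = connected components of the
# distance <= cutoff graph, via union-find.
brute_single_linkage <- function(points, cutoff, spec = NULL) {
  np <- nrow(points)
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    d <- if (is.null(spec)) sqrt(sum((points[i, ] - points[j, ])^2))
    else {
      A <- frac_to_cart_matrix(spec)
      df <- solve(A) %*% (points[i, ] - points[j, ])
      df <- df - round(df)
      sqrt(sum((A %*% df)^2))
    }
    if (d <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(np), find, integer(1))
}

# Write a constant-valued CCP4 map through gemmi (independent third-party
# writer, pre-installed in the environment's python).
gemmi_write_constant_map <- function(path, shape, cell, value) {
  py <- tempfile(fileext = ".py")
  writeLines(sprintf(paste0(
    "import gemmi, numpy as np\n",
    "m = gemmi.Ccp4Map()\n",
    "m.grid = gemmi.FloatGrid(np.full((%d, %d, %d), %.17g, dtype=np.float32))\n",
    "m.grid.unit_cell = gemmi.UnitCell(%.17g, %.17g, %.17g, 90, 90, 90)\n",
    "m.grid.spacegroup = gemmi.find_spacegroup_by_name('P1')\n",
    "m.update_ccp4_header()\n",
    "m.write_ccp4_map(r'%s')\n"),
    shape[1], shape[2], shape[3], value, cell[1], cell[2], cell[3], path), py)
  status <- system2("python", py, stdout = TRUE, stderr = TRUE)
  unlink(py)
  invisible(status)
}

# Parse a CCP4 header through gemmi and return cell lengths and a probe value.
gemmi_probe_map <- function(path) {
  py <- tempfile(fileext = ".py")
  writeLines(sprintf(paste0(
    "import gemmi\n",
    "g = gemmi.read_ccp4_map(r'%s')\n",
    "c = g.grid.unit_cell\n",
    "print(c.a, c.b, c.c, g.grid.nu, g.grid.nv, g.grid.nw, g.grid.get_value(1, 2, 3))\n"),
    path), py)
  out <- system2("python", py, stdout = TRUE, stderr = TRUE)
  unlink(py)
  as.numeric(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
}
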