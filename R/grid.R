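#' Crystallographic grid specification
#'
#' A `grid_spec` describes the voxel grid on which a density map is sampled:
#' the number of grid points along each unit-cell axis, the cell lengths and
#' the cell angles. Grids are always interpreted as covering one full unit
#' cell in P1, with grid point `(i, j, k)` (1-based) sitting at fractional
#' coordinates `((i-1)/nx, (j-1)/ny, (k-1)/nz)` and periodic boundary
#' conditions along every axis.
#'
#' @param shape integer vector of length 3: grid points along a, b, c.
#' @param cell_lengths numeric vector of length 3: a, b, c in Angstrom.
#' @param cell_angles numeric vector of length 3: alpha, beta, gamma in
#'   degrees. Defaults to an orthogonal cell.
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(c(64, 64, 64), c(32, 32, 32))
#' voxel_spacing(spec)
#' @export
grid_spec <- function(shape, cell_lengths, cell_angles = c(90, 90, 90)) {
  shape <- as.integer(shape)
  cell_lengths <- as.numeric(cell_lengths)
  cell_angles <- as.numeric(cell_angles)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 2L))
    stop("grid_spec: 'shape' must be 3 integers, all >= 2", call. = FALSE)
  if (length(cell_lengths) != 3L || anyNA(cell_lengths) || any(cell_lengths <= 0))
    stop("grid_spec: 'cell_lengths' must be 3 positive reals", call. = FALSE)
  if (length(cell_angles) != 3L || anyNA(cell_angles) ||
      any(cell_angles <= 0) || any(cell_angles >= 180))
    stop("grid_spec: 'cell_angles' must lie in (0, 180) degrees", call. = FALSE)
  structure(list(shape = shape,
                 cell_lengths = cell_lengths,
                 cell_angles = cell_angles),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d points, cell %.2f %.2f %.2f A, angles %.1f %.1f %.1f deg\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$cell_lengths[1], x$cell_lengths[2], x$cell_lengths[3],
              x$cell_angles[1], x$cell_angles[2], x$cell_angles[3]))
  invisible(x)
}

#' Voxel spacing along each cell axis
#'
#' @param spec a [grid_spec()].
#' @return numeric length-3 vector of spacings in Angstrom.
#' @export
voxel_spacing <- function(spec) spec$cell_lengths / spec$shape

#' Volume of one voxel in cubic Angstrom
#'
#' Uses the full triclinic cell volume divided by the number of grid points.
#'
#' @param spec a [grid_spec()].
#' @return voxel volume in Angstrom^3.
#' @export
voxel_volume <- function(spec) {
  ca <- cospi(spec$cell_angles / 180)
  v <- sqrt(max(0, 1 - sum(ca^2) + 2 * prod(ca)))
  prod(spec$cell_lengths) * v / prod(spec$shape)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard crystallographic convention: a along x, b in the xy plane.
#'
#' @param spec a [grid_spec()].
#' @return 3x3 matrix `A` such that `cart = A %*% frac`.
#' @export
frac_to_cart_matrix <- function(spec) {
  len <- spec$cell_lengths
  # cospi/sinpi make right angles exact (cos 90 == 0 bit-for-bit)
  ca <- cospi(spec$cell_angles / 180); sa <- sinpi(spec$cell_angles / 180)
  v <- sqrt(max(0, 1 - sum(ca^2) + 2 * prod(ca)))
  matrix(c(len[1], len[2] * ca[3], len[3] * ca[2],
           0,      len[2] * sa[3], len[3] * (ca[1] - ca[2] * ca[3]) / sa[3],
           0,      0,              len[3] * v / sa[3]),
         nrow = 3, byrow = TRUE)
}

#' @rdname frac_to_cart_matrix
#' @export
cart_to_frac_matrix <- function(spec) solve(frac_to_cart_matrix(spec))

same_spec <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$cell_lengths - b$cell_lengths) < tol * pmax(1, a$cell_lengths)) &&
    all(abs(a$cell_angles - b$cell_angles) < 1e-6)
}

#' Voxel grid: a scalar density field on a crystallographic grid
#'
#' The universal data container of the pipeline: a 3-D array of density
#' values together with its [grid_spec()]. Values are stored with axis order
#' normalized to (fast = x, medium = y, slow = z); file axis permutations are
#' resolved by [read_density_map()].
#'
#' @param values numeric 3-D array whose dimensions equal `spec$shape`.
#' @param spec a [grid_spec()].
#' @param unit_label free-text unit tag, conventionally `"raw"` for map units
#'   as read from file and `"sigma"` after [sigma_scale()].
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spec, unit_label = "raw") {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(dim(values))) dim(values) <- spec$shape
  if (!all(dim(values) == spec$shape))
    stop("voxel_grid: values dimensions do not match spec$shape", call. = FALSE)
  if (!all(is.finite(values)))
    stop("voxel_grid: all values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spec = spec, unit_label = unit_label),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid [%s]: %d x %d x %d, range [%.4g, %.4g], mean %.4g\n",
              x$unit_label, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values), mean(x$values)))
  print(x$spec)
  invisible(x)
}

# Cartesian coordinates of every voxel centre, as an N x 3 matrix in the
# grid's storage order (x fastest).
voxel_cart_coords <- function(spec) {
  n <- spec$shape
  fr <- cbind(rep((seq_len(n[1]) - 1) / n[1], times = n[2] * n[3]),
              rep(rep((seq_len(n[2]) - 1) / n[2], each = n[1]), times = n[3]),
              rep((seq_len(n[3]) - 1) / n[3], each = n[1] * n[2]))
  fr %*% t(frac_to_cart_matrix(spec))
}

#' Trilinear interpolation of a voxel grid at fractional coordinates
#'
#' Interpolates with periodic wrapping, so coordinates outside `[0, 1)` are
#' valid. Exact on fields that are trilinear in fractional coordinates.
#'
#' @param grid a [voxel_grid()].
#' @param frac N x 3 matrix of fractional coordinates.
#' @return numeric vector of N interpolated values.
#' @export
interpolate_trilinear <- function(grid, frac) {
  frac <- matrix(as.numeric(frac), ncol = 3)
  n <- grid$spec$shape
  v <- grid$values
  out <- 0
  u <- sweep(frac, 2, n, `*`)         # continuous grid index, node i at u = i-1
  i0 <- floor(u)
  t3 <- u - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t3[, 1] else 1 - t3[, 1]) *
         (if (dy) t3[, 2] else 1 - t3[, 2]) *
         (if (dz) t3[, 3] else 1 - t3[, 3])
    ix <- (i0[, 1] + dx) %% n[1]
    iy <- (i0[, 2] + dy) %% n[2]
    iz <- (i0[, 3] + dz) %% n[3]
    out <- out + w * v[1 + ix + n[1] * (iy + n[2] * iz)]
  }
  out
}

#' Resample a map onto a reference grid
#'
#' Reconciles residual grid differences between near-isomorphous datasets:
#' the map is evaluated at every voxel of `reference` by trilinear
#' interpolation in fractional coordinates with periodic wrapping. Cells must
#' agree within `tolerance` (relative, on lengths and angles); larger
#' deviations indicate a different crystal form and raise an error.
#'
#' @param grid a [voxel_grid()].
#' @param reference target [grid_spec()].
#' @param tolerance maximum relative cell deviation (default 0.02).
#' @return a [voxel_grid()] on `reference`.
#' @export
resample_onto <- function(grid, reference, tolerance = 0.02) {
  stopifnot(inherits(reference, "grid_spec"))
  rel_len <- abs(grid$spec$cell_lengths - reference$cell_lengths) / reference$cell_lengths
  rel_ang <- abs(grid$spec$cell_angles - reference$cell_angles) / reference$cell_angles
  if (any(c(rel_len, rel_ang) > tolerance)) {
    bad <- c(sprintf("a/b/c deviation %.3f/%.3f/%.3f", rel_len[1], rel_len[2], rel_len[3]),
             sprintf("angle deviation %.3f/%.3f/%.3f", rel_ang[1], rel_ang[2], rel_ang[3]))
    stop("resample_onto: cells are not isomorphous within tolerance ",
         tolerance, " (", paste(bad, collapse = "; "), ")", call. = FALSE)
  }
  if (identical(grid$spec$shape, reference$shape) &&
      all(grid$spec$cell_lengths == reference$cell_lengths) &&
      all(grid$spec$cell_angles == reference$cell_angles))
    return(voxel_grid(grid$values, reference, grid$unit_label))
  n <- reference$shape
  fr <- cbind(rep((seq_len(n[1]) - 1) / n[1], times = n[2] * n[3]),
              rep(rep((seq_len(n[2]) - 1) / n[2], each = n[1]), times = n[3]),
              rep((seq_len(n[3]) - 1) / n[3], each = n[1] * n[2]))
  voxel_grid(array(interpolate_trilinear(grid, fr), dim = n),
             reference, grid$unit_label)
}

#' Sigma-scale a map
#'
#' Standardizes the map so that it has mean 0 and standard deviation 1 over
#' the mask region (the whole grid if no mask is given), the convention under
#' which maps are contoured in sigma units.
#'
#' @param grid a [voxel_grid()].
#' @param mask optional logical array of the same shape; statistics are
#'   computed over `TRUE` voxels but the whole grid is transformed.
#' @return a [voxel_grid()] with `unit_label = "sigma"`.
#' @export
sigma_scale <- function(grid, mask = NULL) {
  v <- grid$values
  sel <- if (is.null(mask)) v else {
    stopifnot(all(dim(mask) == dim(v)))
    if (!any(mask)) stop("sigma_scale: empty mask", call. = FALSE)
    v[mask]
  }
  m <- mean(sel)
  s <- stats::sd(sel)
  if (!is.finite(s) || s == 0)
    stop("sigma_scale: degenerate map (zero variance over mask)", call. = FALSE)
  voxel_grid((v - m) / s, grid$spec, unit_label = "sigma")
}

#' Boolean mask of voxels within a radius of any atom
#'
#' A voxel is selected iff its centre lies within `radius` of any atom
#' position under periodic (minimum-image) distance. An empty atom table
#' yields an all-`FALSE` mask.
#'
#' @param atoms an atom table (see [atom_records()]): needs columns x, y, z.
#' @param radius sphere radius in Angstrom (> 0).
#' @param spec a [grid_spec()].
#' @return logical array of shape `spec$shape`.
#' @export
sphere_mask <- function(atoms, radius, spec) {
  if (radius <= 0) stop("sphere_mask: radius must be > 0", call. = FALSE)
  n <- spec$shape
  mask <- array(FALSE, dim = n)
  if (is.null(atoms) || nrow(atoms) == 0L) return(mask)
  A <- frac_to_cart_matrix(spec)
  Ainv <- solve(A)
  # conservative fractional half-widths of the bounding box of a sphere
  dfrac <- radius * sqrt(rowSums(Ainv^2))
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  fr_atoms <- pos %*% t(Ainv)
  r2 <- radius^2
  for (i in seq_len(nrow(pos))) {
    fa <- fr_atoms[i, ]
    rng <- lapply(1:3, function(j) {
      lo <- floor((fa[j] - dfrac[j]) * n[j])
      hi <- ceiling((fa[j] + dfrac[j]) * n[j])
      lo:hi
    })
    gx <- rng[[1]]; gy <- rng[[2]]; gz <- rng[[3]]
    df1 <- gx / n[1] - fa[1]
    df2 <- gy / n[2] - fa[2]
    df3 <- gz / n[3] - fa[3]
    d1 <- rep(df1, times = length(gy) * length(gz))
    d2 <- rep(rep(df2, each = length(gx)), times = length(gz))
    d3 <- rep(df3, each = length(gx) * length(gy))
    dc <- cbind(d1, d2, d3) %*% t(A)
    hit <- rowSums(dc^2) <= r2
    if (any(hit)) {
      ix <- rep(gx %% n[1], times = length(gy) * length(gz))[hit]
      iy <- rep(rep(gy %% n[2], each = length(gx)), times = length(gz))[hit]
      iz <- rep(gz %% n[3], each = length(gx) * length(gy))[hit]
      mask[1 + ix + n[1] * (iy + n[2] * iz)] <- TRUE
    }
  }
  mask
}

#' Gaussian low-pass filter of a map
#'
#' Convolves the map with an isotropic Gaussian of standard deviation
#' `width` Angstrom, implemented in reciprocal space (exact for the periodic
#' field). Used to band-limit maps to a common effective resolution before
#' statistical comparison; crystallographic maps are band-limited by
#' construction, so uncorrelated voxel noise at finer scales is unphysical
#' and is suppressed by this step.
#'
#' @param grid a [voxel_grid()].
#' @param width Gaussian sigma in Angstrom; `0` returns the input unchanged.
#' @return a smoothed [voxel_grid()].
#' @export
smooth_map <- function(grid, width) {
  if (width < 0) stop("smooth_map: width must be >= 0", call. = FALSE)
  if (width == 0) return(grid)
  n <- grid$spec$shape
  # reciprocal-space Gaussian: exp(-2 pi^2 w^2 |s|^2), s = h a* + k b* + l c*
  Bstar <- t(cart_to_frac_matrix(grid$spec))          # columns a*, b*, c*
  G <- crossprod(Bstar)                               # reciprocal metric
  h <- ifelse(seq_len(n[1]) - 1 > n[1] / 2, seq_len(n[1]) - 1 - n[1], seq_len(n[1]) - 1)
  k <- ifelse(seq_len(n[2]) - 1 > n[2] / 2, seq_len(n[2]) - 1 - n[2], seq_len(n[2]) - 1)
  l <- ifelse(seq_len(n[3]) - 1 > n[3] / 2, seq_len(n[3]) - 1 - n[3], seq_len(n[3]) - 1)
  H <- rep(h, times = n[2] * n[3])
  K <- rep(rep(k, each = n[1]), times = n[3])
  L <- rep(l, each = n[1] * n[2])
  s2 <- G[1, 1] * H^2 + G[2, 2] * K^2 + G[3, 3] * L^2 +
    2 * (G[1, 2] * H * K + G[1, 3] * H * L + G[2, 3] * K * L)
  filt <- array(exp(-2 * pi^2 * width^2 * s2), dim = n)
  sm <- Re(stats::fft(stats::fft(grid$values) * filt, inverse = TRUE)) / prod(n)
  voxel_grid(sm, grid$spec, grid$unit_label)
}

# Periodic minimum-image Cartesian distance between two points (rows of 3)
periodic_distance <- function(p, q, spec) {
  Ainv <- cart_to_frac_matrix(spec)
  A <- frac_to_cart_matrix(spec)
  df <- Ainv %*% (as.numeric(p) - as.numeric(q))
  df <- df - round(df)
  sqrt(sum((A %*% df)^2))
}
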