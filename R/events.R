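#' Detect candidate binding events in a Z-map
#'
#' Connected components (26-neighbour connectivity with periodic wrapping)
#' of voxels with `z >= threshold`, discarding components smaller than
#' `min_volume`. Components are returned in order of descending peak
#' z-score. The centroid is the z-weighted mean of the member voxel centres
#' in Cartesian Angstrom, computed with minimum-image wrapping about the
#' peak voxel so that clusters crossing the cell boundary are handled
#' correctly.
#'
#' @param zmap a [compute_z_map()] result (or a bare [voxel_grid()]).
#' @param threshold z-score detection threshold (> 0), default 2.5.
#' @param min_volume minimum component volume in Angstrom^3, default 5.
#' @param mask optional logical array restricting the search (e.g. the
#'   protein vicinity); voxels outside it are ignored.
#' @return list of `density_event` objects (fields `dataset_id`,
#'   `voxel_indices`, `centroid`, `peak_z`, `volume`, `bdc`,
#'   `occupancy_estimate`; the last two are `NA` until BDC estimation).
#' @export
find_events <- function(zmap, threshold = 2.5, min_volume = 5, mask = NULL) {
  if (threshold <= 0) stop("find_events: threshold must be > 0", call. = FALSE)
  if (min_volume < 0) stop("find_events: min_volume must be >= 0", call. = FALSE)
  grid <- if (inherits(zmap, "z_map")) zmap$grid else zmap
  dataset_id <- if (inherits(zmap, "z_map")) zmap$dataset_id else NA_character_
  n <- grid$spec$shape
  above <- grid$values >= threshold
  if (!is.null(mask)) above <- above & mask
  sel <- which(above)
  if (length(sel) == 0) return(list())
  # voxel coordinates (0-based) of selected voxels
  i0 <- sel - 1L
  ix <- i0 %% n[1]
  iy <- (i0 %/% n[1]) %% n[2]
  iz <- i0 %/% (n[1] * n[2])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    jx <- (ix + offs[k, 1]) %% n[1]
    jy <- (iy + offs[k, 2]) %% n[2]
    jz <- (iz + offs[k, 3]) %% n[3]
    nbr <- 1 + jx + n[1] * (jy + n[2] * jz)
    m <- match(nbr, sel)
    ok <- !is.na(m) & m > seq_along(sel)
    if (any(ok)) edges[[k]] <- cbind(which(ok), m[ok])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  vvol <- voxel_volume(grid$spec)
  A <- frac_to_cart_matrix(grid$spec)
  events <- list()
  for (cid in seq_len(max(comp))) {
    members <- which(comp == cid)
    if (length(members) * vvol < min_volume) next
    zi <- grid$values[sel[members]]
    fr <- cbind(ix[members] / n[1], iy[members] / n[2], iz[members] / n[3])
    peak <- which.max(zi)
    dfr <- sweep(fr, 2, fr[peak, ])
    dfr <- dfr - round(dfr)
    cfr <- fr[peak, ] + colSums(dfr * zi) / sum(zi)
    cfr <- cfr %% 1
    ev <- structure(list(dataset_id = dataset_id,
                         voxel_indices = cbind(ix = ix[members] + 1L,
                                               iy = iy[members] + 1L,
                                               iz = iz[members] + 1L),
                         centroid = as.numeric(A %*% cfr),
                         peak_z = max(zi),
                         volume = length(members) * vvol,
                         bdc = NA_real_,
                         occupancy_estimate = NA_real_),
                    class = "density_event")
    events[[length(events) + 1L]] <- ev
  }
  events[order(vapply(events, `[[`, numeric(1), "peak_z"), decreasing = TRUE)]
}

#' @export
print.density_event <- function(x, ...) {
  cat(sprintf("event [%s]: peak z %.2f, volume %.1f A^3, centroid (%.1f, %.1f, %.1f)",
              x$dataset_id, x$peak_z, x$volume,
              x$centroid[1], x$centroid[2], x$centroid[3]))
  if (!is.na(x$bdc))
    cat(sprintf(", BDC %.2f (occupancy estimate %.2f)", x$bdc, x$occupancy_estimate))
  cat("\n")
  invisible(x)
}

#' Dilate a boolean mask by a radius
#'
#' Periodic binary dilation with a spherical structuring element of the
#' given radius in Angstrom, implemented as an FFT convolution with a ball
#' kernel (the convolution counts mask voxels within the radius; any voxel
#' with a nonzero count is in the dilation).
#'
#' @param mask logical array.
#' @param radius dilation radius in Angstrom (`0` returns the input).
#' @param spec the mask's [grid_spec()].
#' @return logical array.
#' @export
dilate_mask <- function(mask, radius, spec) {
  if (radius <= 0) return(mask)
  n <- spec$shape
  A <- frac_to_cart_matrix(spec)
  kernel <- array(0, dim = n)
  ax <- lapply(1:3, function(j) {
    i <- seq_len(n[j]) - 1
    ifelse(i > n[j] / 2, i - n[j], i) / n[j]   # min-image fractional offsets
  })
  d1 <- rep(ax[[1]], times = n[2] * n[3])
  d2 <- rep(rep(ax[[2]], each = n[1]), times = n[3])
  d3 <- rep(ax[[3]], each = n[1] * n[2])
  dc2 <- rowSums((cbind(d1, d2, d3) %*% t(A))^2)
  kernel[dc2 <= radius^2] <- 1
  conv <- Re(stats::fft(stats::fft(array(as.numeric(mask), n)) *
                          stats::fft(kernel), inverse = TRUE)) / prod(n)
  array(conv > 0.5, dim = n)
}

# Mask of an event's member voxels, optionally dilated.
event_mask <- function(event, spec, dilate = 0) {
  m <- array(FALSE, dim = spec$shape)
  vi <- event$voxel_indices
  m[vi[, 1] + spec$shape[1] * (vi[, 2] - 1L + spec$shape[2] * (vi[, 3] - 1L))] <- TRUE
  if (dilate > 0) m <- dilate_mask(m, dilate, spec)
  m
}

#' Estimate the background density correction (BDC) factor
#'
#' Scans `b` over `{0, step, ..., 0.99}`, forming for each candidate the
#' background-subtracted map `obs - b * mean_map` and correlating it with
#' the ground-state mean over the local event region. The estimate is the
#' local decorrelation point,
#' \deqn{b^* = \arg\min_b \; | corr_{event}(b) |,}
#' the subtraction fraction at which the event region retains no residual
#' trace of the ground state: positive residual correlation means
#' under-subtraction, negative means over-subtraction. Because the
#' correlation's numerator is linear in `b` and voxel noise is uncorrelated
#' with the mean map, the crossing point is unbiased by noise; for an
#' occupancy-`q` superposition whose bound-state density is uncorrelated
#' with the ground state over the event region, `b* = 1 - q`, so `1 - b*`
#' estimates the bound-state occupancy. Ties break toward the smaller `b`.
#'
#' The scan is evaluated over the subset of the event region where density
#' was lost (`obs < mean_map`): those voxels are the ones whose ground-state
#' density is displaced by the bound state and therefore carries the
#' `(1 - occupancy)` background weight, whereas density-gain voxels carry
#' the new bound-state density, which is uninformative about the background
#' fraction and geometrically anti-correlated with the ground state (ligands
#' occupy voids). If fewer than 30 such voxels exist the full event region
#' is used.
#'
#' The reference region provides the complementary global diagnostic: the
#' subtracted map should still agree with the ground state away from the
#' event. Its correlation curve is returned alongside the local one, and a
#' flat local curve (no event signal, e.g. `obs` identical to the mean map)
#' raises a warning and sets the `flat_objective` attribute.
#'
#' Both maps can be low-pass filtered (`smooth_width`) before correlation;
#' with band-limited input (the analysis pipeline smooths on loading) this
#' is unnecessary and off by default.
#'
#' @param obs observed dataset map ([voxel_grid()]).
#' @param mean_map ground-state mean on the same spec.
#' @param event_mask logical array: the event region (cluster voxels,
#'   typically dilated by ~1.5 Angstrom).
#' @param reference_mask logical array: the global comparison region,
#'   disjoint from the event region (characterization mask minus the dilated
#'   event region).
#' @param step scan step (default 0.01, matching the two-decimal convention
#'   in which BDC values are reported).
#' @param smooth_width Gaussian presmoothing sigma in Angstrom (default 0;
#'   set to ~the map resolution/3 for raw unsmoothed maps).
#' @return `b*` in `[0, 0.99]`, with attributes `curve` (the scan table:
#'   `b`, `corr_ref`, `corr_event`, `objective`) and `flat_objective`.
#' @export
estimate_bdc <- function(obs, mean_map, event_mask, reference_mask,
                         step = 0.01, smooth_width = 0) {
  if (!any(event_mask) || !any(reference_mask))
    stop("estimate_bdc: empty mask", call. = FALSE)
  if (any(event_mask & reference_mask))
    stop("estimate_bdc: event and reference masks must be disjoint", call. = FALSE)
  if (smooth_width > 0) {
    obs <- smooth_map(obs, smooth_width)
    mean_map <- smooth_map(mean_map, smooth_width)
  }
  bs <- seq(0, 0.99, by = step)
  corr_scan <- function(mask) {
    o <- obs$values[mask]; m <- mean_map$values[mask]
    v_m <- stats::var(m)
    if (!is.finite(v_m) || v_m < .Machine$double.eps)
      stop("estimate_bdc: degenerate region (ground-state mean has no variance in a mask)",
           call. = FALSE)
    v_o <- stats::var(o)
    c_om <- stats::cov(o, m)
    cov_b <- c_om - bs * v_m
    var_b <- v_o - 2 * bs * c_om + bs^2 * v_m
    corr <- ifelse(var_b > 1e-12 * v_m, cov_b / sqrt(pmax(var_b, 0) * v_m), 0)
    pmin(1, pmax(-1, corr))
  }
  c_ref <- corr_scan(reference_mask)
  loss <- event_mask & (obs$values < mean_map$values)
  c_evt <- corr_scan(if (sum(loss) >= 30) loss else event_mask)
  objective <- -abs(c_evt)
  b_star <- bs[which.max(objective)]
  flat <- (max(objective) - min(objective)) < 1e-6
  if (flat)
    warning("estimate_bdc: flat objective; BDC is not determined for this region",
            call. = FALSE)
  structure(b_star,
            curve = data.frame(b = bs, corr_ref = c_ref, corr_event = c_evt,
                               objective = objective),
            flat_objective = flat)
}

#' Compute a background-corrected event map
#'
#' The partial-difference map approximating the bound state's density:
#' \deqn{E(x) = (\rho_{obs}(x) - b \, \mu(x)) / (1 - b)}
#'
#' @param obs observed map ([voxel_grid()]).
#' @param mean_map ground-state mean on the same spec.
#' @param bdc background density correction factor in `[0, 1)`.
#' @return a [voxel_grid()].
#' @export
compute_event_map <- function(obs, mean_map, bdc) {
  if (is.na(bdc) || bdc < 0 || bdc >= 1)
    stop("compute_event_map: bdc must lie in [0, 1)", call. = FALSE)
  if (!all(dim(obs$values) == dim(mean_map$values)))
    stop("compute_event_map: grids on different specs", call. = FALSE)
  voxel_grid((obs$values - bdc * mean_map$values) / (1 - bdc),
             obs$spec, obs$unit_label)
}

#' Group events into binding sites
#'
#' Single-linkage clustering of event centroids under periodic
#' (minimum-image) distance: events from different datasets that bind the
#' same locus merge into one multiply-occupied site. Sites are ordered by
#' descending member count; site centroids are the member means.
#'
#' @param events list of `density_event` objects (possibly across datasets).
#' @param cutoff single-linkage merge distance in Angstrom (default 5,
#'   a fragment-sized locus).
#' @param spec a [grid_spec()] supplying the periodic cell; defaults to an
#'   effectively aperiodic treatment when omitted.
#' @return list of `event_site` objects: `site_id`, `event_refs` (data frame
#'   with `dataset_id` and `event` index into `events`), `centroid`.
#' @export
group_into_sites <- function(events, cutoff = 5, spec = NULL) {
  if (cutoff <= 0) stop("group_into_sites: cutoff must be > 0", call. = FALSE)
  if (length(events) == 0) return(list())
  cent <- t(vapply(events, `[[`, numeric(3), "centroid"))
  nev <- nrow(cent)
  if (nev == 1L) {
    memb <- 1L
  } else {
    d <- matrix(0, nev, nev)
    for (i in seq_len(nev - 1)) for (j in (i + 1):nev) {
      d[i, j] <- d[j, i] <- if (is.null(spec))
        sqrt(sum((cent[i, ] - cent[j, ])^2))
      else periodic_distance(cent[i, ], cent[j, ], spec)
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    memb <- stats::cutree(hc, h = cutoff)
  }
  ids <- vapply(events, `[[`, character(1), "dataset_id")
  sites <- lapply(unique(memb), function(m) {
    members <- which(memb == m)
    pts <- cent[members, , drop = FALSE]
    if (!is.null(spec)) {
      Ainv <- cart_to_frac_matrix(spec); A <- frac_to_cart_matrix(spec)
      fr <- pts %*% t(Ainv)
      dfr <- sweep(fr, 2, fr[1, ]); dfr <- dfr - round(dfr)
      ctr <- as.numeric(A %*% ((fr[1, ] + colMeans(dfr)) %% 1))
    } else ctr <- colMeans(pts)
    structure(list(site_id = NA_integer_,
                   event_refs = data.frame(dataset_id = ids[members],
                                           event = members,
                                           stringsAsFactors = FALSE),
                   centroid = ctr),
              class = "event_site")
  })
  sites <- sites[order(vapply(sites, function(s) nrow(s$event_refs), integer(1)),
                       decreasing = TRUE)]
  for (i in seq_along(sites)) sites[[i]]$site_id <- i
  sites
}

#' Tabulate events (and their site assignments)
#'
#' @param events list of `density_event` objects.
#' @param sites optional [group_into_sites()] result used to attach a
#'   `site_id` column.
#' @return a data frame with one row per event: dataset id, event index
#'   within its dataset, centroid, peak z, volume, BDC, occupancy estimate
#'   and site id.
#' @export
events_to_table <- function(events, sites = NULL) {
  if (length(events) == 0)
    return(data.frame(dataset_id = character(), event = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      peak_z = numeric(), volume = numeric(),
                      bdc = numeric(), occupancy_estimate = numeric(),
                      site_id = integer(), stringsAsFactors = FALSE))
  ids <- vapply(events, `[[`, character(1), "dataset_id")
  ev_index <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  tab <- data.frame(dataset_id = ids, event = ev_index,
                    x = vapply(events, function(e) e$centroid[1], numeric(1)),
                    y = vapply(events, function(e) e$centroid[2], numeric(1)),
                    z = vapply(events, function(e) e$centroid[3], numeric(1)),
                    peak_z = vapply(events, `[[`, numeric(1), "peak_z"),
                    volume = vapply(events, `[[`, numeric(1), "volume"),
                    bdc = vapply(events, `[[`, numeric(1), "bdc"),
                    occupancy_estimate = vapply(events, `[[`, numeric(1),
                                                "occupancy_estimate"),
                    site_id = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(sites))
    for (s in sites) tab$site_id[s$event_refs$event] <- s$site_id
  tab
}
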