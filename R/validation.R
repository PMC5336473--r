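#' Real-space correlation coefficient (RSCC)
#'
#' Pearson correlation between a model-calculated density and an observed
#' (event) map over a masked local region. Invariant under positive affine
#' rescaling of either map, so raw and sigma-scaled maps score identically.
#'
#' @param model_density model-calculated [voxel_grid()].
#' @param event_map observed or background-corrected [voxel_grid()].
#' @param mask logical array selecting the local region (e.g. a
#'   [sphere_mask()] around the ligand).
#' @return correlation in `[-1, 1]`.
#' @export
rscc <- function(model_density, event_map, mask) {
  if (!all(dim(model_density$values) == dim(event_map$values)))
    stop("rscc: grids on different specs", call. = FALSE)
  if (!any(mask)) stop("rscc: empty mask", call. = FALSE)
  a <- model_density$values[mask]
  b <- event_map$values[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("rscc: degenerate region (zero variance over mask)", call. = FALSE)
  stats::cor(a, b)
}

#' Ligand model with validation scores
#'
#' @param dataset_id dataset the ligand was modelled in.
#' @param atoms an [atom_records()] table (nonempty).
#' @param refined_occupancy refined occupancy in `(0, 1]`.
#' @param scores named numeric vector of validation metrics (filled by the
#'   scoring functions).
#' @return an object of class `ligand_model`.
#' @export
ligand_model <- function(dataset_id, atoms, refined_occupancy, scores = numeric()) {
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("ligand_model: atoms must be nonempty", call. = FALSE)
  if (refined_occupancy <= 0 || refined_occupancy > 1)
    stop("ligand_model: refined_occupancy must lie in (0, 1]", call. = FALSE)
  structure(list(dataset_id = as.character(dataset_id), atoms = atoms,
                 refined_occupancy = refined_occupancy, scores = scores),
            class = "ligand_model")
}

#' RSZO/OCC: observed density strength per unit occupancy
#'
#' RSZO is the mean of the sigma-scaled event-map values interpolated at the
#' ligand atom centres (trilinear); dividing by the refined occupancy gives
#' a density-strength-per-occupancy quality metric. Well-fit ligands in
#' clean event maps score high; misplacements and over-estimated occupancies
#' drag the score down.
#'
#' @param event_map_sigma sigma-scaled event map (see [sigma_scale()]).
#' @param ligand a [ligand_model()] with `refined_occupancy > 0`.
#' @return RSZO divided by the refined occupancy.
#' @export
rszo_over_occ <- function(event_map_sigma, ligand) {
  if (!identical(event_map_sigma$unit_label, "sigma"))
    stop("rszo_over_occ: event map must be sigma-scaled", call. = FALSE)
  if (ligand$refined_occupancy <= 0)
    stop("rszo_over_occ: refined occupancy must be > 0", call. = FALSE)
  Ainv <- cart_to_frac_matrix(event_map_sigma$spec)
  fr <- as.matrix(ligand$atoms[, c("x", "y", "z")]) %*% t(Ainv)
  rszo <- mean(interpolate_trilinear(event_map_sigma, fr))
  rszo / ligand$refined_occupancy
}

#' Surroundings B-factor ratio
#'
#' Ratio of the mean ligand B-factor to the mean B-factor of environment
#' atoms within `radius` of any ligand atom (periodic minimum-image
#' distance). Values well above 1 flag ligands that refine to much larger
#' displacement parameters than their protein surroundings.
#'
#' @param ligand a [ligand_model()].
#' @param environment an [atom_records()] table of surrounding atoms.
#' @param radius contact-shell radius in Angstrom (default 4).
#' @param spec optional [grid_spec()] supplying periodicity; omit for
#'   aperiodic distances.
#' @return positive ratio.
#' @export
surroundings_b_ratio <- function(ligand, environment, radius = 4, spec = NULL) {
  lp <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  ep <- as.matrix(environment[, c("x", "y", "z")])
  near <- vapply(seq_len(nrow(ep)), function(i) {
    d <- if (is.null(spec))
      sqrt(colSums((t(lp) - ep[i, ])^2))
    else vapply(seq_len(nrow(lp)), function(j)
      periodic_distance(lp[j, ], ep[i, ], spec), numeric(1))
    any(d <= radius)
  }, logical(1))
  if (!any(near))
    stop("surroundings_b_ratio: no environment atoms within ", radius,
         " A of the ligand", call. = FALSE)
  mean(ligand$atoms$b) / mean(environment$b[near])
}

#' Check that ensemble state occupancies sum to unity
#'
#' Ensemble models label the bound and unbound states of the crystal as
#' alternate conformers whose occupancies are constrained to sum to 1.
#'
#' @param states numeric vector of state occupancies, or a list with
#'   elements carrying an `occupancy` field.
#' @param tolerance allowed deviation of the sum from 1 (default 0.01,
#'   matching two-decimal occupancy rounding).
#' @return `TRUE` iff `|sum - 1| <= tolerance`.
#' @export
check_occupancy_sum <- function(states, tolerance = 0.01) {
  occ <- if (is.numeric(states)) states
         else vapply(states, function(s) s$occupancy, numeric(1))
  if (length(occ) == 0) stop("check_occupancy_sum: no states", call. = FALSE)
  if (any(occ < 0 | occ > 1))
    stop("check_occupancy_sum: occupancies must lie in [0, 1]", call. = FALSE)
  abs(sum(occ) - 1) <= tolerance
}

#' Screen hit rate in percent
#'
#' @param n_hit_datasets number of datasets with at least one modelled hit.
#' @param n_screened total number of screened datasets (> 0).
#' @return `100 * n_hit_datasets / n_screened`, rounded to one decimal.
#' @examples
#' hit_rate(24, 226)  # 10.6
#' hit_rate(2, 226)   # 0.9
#' @export
hit_rate <- function(n_hit_datasets, n_screened) {
  if (n_screened <= 0) stop("hit_rate: n_screened must be > 0", call. = FALSE)
  if (n_hit_datasets < 0 || n_hit_datasets > n_screened)
    stop("hit_rate: need 0 <= n_hit_datasets <= n_screened", call. = FALSE)
  round(100 * n_hit_datasets / n_screened, 1)
}

#' Screen-level summary
#'
#' Counts, hit rate, the occupancy histogram of modelled ligands (bin width
#' 0.1 over `[0, 1]`) and five-number summaries (min, lower quartile,
#' median, upper quartile, max; type-7 quantiles) of the dataset statistics
#' resolution, R-work and R-free.
#'
#' @param datasets list of [crystal_dataset()] (the full screen).
#' @param ligands list of [ligand_model()] (the modelled hits).
#' @return an object of class `screen_summary`.
#' @export
summarize_screen <- function(datasets, ligands = list()) {
  n <- length(datasets)
  lig_ids <- vapply(ligands, `[[`, character(1), "dataset_id")
  n_hit <- length(unique(lig_ids))
  occ <- vapply(ligands, `[[`, numeric(1), "refined_occupancy")
  breaks <- seq(0, 1, by = 0.1)
  counts <- if (length(occ)) {
    bin <- pmin(findInterval(occ, breaks, rightmost.closed = TRUE), 10L)
    tabulate(bin, nbins = 10L)
  } else integer(10)
  hist_df <- data.frame(bin_low = breaks[-11], bin_high = breaks[-1],
                        count = counts)
  five_num <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(rep(NA_real_, 5))
    stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  }
  stat_quartiles <- rbind(
    resolution = five_num(vapply(datasets, `[[`, numeric(1), "resolution")),
    r_work = five_num(vapply(datasets, `[[`, numeric(1), "r_work")),
    r_free = five_num(vapply(datasets, `[[`, numeric(1), "r_free")))
  colnames(stat_quartiles) <- c("min", "lower_quartile", "median",
                                "upper_quartile", "max")
  structure(list(n_datasets = n,
                 n_hit_datasets = n_hit,
                 n_ligands = length(ligands),
                 hit_rate_percent = if (n > 0) hit_rate(n_hit, n) else NA_real_,
                 occupancy_histogram = hist_df,
                 stat_quartiles = stat_quartiles),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("screen_summary: %d datasets, %d hit datasets (%s%%), %d ligands\n",
              x$n_datasets, x$n_hit_datasets,
              format(x$hit_rate_percent, nsmall = 1), x$n_ligands))
  if (x$n_ligands > 0) {
    cat("occupancy histogram (bin width 0.1):\n")
    print(x$occupancy_histogram)
  }
  cat("dataset statistics (type-7 quantiles):\n")
  print(round(x$stat_quartiles, 3))
  invisible(x)
}
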