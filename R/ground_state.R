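#' Robust per-dataset uncertainty estimate
#'
#' Estimates the noise level of one dataset relative to the ground-state
#' mean as a robust scale of the masked residuals `grid - mean_map`:
#' the median absolute deviation about the residual median, scaled by
#' 1.4826 for consistency with the Gaussian standard deviation. Robustness
#' matters because a bound ligand contaminates a small fraction of voxels
#' with large residuals that must not inflate the dataset's noise estimate.
#'
#' @param grid a [voxel_grid()].
#' @param mean_map the ground-state mean, on the same spec.
#' @param mask optional logical array restricting the residuals.
#' @return a single non-negative number (map units).
#' @export
estimate_dataset_uncertainty <- function(grid, mean_map, mask = NULL) {
  if (!all(dim(grid$values) == dim(mean_map$values)))
    stop("estimate_dataset_uncertainty: grids on different specs", call. = FALSE)
  res <- grid$values - mean_map$values
  if (!is.null(mask)) {
    if (!any(mask)) stop("estimate_dataset_uncertainty: empty mask", call. = FALSE)
    res <- res[mask]
  }
  stats::mad(res, constant = 1.4826)
}

#' Fit the statistical ground-state model
#'
#' Characterizes the unbound state of the crystal from many datasets of the
#' same crystal form (all on one grid; [resample_onto()] first if needed):
#' the voxel-wise mean map, a per-dataset uncertainty
#' (via [estimate_dataset_uncertainty()]), and a per-voxel variability map
#' capturing systematic voxel-to-voxel variation in excess of dataset-level
#' noise: `sigma_m(x)^2 = max(0, sample_variance(x) - mean_d sigma(u_d)^2)`.
#' All datasets, including eventual hits, participate by default; the robust
#' uncertainty estimator tolerates the small contaminated voxel fraction a
#' bound ligand introduces. Datasets named in `exclude` are left out.
#'
#' @param datasets list of [crystal_dataset()] on a common spec.
#' @param mask optional logical array: the characterization region over
#'   which uncertainties are estimated (default: whole grid).
#' @param min_datasets hard floor on the dataset count (default 10); fewer
#'   raises an error, fewer than 30 a warning.
#' @param exclude character vector of dataset ids to leave out.
#' @return an object of class `ground_state_model` with fields `mean_map`,
#'   `voxel_sd_map`, `n_datasets`, `dataset_uncertainties` (named numeric)
#'   and `characterization_mask`.
#' @export
fit_ground_state <- function(datasets, mask = NULL, min_datasets = 10,
                             exclude = NULL) {
  if (!is.null(exclude))
    datasets <- Filter(function(d) !(d$id %in% exclude), datasets)
  n <- length(datasets)
  if (n < min_datasets)
    stop("fit_ground_state: ", n, " datasets supplied but at least ",
         min_datasets, " are required to characterize the ground state",
         call. = FALSE)
  if (n < 30)
    warning("fit_ground_state: only ", n,
            " characterization datasets; the ground-state model may be poorly determined",
            call. = FALSE)
  spec <- datasets[[1]]$grid$spec
  for (d in datasets)
    if (!same_spec(d$grid$spec, spec))
      stop("fit_ground_state: dataset ", d$id,
           " is on a different grid spec; resample first", call. = FALSE)
  dims <- spec$shape
  s1 <- array(0, dims); s2 <- array(0, dims)
  for (d in datasets) {
    s1 <- s1 + d$grid$values
    s2 <- s2 + d$grid$values^2
  }
  mean_vals <- s1 / n
  samp_var <- pmax(0, (s2 - n * mean_vals^2) / (n - 1))
  mean_map <- voxel_grid(mean_vals, spec, datasets[[1]]$grid$unit_label)
  unc <- vapply(datasets, function(d)
    estimate_dataset_uncertainty(d$grid, mean_map, mask), numeric(1))
  names(unc) <- vapply(datasets, `[[`, character(1), "id")
  sd_m <- sqrt(pmax(0, samp_var - mean(unc^2)))
  structure(list(mean_map = mean_map,
                 voxel_sd_map = voxel_grid(sd_m, spec, "raw"),
                 n_datasets = n,
                 dataset_uncertainties = unc,
                 characterization_mask = mask),
            class = "ground_state_model")
}

#' @export
print.ground_state_model <- function(x, ...) {
  cat(sprintf("ground_state_model: %d datasets, dataset uncertainty %.4g-%.4g, median voxel sd %.4g\n",
              x$n_datasets, min(x$dataset_uncertainties),
              max(x$dataset_uncertainties), stats::median(x$voxel_sd_map$values)))
  invisible(x)
}

#' Compute a dataset's Z-map against the ground state
#'
#' Voxel-wise standardized deviation from the ground-state mean:
#' `z(x) = (rho_d(x) - mu(x)) / sqrt(sigma(u_d)^2 + sigma_m(x)^2)`.
#' The denominator is floored at `1e-6` map units so that flat solvent
#' regions cannot produce division blow-ups; the number of floored voxels is
#' reported as the attribute `"n_floored"`. If the dataset was not part of
#' the model fit, its uncertainty is estimated on the fly against the mean
#' map over the characterization mask.
#'
#' @param dataset a [crystal_dataset()] on the model's spec.
#' @param model a [fit_ground_state()] result.
#' @return an object of class `z_map`: fields `dataset_id` and `grid`
#'   (a unitless [voxel_grid()]).
#' @export
compute_z_map <- function(dataset, model) {
  if (!same_spec(dataset$grid$spec, model$mean_map$spec))
    stop("compute_z_map: dataset not on the model's grid spec", call. = FALSE)
  u <- model$dataset_uncertainties[dataset$id]
  if (is.na(u))
    u <- estimate_dataset_uncertainty(dataset$grid, model$mean_map,
                                      model$characterization_mask)
  denom <- sqrt(u^2 + model$voxel_sd_map$values^2)
  floored <- denom < 1e-6
  denom[floored] <- 1e-6
  z <- (dataset$grid$values - model$mean_map$values) / denom
  g <- voxel_grid(z, model$mean_map$spec, "sigma")
  structure(list(dataset_id = dataset$id, grid = g,
                 n_floored = sum(floored)),
            class = "z_map")
}

#' Persist a ground-state model to disk
#'
#' Writes the mean and voxel-sd maps as CCP4 files plus a JSON sidecar with
#' the per-dataset uncertainties and parameters.
#'
#' @param model a `ground_state_model`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_ground_state <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_density_map(model$mean_map, file.path(dir, "mean_map.ccp4"))
  write_density_map(model$voxel_sd_map, file.path(dir, "voxel_sd_map.ccp4"))
  jsonlite::write_json(list(n_datasets = model$n_datasets,
                            dataset_uncertainties = as.list(model$dataset_uncertainties)),
                       file.path(dir, "ground_state.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a persisted ground-state model
#'
#' @param dir directory written by [write_ground_state()].
#' @return a `ground_state_model` (without the characterization mask).
#' @export
read_ground_state <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "ground_state.json"),
                              simplifyVector = TRUE)
  structure(list(mean_map = read_density_map(file.path(dir, "mean_map.ccp4")),
                 voxel_sd_map = read_density_map(file.path(dir, "voxel_sd_map.ccp4")),
                 n_datasets = side$n_datasets,
                 dataset_uncertainties = unlist(side$dataset_uncertainties),
                 characterization_mask = NULL),
            class = "ground_state_model")
}
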