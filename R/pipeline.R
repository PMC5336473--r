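#' Analysis configuration
#'
#' Collects every tunable parameter of the screen analysis. The defaults
#' are the package's standard parameter set; all are configurable. The
#' object round-trips through JSON unchanged.
#'
#' @param input_dir directory of `dataset_*/map.ccp4` subdirectories.
#' @param output_dir directory for all analysis outputs.
#' @param z_threshold Z-map detection threshold (default 2.5).
#' @param min_volume minimum event volume in Angstrom^3 (default 5).
#' @param bdc_step BDC scan step (default 0.01).
#' @param site_cutoff site merge distance in Angstrom (default 5).
#' @param min_datasets minimum number of characterization datasets
#'   (default 10).
#' @param smooth_width Gaussian band-limiting sigma in Angstrom applied to
#'   every map on loading (default 0.5, matching the ~1.4 Angstrom median
#'   resolution of a well-diffracting fragment-screen crystal system:
#'   crystallographic maps carry no information below their resolution, so
#'   voxel noise at finer scales is suppressed without touching signal;
#'   0 disables).
#' @param mask_quantile the characterization mask keeps voxels whose mean
#'   density exceeds this quantile of the provisional mean map
#'   (default 0.7: the densest ~30% of the cell, i.e. the molecular region).
#' @param event_dilation dilation in Angstrom of an event's cluster voxels
#'   when forming its BDC event region (default 3: wide enough to take in
#'   the displaced ground-state density around the cluster, which is what
#'   the BDC scan measures).
#' @param detect_dilation events are searched only within the
#'   characterization mask dilated by this many Angstrom (default 4):
#'   fragment-binding events occur at the protein surface and in its
#'   pockets, so outliers in bulk solvent are not chemically meaningful.
#' @param write_zmaps also write each dataset's Z-map (default `FALSE`).
#' @param seed integer seed recorded with the run (the analysis itself is
#'   deterministic; the seed also feeds any simulation driven by the run).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = NULL,
                       z_threshold = 2.5, min_volume = 5, bdc_step = 0.01,
                       site_cutoff = 5, min_datasets = 10,
                       smooth_width = 0.5, mask_quantile = 0.7,
                       event_dilation = 3, detect_dilation = 4,
                       write_zmaps = FALSE, seed = 1) {
  for (nm in c("z_threshold", "min_volume", "bdc_step", "site_cutoff",
               "min_datasets"))
    if (get(nm) <= 0) stop("run_config: ", nm, " must be positive", call. = FALSE)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 z_threshold = z_threshold, min_volume = min_volume,
                 bdc_step = bdc_step, site_cutoff = site_cutoff,
                 min_datasets = min_datasets, smooth_width = smooth_width,
                 mask_quantile = mask_quantile, event_dilation = event_dilation,
                 detect_dilation = detect_dilation,
                 write_zmaps = isTRUE(write_zmaps), seed = as.integer(seed)),
            class = "run_config")
}

#' In-memory screen analysis
#'
#' The full analysis chain on a list of loaded datasets: resample onto a
#' common grid, band-limit, build the characterization mask, sigma-scale,
#' fit the ground-state model, compute Z-maps, detect events, estimate each
#' event's BDC, compute event maps, and group events into sites.
#'
#' @param datasets list of [crystal_dataset()].
#' @param config a [run_config()].
#' @return a list of class `screen_analysis`: `model`, `datasets` (the
#'   processed, sigma-scaled datasets), `zmaps`, `events` (flat list with
#'   BDC filled in), `event_maps` (one [voxel_grid()] per event), `sites`,
#'   `events_table`, `summary`, `mask`, `config`.
#' @export
analyze_datasets <- function(datasets, config = run_config()) {
  n <- length(datasets)
  if (n < config$min_datasets)
    stop("analyze_datasets: ", n, " datasets but min_datasets = ",
         config$min_datasets, call. = FALSE)
  ref_spec <- datasets[[1]]$grid$spec
  datasets <- lapply(datasets, function(d) {
    if (!same_spec(d$grid$spec, ref_spec))
      d$grid <- resample_onto(d$grid, ref_spec)
    if (config$smooth_width > 0)
      d$grid <- smooth_map(d$grid, config$smooth_width)
    d
  })
  prov_mean <- Reduce(`+`, lapply(datasets, function(d) d$grid$values)) / n
  mask <- prov_mean >= stats::quantile(prov_mean, config$mask_quantile)
  datasets <- lapply(datasets, function(d) {
    d$grid <- sigma_scale(d$grid, mask)
    d
  })
  model <- fit_ground_state(datasets, mask = mask,
                            min_datasets = config$min_datasets)
  zmaps <- lapply(datasets, compute_z_map, model = model)
  detect_mask <- if (config$detect_dilation > 0)
    dilate_mask(mask, config$detect_dilation, ref_spec) else NULL
  events_per_ds <- lapply(zmaps, find_events,
                          threshold = config$z_threshold,
                          min_volume = config$min_volume,
                          mask = detect_mask)
  events <- list(); event_maps <- list()
  for (i in seq_len(n)) {
    evs <- events_per_ds[[i]]
    if (length(evs) == 0) next
    regions <- lapply(evs, event_mask, spec = ref_spec,
                      dilate = config$event_dilation)
    all_regions <- Reduce(`|`, regions)
    ref_mask <- mask & !all_regions
    for (j in seq_along(evs)) {
      b <- tryCatch(
        estimate_bdc(datasets[[i]]$grid, model$mean_map, regions[[j]], ref_mask,
                     step = config$bdc_step, smooth_width = 0),
        error = function(e) NA_real_, warning = function(w) NA_real_)
      evs[[j]]$bdc <- as.numeric(b)
      evs[[j]]$occupancy_estimate <- 1 - as.numeric(b)
      events[[length(events) + 1L]] <- evs[[j]]
      event_maps[length(events)] <- list(if (!is.na(b))
        compute_event_map(datasets[[i]]$grid, model$mean_map, as.numeric(b))
      else NULL)
    }
  }
  sites <- group_into_sites(events, cutoff = config$site_cutoff, spec = ref_spec)
  tab <- events_to_table(events, sites)
  n_hit <- length(unique(tab$dataset_id))
  occ <- tab$occupancy_estimate[!is.na(tab$occupancy_estimate)]
  breaks <- seq(0, 1, by = 0.1)
  counts <- if (length(occ)) {
    bin <- pmin(findInterval(occ, breaks, rightmost.closed = TRUE), 10L)
    tabulate(bin, nbins = 10L)
  } else integer(10)
  summary <- summarize_screen(datasets, ligands = list())
  summary$n_hit_datasets <- n_hit
  summary$n_ligands <- nrow(tab)
  summary$hit_rate_percent <- hit_rate(n_hit, n)
  summary$occupancy_histogram <- data.frame(bin_low = breaks[-11],
                                            bin_high = breaks[-1],
                                            count = counts)
  summary$events_per_dataset <- vapply(events_per_ds, length, integer(1))
  structure(list(model = model, datasets = datasets, zmaps = zmaps,
                 events = events, event_maps = event_maps, sites = sites,
                 events_table = tab, summary = summary, mask = mask,
                 config = config),
            class = "screen_analysis")
}

#' Run the end-to-end screen analysis on a directory of maps
#'
#' Loads every `dataset_*/map.ccp4` under `config$input_dir` (a malformed
#' map is logged and skipped; the remaining datasets are still processed),
#' runs [analyze_datasets()], and writes the events table (CSV and JSON),
#' the site table, the screen summary, the ground-state model, one event
#' map per event (`<dataset>_event_<n>_bdc_<value>.ccp4`), optional Z-maps,
#' and a JSON run log recording every parameter, the seed, the per-dataset
#' uncertainties and any skipped files. Input files are never modified.
#'
#' @param config a [run_config()] with `input_dir` and `output_dir` set.
#' @return invisibly, the [analyze_datasets()] result, with `failures`
#'   attached.
#' @export
run_screen_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_dir) || is.null(config$output_dir))
    stop("run_screen_analysis: config needs input_dir and output_dir", call. = FALSE)
  dds <- sort(list.dirs(config$input_dir, recursive = FALSE))
  dds <- dds[grepl("^dataset_", basename(dds))]
  datasets <- list(); failures <- character()
  for (dd in dds) {
    d <- tryCatch({
      id <- sub("^dataset_", "", basename(dd))
      g <- read_density_map(file.path(dd, "map.ccp4"))
      meta <- list(resolution = NA_real_, r_work = NA_real_, r_free = NA_real_,
                   spacegroup = "P 1")
      mf <- file.path(dd, "meta.json")
      if (file.exists(mf)) {
        m <- jsonlite::read_json(mf, simplifyVector = TRUE)
        meta[names(m)[names(m) %in% names(meta)]] <- m[names(m) %in% names(meta)]
      }
      crystal_dataset(id, g, meta$resolution, meta$r_work, meta$r_free,
                      meta$spacegroup)
    }, error = function(e) {
      failures <<- c(failures, paste0(dd, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(d)) datasets[[length(datasets) + 1L]] <- d
  }
  if (length(datasets) < config$min_datasets)
    stop("run_screen_analysis: only ", length(datasets),
         " readable datasets under ", config$input_dir, " but min_datasets = ",
         config$min_datasets, call. = FALSE)
  res <- analyze_datasets(datasets, config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$events_table, file.path(out, "events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$events_table, file.path(out, "events.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  site_tab <- data.frame(
    site_id = vapply(res$sites, `[[`, integer(1), "site_id"),
    n_events = vapply(res$sites, function(s) nrow(s$event_refs), integer(1)),
    x = vapply(res$sites, function(s) s$centroid[1], numeric(1)),
    y = vapply(res$sites, function(s) s$centroid[2], numeric(1)),
    z = vapply(res$sites, function(s) s$centroid[3], numeric(1)))
  utils::write.csv(site_tab, file.path(out, "sites.csv"), row.names = FALSE)
  s <- res$summary
  jsonlite::write_json(list(n_datasets = s$n_datasets,
                            n_hit_datasets = s$n_hit_datasets,
                            n_ligands = s$n_ligands,
                            hit_rate_percent = s$hit_rate_percent,
                            occupancy_histogram = s$occupancy_histogram,
                            stat_quartiles = as.data.frame(s$stat_quartiles),
                            events_per_dataset = s$events_per_dataset),
                       file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_ground_state(res$model, file.path(out, "ground_state"))
  for (k in seq_along(res$events)) {
    ev <- res$events[[k]]
    if (is.null(res$event_maps[[k]]) || is.na(ev$bdc)) next
    idx <- res$events_table$event[k]
    write_density_map(res$event_maps[[k]],
                      file.path(out, sprintf("%s_event_%d_bdc_%.2f.ccp4",
                                             ev$dataset_id, idx, ev$bdc)))
  }
  if (config$write_zmaps)
    for (zm in res$zmaps)
      write_density_map(zm$grid, file.path(out, sprintf("%s_zmap.ccp4",
                                                        zm$dataset_id)))
  jsonlite::write_json(
    list(config = unclass(config),
         n_datasets = length(datasets),
         skipped = as.list(failures),
         dataset_uncertainties = as.list(res$model$dataset_uncertainties)),
    file.path(out, "run_log.json"), auto_unbox = TRUE, digits = NA)
  res$failures <- failures
  invisible(res)
}
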