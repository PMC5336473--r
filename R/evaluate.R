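#' Score a screen analysis against a synthetic truth table
#'
#' For every true hit of a simulated screen, finds the nearest detected
#' event in that dataset (periodic distance between the event centroid and
#' the true ligand centroid), and for matched hits computes the real-space
#' correlation coefficient between the noiseless bound-state ligand density
#' (band-limited exactly as the analysis band-limits its maps) and the
#' event's background-corrected event map, over a sphere mask around the
#' ligand atoms.
#'
#' @param analysis an [analyze_datasets()] result for the screen's datasets.
#' @param sim the [simulate_screen()] result the datasets came from.
#' @param match_radius maximum centroid distance in Angstrom for an event
#'   to count as detecting the hit (default 4).
#' @param rscc_radius ligand mask radius in Angstrom (default 1.5).
#' @return data frame with one row per true hit: `id`, `site`,
#'   `true_occupancy`, `detected`, `distance`, `peak_z`, `bdc`,
#'   `occupancy_estimate`, `rscc`.
#' @export
evaluate_against_truth <- function(analysis, sim, match_radius = 4,
                                   rscc_radius = 1.5) {
  stopifnot(inherits(analysis, "screen_analysis"),
            inherits(sim, "synthetic_screen"))
  spec <- sim$structure$spec
  tab <- analysis$events_table
  hits <- sim$truth[sim$truth$is_hit, , drop = FALSE]
  lig_density <- list()
  out <- data.frame(id = hits$id, site = hits$site,
                    true_occupancy = hits$true_occupancy,
                    detected = FALSE, distance = NA_real_, peak_z = NA_real_,
                    bdc = NA_real_, occupancy_estimate = NA_real_,
                    rscc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    rows <- which(tab$dataset_id == h$id)
    if (length(rows) == 0) next
    d <- vapply(rows, function(r)
      periodic_distance(as.numeric(tab[r, c("x", "y", "z")]),
                        c(h$cx, h$cy, h$cz), spec), numeric(1))
    j <- which.min(d)
    if (d[j] > match_radius) next
    r <- rows[j]
    out$detected[i] <- TRUE
    out$distance[i] <- d[j]
    out$peak_z[i] <- tab$peak_z[r]
    out$bdc[i] <- tab$bdc[r]
    out$occupancy_estimate[i] <- tab$occupancy_estimate[r]
    em <- analysis$event_maps[[r]]
    if (is.null(em) || is.na(tab$bdc[r])) next
    key <- as.character(h$site)
    if (is.null(lig_density[[key]])) {
      ld <- atoms_to_density(sim$structure$sites[[h$site]]$ligand, spec)
      if (analysis$config$smooth_width > 0)
        ld <- smooth_map(ld, analysis$config$smooth_width)
      lig_density[[key]] <- ld
    }
    lmask <- sphere_mask(sim$structure$sites[[h$site]]$ligand,
                         rscc_radius, spec)
    out$rscc[i] <- rscc(lig_density[[key]], em, lmask)
  }
  out
}
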