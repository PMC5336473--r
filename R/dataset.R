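#' Crystallographic dataset container
#'
#' Bundles one dataset's density map with its crystallographic metadata.
#'
#' @param id dataset label, e.g. `"x401"`.
#' @param grid a [voxel_grid()].
#' @param resolution resolution in Angstrom (> 0).
#' @param r_work,r_free refinement R-factors in `[0, 1]`.
#' @param spacegroup spacegroup label carried as metadata; maps are always
#'   interpreted as full-cell P1 grids.
#' @param ligand_id optional identifier of the soaked compound.
#' @return an object of class `crystal_dataset`.
#' @export
crystal_dataset <- function(id, grid, resolution = NA_real_,
                            r_work = NA_real_, r_free = NA_real_,
                            spacegroup = "P 1", ligand_id = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.na(resolution) && resolution <= 0)
    stop("crystal_dataset: resolution must be > 0", call. = FALSE)
  for (r in list(r_work, r_free))
    if (!is.na(r) && (r < 0 || r > 1))
      stop("crystal_dataset: R-factors must lie in [0, 1]", call. = FALSE)
  structure(list(id = as.character(id), grid = grid,
                 resolution = resolution, r_work = r_work, r_free = r_free,
                 spacegroup = spacegroup, ligand_id = ligand_id),
            class = "crystal_dataset")
}

#' @export
print.crystal_dataset <- function(x, ...) {
  cat(sprintf("crystal_dataset %s: %.2f A, R-work %.3f, R-free %.3f, %s\n",
              x$id, x$resolution, x$r_work, x$r_free, x$spacegroup))
  print(x$grid)
  invisible(x)
}
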