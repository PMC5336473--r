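#' Read a CCP4/MRC density map
#'
#' Reads a mode-2 (32-bit real) CCP4/MRC map covering one full unit cell.
#' The file's axis permutation (MAPC/MAPR/MAPS header fields) is resolved so
#' that the returned grid is always stored in the internal
#' (fast = x, medium = y, slow = z) convention. Both little- and big-endian
#' files are handled.
#'
#' @param path path to a CCP4/MRC map file.
#' @return a [voxel_grid()] with `unit_label = "raw"`.
#' @export
read_density_map <- function(path) {
  if (!file.exists(path))
    stop("read_density_map: no such file: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("read_density_map: file too small for a CCP4 header (header truncated): ", path,
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)

  parse_header <- function(endian) {
    ints <- readBin(hdr_raw, "integer", n = 256, size = 4, endian = endian)
    flts <- readBin(hdr_raw, "double", n = 256, size = 4, endian = endian)
    list(nc = ints[1], nr = ints[2], ns = ints[3], mode = ints[4],
         start = ints[5:7], m = ints[8:10],
         cell = flts[11:16], map_axes = ints[17:19],
         ispg = ints[23], nsymbt = ints[24], endian = endian)
  }
  h <- parse_header("little")
  plausible <- function(h) {
    h$mode %in% 0:6 && all(h$nc > 0, h$nr > 0, h$ns > 0) &&
      all(c(h$nc, h$nr, h$ns) < 1e7)
  }
  if (!plausible(h)) {
    h <- parse_header("big")
    if (!plausible(h))
      stop("read_density_map: unreadable header (MODE field is ", h$mode,
           "; not a CCP4/MRC map?): ", path, call. = FALSE)
  }
  if (h$mode != 2L)
    stop("read_density_map: unsupported MODE ", h$mode,
         " (only mode 2, 32-bit real, is supported)", call. = FALSE)
  if (!all(sort(h$map_axes) == 1:3))
    stop("read_density_map: invalid MAPC/MAPR/MAPS axis fields (",
         paste(h$map_axes, collapse = ","), ")", call. = FALSE)
  if (any(h$cell[1:3] <= 0) || any(h$cell[4:6] <= 0) || any(h$cell[4:6] >= 180))
    stop("read_density_map: invalid CELL header field (",
         paste(signif(h$cell, 6), collapse = ","), ")", call. = FALSE)

  nvox <- as.double(h$nc) * h$nr * h$ns
  need <- 1024 + h$nsymbt + 4 * nvox    # NSYMBT is a byte count
  if (sz < need)
    stop("read_density_map: data section truncated: NC*NR*NS = ", nvox,
         " voxels declared but file holds ", floor((sz - 1024 - h$nsymbt) / 4),
         call. = FALSE)
  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)
  vals <- readBin(con, "double", n = nvox, size = 4, endian = h$endian)
  if (!all(is.finite(vals)))
    stop("read_density_map: non-finite values in map data section", call. = FALSE)

  arr <- array(vals, dim = c(h$nc, h$nr, h$ns))
  # permute from file order (MAPC fastest) to internal x,y,z order
  arr <- aperm(arr, match(1:3, h$map_axes))
  # full-unit-cell check: sampling counts along x,y,z
  dims <- dim(arr)
  starts_xyz <- h$start[match(1:3, h$map_axes)]
  if (!all(dims == h$m))
    stop("read_density_map: map does not cover one full unit cell: ",
         "grid extent (NC,NR,NS reordered) ", paste(dims, collapse = "x"),
         " vs cell sampling (MX,MY,MZ) ", paste(h$m, collapse = "x"), call. = FALSE)
  if (!all(starts_xyz == 0L))
    stop("read_density_map: nonzero NCSTART/NRSTART/NSSTART (",
         paste(h$start, collapse = ","), "); only full-cell maps with origin 0 are supported",
         call. = FALSE)
  spec <- grid_spec(dims, h$cell[1:3], h$cell[4:6])
  voxel_grid(arr, spec, unit_label = "raw")
}

#' Write a CCP4/MRC density map
#'
#' Writes a standards-conformant mode-2 CCP4/MRC map (full unit cell, P1,
#' axis order x fastest, little-endian) that is re-readable by
#' [read_density_map()] and by independent tools.
#'
#' @param grid a [voxel_grid()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_density_map <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  n <- grid$spec$shape
  if (any(n < 2))
    stop("write_density_map: degenerate grid", call. = FALSE)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("write_density_map: cannot open '",
                                           path, "' for writing", call. = FALSE))
  on.exit(close(con))
  v <- grid$values
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wint(n)                        # NC NR NS
  wint(2)                        # MODE 2
  wint(c(0, 0, 0))               # NCSTART NRSTART NSSTART
  wint(n)                        # MX MY MZ
  wflt(c(grid$spec$cell_lengths, grid$spec$cell_angles))
  wint(1:3)                      # MAPC MAPR MAPS: x fast, y medium, z slow
  wflt(c(min(v), max(v), mean(v)))
  wint(1)                        # ISPG (P1)
  wint(0)                        # NSYMBT
  wint(rep(0L, 25))              # LSKFLG + skew block + extra (words 25-49)
  wflt(c(0, 0, 0))               # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)   # little-endian machine stamp
  wflt(stats::sd(v))             # ARMS
  wint(1)                        # NLABL
  lab <- sprintf("%-80s", "Created by pandensity")
  writeBin(charToRaw(paste0(lab, strrep(" ", 80 * 9))), con)
  wflt(v)
  invisible(path)
}

#' Atom table constructor
#'
#' Atoms are represented as a plain data frame with one row per atom and
#' columns `element`, `x`, `y`, `z` (Cartesian Angstrom), `b` (isotropic
#' B-factor, Angstrom^2), `occ` (occupancy in `[0, 1]`) and `residue`
#' (free-text residue tag).
#'
#' @param element character vector of element symbols.
#' @param pos N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param b numeric B-factors (>= 0), recycled.
#' @param occ numeric occupancies in `[0, 1]`, recycled.
#' @param residue character residue tags, recycled.
#' @return a data.frame of class `atom_records`.
#' @export
atom_records <- function(element, pos, b = 20, occ = 1, residue = "UNK") {
  pos <- matrix(as.numeric(pos), ncol = 3)
  nr <- nrow(pos)
  b <- rep_len(as.numeric(b), nr)
  occ <- rep_len(as.numeric(occ), nr)
  if (any(b < 0)) stop("atom_records: B-factors must be >= 0", call. = FALSE)
  if (any(occ < 0 | occ > 1)) stop("atom_records: occupancies must lie in [0, 1]", call. = FALSE)
  out <- data.frame(element = rep_len(as.character(element), nr),
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    b = b, occ = occ,
                    residue = rep_len(as.character(residue), nr),
                    stringsAsFactors = FALSE)
  class(out) <- c("atom_records", "data.frame")
  out
}

#' Read atoms from a PDB file
#'
#' Thin wrapper around `bio3d::read.pdb` returning an [atom_records()]
#' table (ATOM and HETATM records).
#'
#' @param path path to a PDB file.
#' @param hetatm include HETATM records (default `TRUE`).
#' @return an [atom_records()] data frame.
#' @export
read_structure <- function(path, hetatm = TRUE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- gsub("[0-9']", "", substr(trimws(at$elety), 1, 1))
  atom_records(element = trimws(elem),
               pos = cbind(at$x, at$y, at$z),
               b = at$b, occ = pmin(1, pmax(0, at$o)),
               residue = paste0(at$resid, at$resno))
}
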