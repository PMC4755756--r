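#' Density map on a crystallographic grid
#'
#' A scalar density lattice over a [unit_cell]. Grid point `(i, j, k)`
#' (0-based) sits at fractional coordinate `(i/nx, j/ny, k/nz)`, i.e. the
#' map origin is the fractional origin and the axis order is fixed to
#' X, Y, Z; this removes the usual CCP4 axis-permutation ambiguity. Values
#' are stored x-fastest, matching the file layout on disk. All synthetic
#' maps are P1 and wrap periodically.
#'
#' @param cell a [unit_cell].
#' @param dims integer vector of three positive grid counts (nx, ny, nz).
#' @param values numeric vector of length `prod(dims)`, x-fastest, in
#'   arbitrary map units.
#' @return an object of class `map_grid`.
#' @export
map_grid <- function(cell, dims, values) {
  stopifnot(inherits(cell, "unit_cell"))
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims <= 0)) {
    stopf("dims must be three positive integers")
  }
  if (length(values) != prod(dims)) {
    stopf("length(values) [%d] != prod(dims) [%d]",
          length(values), prod(dims))
  }
  structure(list(cell = cell, dims = dims, values = as.numeric(values)),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("map grid %d x %d x %d (%d voxels), rms %.4g\n",
              x$dims[1], x$dims[2], x$dims[3], prod(x$dims), map_rms(x)))
  print(x$cell)
  invisible(x)
}

# Voxel volume in A^3 (cell volume / number of grid points).
voxel_volume <- function(map) map$cell$volume / prod(map$dims)

# Grid spacing along each cell axis in A.
grid_spacing <- function(map) c(map$cell$a, map$cell$b, map$cell$c) / map$dims

#' Write a map in CCP4/MRC mode-2 format
#'
#' Mode 2 stores 32-bit IEEE floats, little-endian, x-fastest, with the
#' standard 1024-byte header (MRC-2014 'MAP ' stamp, axis order X,Y,Z,
#' space group P1, grid origin at the fractional origin). Maps produced by
#' [render_map()] are already quantized to float32, so a write/read round
#' trip reproduces the in-memory values bit-exactly.
#'
#' @param map a [map_grid].
#' @param path output file path (conventionally `.ccp4` or `.mrc`).
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(map, path) {
  stopifnot(inherits(map, "map_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- map$values
  wint(map$dims)                         # NC NR NS
  wint(2L)                               # MODE 2 = float32
  wint(c(0L, 0L, 0L))                    # NCSTART NRSTART NSSTART
  wint(map$dims)                         # NX NY NZ (sampling = full cell)
  wflt(c(map$cell$a, map$cell$b, map$cell$c,
         map$cell$alpha, map$cell$beta, map$cell$gamma))
  wint(c(1L, 2L, 3L))                    # MAPC MAPR MAPS = X Y Z
  wflt(c(min(v), max(v), mean(v)))       # AMIN AMAX AMEAN
  wint(1L)                               # ISPG = P1
  wint(0L)                               # NSYMBT
  wint(rep(0L, 25))                      # EXTRA (words 26-50)
  wflt(c(0, 0, 0))                       # ORIGIN (MRC-2014)
  writeBin(charToRaw("MAP "), con)       # map stamp
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian MACHST
  wflt(sqrt(mean((v - mean(v))^2)))      # RMS about mean
  wint(1L)                               # NLABL
  lab <- sprintf("%-80s", "selenotrace synthetic anomalous difference map")
  writeBin(charToRaw(paste0(lab, strrep(" ", 720))), con)
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC mode-2 map
#'
#' Accepts only the conventions this package writes: mode 2, axis order
#' X,Y,Z, zero start indices, grid sampling equal to the full cell.
#'
#' @param path path to a mode-2 map file.
#' @return a [map_grid].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rflt <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  dims <- rint(3)
  mode <- rint(1)
  if (mode != 2L) stopf("unsupported map mode %d (only mode 2 supported)", mode)
  start <- rint(3)
  if (any(start != 0L)) stopf("nonzero map start indices are not supported")
  nxyz <- rint(3)
  cellp <- rflt(6)
  maporder <- rint(3)
  if (!identical(maporder, c(1L, 2L, 3L))) {
    stopf("unsupported map axis order (%s); expected X,Y,Z",
          paste(maporder, collapse = ","))
  }
  if (any(nxyz != dims)) stopf("map section counts do not cover the full cell")
  rflt(3)                                # AMIN AMAX AMEAN
  rint(1)                                # ISPG
  nsymbt <- rint(1)
  seek(con, 1024 + nsymbt)
  values <- rflt(prod(dims))
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])
  map_grid(cell, dims, values)
}

#' Root mean square of all map values
#'
#' The map RMS (about zero, as appropriate for an anomalous difference map
#' that is zero-mean away from scatterers) underlies sigma-level contouring
#' and the occupancy detection floor.
#'
#' @param map a [map_grid].
#' @return RMS in map units.
#' @export
map_rms <- function(map) {
  stopifnot(inherits(map, "map_grid"))
  if (prod(map$dims) < 1) stopf("empty map")
  sqrt(mean(map$values^2))
}

# Periodic trilinear interpolation of map values at Cartesian points
# (n x 3 matrix). Used for peak heights and subgrid integration.
trilinear_at <- function(map, cart) {
  if (!is.matrix(cart)) cart <- matrix(cart, ncol = 3)
  fr <- fractionalize(cart, map$cell)
  n <- map$dims
  g <- sweep(fr %% 1, 2, n, `*`)         # continuous grid coords in [0, n)
  i0 <- floor(g)
  w <- g - i0
  vals <- numeric(nrow(cart))
  idx <- function(ix, iy, iz) {
    1 + (ix %% n[1]) + n[1] * ((iy %% n[2]) + n[2] * (iz %% n[3]))
  }
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    vals <- vals + wt * map$values[idx(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  vals
}
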