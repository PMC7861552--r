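#' Build the coupled CRU / mitochondrion lattice
#'
#' Constructs the 3-D lattice of Ca2+ release units (CRUs), the coarser
#' lattice of mitochondria, and the map assigning each mitochondrion the
#' contiguous block of CRUs it serves. The full-scale cell uses
#' 64 x 28 x 12 = 21504 CRUs and 64 x 14 x 6 = 5376 mitochondria, i.e. one
#' mitochondrion per 1 x 2 x 2 block of CRUs; smaller lattices with the same
#' divisibility structure are accepted for reduced-scale simulation.
#'
#' Linear indexing is x-fastest (1-based): `i = x + nx * (y - 1 + ny * (z - 1))`.
#' Boundaries are no-flux: neighbour lists are simply truncated at the faces.
#'
#' @param cru_dims integer vector `c(nx, ny, nz)` of CRU lattice dimensions.
#' @param mito_dims integer vector of mitochondrion lattice dimensions; each
#'   CRU dimension must be an integer multiple of the corresponding
#'   mitochondrion dimension.
#' @return An object of class `spatial_grid`: a list with `cru_dims`,
#'   `mito_dims`, `cru_count`, `mito_count`, `block` (CRUs per mitochondrion
#'   along each axis), `mito_of_cru` (integer vector, mitochondrion owning
#'   each CRU), `mito_to_cru` (list mapping each mitochondrion to its CRU
#'   block) and `cru_neighbors` (list of face-adjacent CRU indices).
#' @examples
#' g <- build_lattice(c(4, 2, 2), c(4, 1, 1))
#' g$cru_count   # 16
#' g$mito_count  # 4
#' @export
build_lattice <- function(cru_dims, mito_dims) {
  cru_dims <- as.integer(cru_dims)
  mito_dims <- as.integer(mito_dims)
  stopifnot(length(cru_dims) == 3L, length(mito_dims) == 3L)
  if (any(cru_dims < 1L) || any(mito_dims < 1L))
    stop("lattice dimensions must all be >= 1")
  ax <- c("x", "y", "z")
  bad <- which(cru_dims %% mito_dims != 0L)
  if (length(bad))
    stop(sprintf(
      "CRU dimension not divisible by mitochondrion dimension on axis %s (%d %%%% %d != 0)",
      ax[bad[1L]], cru_dims[bad[1L]], mito_dims[bad[1L]]))

  nx <- cru_dims[1L]; ny <- cru_dims[2L]; nz <- cru_dims[3L]
  block <- cru_dims %/% mito_dims
  ncru <- as.integer(prod(cru_dims))
  nmito <- as.integer(prod(mito_dims))

  # x-fastest linear index for every CRU coordinate
  coord <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  mx <- (coord$x - 1L) %/% block[1L]
  my <- (coord$y - 1L) %/% block[2L]
  mz <- (coord$z - 1L) %/% block[3L]
  mito_of_cru <- 1L + mx + mito_dims[1L] * (my + mito_dims[2L] * mz)
  mito_to_cru <- split(seq_len(ncru), mito_of_cru)
  names(mito_to_cru) <- NULL

  idx <- function(x, y, z) x + nx * ((y - 1L) + ny * (z - 1L))
  nbrs <- vector("list", ncru)
  for (i in seq_len(ncru)) {
    x <- coord$x[i]; y <- coord$y[i]; z <- coord$z[i]
    v <- integer(0)
    if (x > 1L) v <- c(v, idx(x - 1L, y, z))
    if (x < nx) v <- c(v, idx(x + 1L, y, z))
    if (y > 1L) v <- c(v, idx(x, y - 1L, z))
    if (y < ny) v <- c(v, idx(x, y + 1L, z))
    if (z > 1L) v <- c(v, idx(x, y, z - 1L))
    if (z < nz) v <- c(v, idx(x, y, z + 1L))
    nbrs[[i]] <- v
  }

  structure(list(
    cru_dims = cru_dims, mito_dims = mito_dims,
    cru_count = ncru, mito_count = nmito,
    block = as.integer(block),
    mito_of_cru = as.integer(mito_of_cru),
    mito_to_cru = mito_to_cru,
    cru_neighbors = nbrs
  ), class = "spatial_grid")
}

#' Face-adjacent neighbours of a CRU
#'
#' @param grid a `spatial_grid` from [build_lattice()].
#' @param cru_index 1-based CRU linear index.
#' @return Integer vector of face-adjacent CRU indices (3 to 6 entries
#'   depending on boundary position; no self, no duplicates).
#' @export
neighbor_list <- function(grid, cru_index) {
  stopifnot(inherits(grid, "spatial_grid"))
  cru_index <- as.integer(cru_index)
  if (length(cru_index) != 1L || is.na(cru_index) ||
      cru_index < 1L || cru_index > grid$cru_count)
    stop(sprintf("CRU index %s out of range 1..%d", cru_index, grid$cru_count))
  grid$cru_neighbors[[cru_index]]
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("CRU/mitochondrion lattice\n  CRUs: %d (%s)\n  mitochondria: %d (%s)\n  CRUs per mitochondrion: %s block\n",
              x$cru_count, paste(x$cru_dims, collapse = "x"),
              x$mito_count, paste(x$mito_dims, collapse = "x"),
              paste(x$block, collapse = "x")))
  invisible(x)
}
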