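# Shared internal helpers: grids, coordinates, seeded RNG scopes, units.

# Physical coordinates of voxel centres (mm): position = origin + index * spacing,
# with 0-based indices.  `which_idx` is a vector of 1-based linear indices.
voxel_coords <- function(dim, spacing, origin, which_idx = NULL) {
  if (is.null(which_idx)) which_idx <- seq_len(prod(dim))
  idx <- arrayInd(which_idx, dim) - 1L
  sweep(idx %*% diag(spacing, 3L), 2L, origin, "+")
}

# Linear index from 0-based integer voxel indices (matrix n x 3); NA outside grid.
linear_index <- function(ijk, dim) {
  ok <- ijk[, 1L] >= 0L & ijk[, 1L] < dim[1L] &
    ijk[, 2L] >= 0L & ijk[, 2L] < dim[2L] &
    ijk[, 3L] >= 0L & ijk[, 3L] < dim[3L]
  out <- rep(NA_integer_, nrow(ijk))
  out[ok] <- 1L + ijk[ok, 1L] + dim[1L] * (ijk[ok, 2L] + dim[2L] * ijk[ok, 3L])
  out
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards (process-restart reproducible).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a parent seed and an index.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483587)
}

gy_to_cgy <- function(x) 100 * x
cgy_to_gy <- function(x) x / 100

# Euclidean distance transform in mm to the TRUE set of a 3-D logical array.
distance_transform <- function(mask, spacing_mm) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) abort("distance_transform: feature mask is empty")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  d2 <- .edt_squared_cpp(as.logical(mask), dim(mask), as.double(spacing_mm))
  array(sqrt(d2), dim = dim(mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
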