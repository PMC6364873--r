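# Candidate non-coplanar beam geometry and the sparse dose-influence matrix
# d = A w (columns in cGy per MU). The beam model is an analytic cone kernel
# in a homogeneous water-equivalent body: inverse-square falloff, exponential
# attenuation with radiological depth, and a flat-core / error-function
# penumbra profile. It stands in for a commercial engine only in the sense
# that it supplies a physically plausible linear dose operator.

#' Generate a quasi-uniform non-coplanar node set
#'
#' Nodes are robot positions on a spherical cap around the head (superior
#' hemisphere plus a lateral band, default polar angle up to 120 degrees),
#' placed by a Fibonacci spiral at `max(head radii) + standoff_mm` from the
#' head centre. The default count of 179 matches a full-head non-coplanar
#' path.
#'
#' @param count Number of nodes (>= 1); `count = 1` gives the apex node.
#' @param phantom A `vs_phantom` supplying the head geometry.
#' @param cap_angle_deg Maximum polar angle of the cap in degrees.
#' @param standoff_mm Clearance from the circumscribing head sphere in mm;
#'   the default places nodes at about the source-axis distance (800 mm)
#'   from the head centre so nominal cone diameters apply at the target.
#' @return A `vs_node_set` with `positions` (count x 3, mm), `radius_mm` and
#'   `centre`.
#' @export
generate_node_set <- function(count = 179, phantom, cap_angle_deg = 120,
                              standoff_mm = 710) {
  stopifnot(count >= 1)
  radius <- max(phantom$spec$head_radii_mm) + standoff_mm
  centre <- c(0, 0, 0)
  if (count == 1L) {
    dirs <- matrix(c(0, 0, 1), 1L)
  } else {
    i <- seq_len(count)
    cosmax <- cos(cap_angle_deg * pi / 180)
    u <- 1 - (1 - cosmax) * (i - 0.5) / count # cos(polar angle)
    phi <- i * pi * (3 - sqrt(5)) # golden angle
    st <- sqrt(pmax(0, 1 - u^2))
    dirs <- cbind(st * cos(phi), st * sin(phi), u)
  }
  pos <- sweep(dirs * radius, 2L, centre, "+")
  ins <- points_in_mask(pos, phantom, "body")
  if (any(ins))
    abort("standoff places nodes inside the body; increase standoff_mm")
  structure(list(positions = pos, count = nrow(pos), radius_mm = radius,
                 centre = centre, cap_angle_deg = cap_angle_deg,
                 standoff_mm = standoff_mm),
            class = "vs_node_set")
}

# nearest-voxel membership of physical points in a phantom mask
points_in_mask <- function(pts, phantom, name) {
  ijk <- round(sweep(pts, 2L, phantom$origin, "-") / phantom$spacing_mm)
  li <- linear_index(ijk, phantom$dim)
  ins <- !is.na(li)
  ins[ins] <- phantom$masks[[name]][li[ins]]
  ins
}

#' Analytic cone-beam kernel parameters
#'
#' Defaults (SAD 800 mm, effective attenuation 0.005/mm, penumbra sigma
#' 2 mm, reference depth 15 mm, output 1 cGy/MU) are documented model
#' choices, not vendor or published values.
#'
#' @param sad_mm Source-axis distance (mm).
#' @param mu_att_per_mm Effective linear attenuation (per mm) of the
#'   homogeneous water-equivalent body.
#' @param penumbra_sigma_mm Penumbra width (mm).
#' @param ref_depth_mm Calibration depth (mm): an on-axis voxel at this depth
#'   and at `sad_mm` from the source receives exactly `output_cgy_per_mu`.
#' @param output_cgy_per_mu Output calibration (cGy per MU).
#' @export
beam_kernel_params <- function(sad_mm = 800, mu_att_per_mm = 0.005,
                               penumbra_sigma_mm = 2, ref_depth_mm = 15,
                               output_cgy_per_mu = 1) {
  pars <- list(sad_mm = sad_mm, mu_att_per_mm = mu_att_per_mm,
               penumbra_sigma_mm = penumbra_sigma_mm,
               ref_depth_mm = ref_depth_mm,
               output_cgy_per_mu = output_cgy_per_mu)
  if (any(unlist(pars) <= 0)) abort("all kernel parameters must be positive")
  structure(pars, class = "vs_kernel")
}

#' Iris-style discrete collimator diameters (mm)
#' @export
collimator_set <- function() c(10, 12.5, 15, 20, 25, 30, 35, 40)

#' A candidate beam
#' @param node_index Index into the node set.
#' @param source Source position (mm).
#' @param aim Aim point (mm); must be inside the body for dose computation.
#' @param collimator_diameter_mm Cone diameter at SAD, within \[10, 40\] mm.
#' @export
candidate_beam <- function(node_index, source, aim, collimator_diameter_mm) {
  if (collimator_diameter_mm < 10 || collimator_diameter_mm > 40)
    abort("collimator diameter must lie in [10, 40] mm")
  structure(list(node_index = node_index, source = as.double(source),
                 aim = as.double(aim),
                 collimator_diameter_mm = collimator_diameter_mm),
            class = "vs_beam")
}

# Sparse per-beam dose over the body voxels (compiled kernel). Returns
# list(i, x): body-voxel row indices and doses (cGy/MU). Depth = in-body
# path length from the entry point (located by bisection along the
# source->voxel ray against the voxelized body) to the voxel.
beam_dose_entries <- function(beam, kernel, phantom, coords_body,
                              n_bisect = 30L) {
  e <- .beam_entries_cpp(as.logical(phantom$masks$body), phantom$dim,
                         phantom$spacing_mm, as.double(phantom$origin),
                         coords_body, beam$source, beam$aim,
                         beam$collimator_diameter_mm, kernel$sad_mm,
                         kernel$mu_att_per_mm, kernel$penumbra_sigma_mm,
                         kernel$ref_depth_mm, kernel$output_cgy_per_mu,
                         as.integer(n_bisect))
  if (length(e$i) == 0L) warn("beam misses the body entirely; zero dose column")
  e
}

#' Dose column of a single beam
#'
#' @param beam A [candidate_beam()]; the aim point must be inside the body.
#' @param kernel A [beam_kernel_params()].
#' @param phantom A `vs_phantom`.
#' @return Full-grid array of dose in cGy per MU (zero outside the body).
#' @export
beam_dose <- function(beam, kernel, phantom) {
  if (!points_in_mask(matrix(beam$aim, 1L), phantom, "body"))
    abort("beam aim point lies outside the body")
  body_idx <- which(phantom$masks$body)
  coords <- voxel_coords(phantom$dim, rep(phantom$spacing_mm, 3L),
                         phantom$origin, body_idx)
  e <- beam_dose_entries(beam, kernel, phantom, coords)
  out <- array(0, phantom$dim)
  out[body_idx[e$i]] <- e$x
  out
}

#' Build the sparse influence matrix
#'
#' Candidate beams are the cross product of nodes, selected collimators and
#' aim points (the PTV centroid plus optionally `aim_k` seeded random
#' PTV-interior voxel centres). Per-column entries below
#' `truncation_rel * max(column)` are dropped. Column ordering is
#' deterministic: node index varies fastest, then collimator, then aim
#' point.
#'
#' @param nodes A `vs_node_set`.
#' @param collimators Subset of [collimator_set()] diameters (mm).
#' @param kernel A [beam_kernel_params()].
#' @param phantom A `vs_phantom`.
#' @param aim_k Number of extra random PTV-interior aim points.
#' @param aim_seed Seed for aim-point sampling.
#' @param truncation_rel Per-column relative truncation threshold.
#' @param max_nnz Refuse assembly beyond this many stored entries.
#' @return A `vs_influence`: sparse `A` (body voxels x beams, cGy/MU), a
#'   `beams` tibble, the body `voxel_index`, and grid geometry.
#' @export
build_influence_matrix <- function(nodes, collimators, kernel, phantom,
                                   aim_k = 0L, aim_seed = 1L,
                                   truncation_rel = 1e-5, max_nnz = 5e7) {
  stopifnot(inherits(nodes, "vs_node_set"))
  if (length(collimators) == 0L) abort("empty collimator set")
  if (any(collimators < 10 | collimators > 40))
    abort("collimator diameters must lie in [10, 40] mm")
  ptv_idx <- which(phantom$masks$PTV)
  if (length(ptv_idx) == 0L) abort("phantom has an empty PTV")
  sp3 <- rep(phantom$spacing_mm, 3L)
  ptv_coords <- voxel_coords(phantom$dim, sp3, phantom$origin, ptv_idx)
  centroid <- colMeans(ptv_coords)
  aims <- matrix(centroid, 1L)
  if (aim_k > 0L) {
    extra <- with_seed(aim_seed, {
      ptv_coords[sample.int(nrow(ptv_coords), min(aim_k, nrow(ptv_coords))), ,
                 drop = FALSE]
    })
    aims <- rbind(aims, extra)
  }
  body_idx <- which(phantom$masks$body)
  coords <- voxel_coords(phantom$dim, sp3, phantom$origin, body_idx)

  grid <- expand.grid(node = seq_len(nodes$count),
                      collimator = collimators,
                      aim = seq_len(nrow(aims)))
  nb <- nrow(grid)
  ii <- vector("list", nb)
  xx <- vector("list", nb)
  nnz <- 0
  for (j in seq_len(nb)) {
    bm <- candidate_beam(grid$node[j], nodes$positions[grid$node[j], ],
                         aims[grid$aim[j], ], grid$collimator[j])
    e <- beam_dose_entries(bm, kernel, phantom, coords)
    if (length(e$x) > 0L && truncation_rel > 0) {
      keep <- e$x >= truncation_rel * max(e$x)
      e$i <- e$i[keep]
      e$x <- e$x[keep]
    }
    nnz <- nnz + length(e$x)
    if (nnz > max_nnz)
      abort(sprintf("influence matrix exceeds max_nnz = %g entries", max_nnz))
    ii[[j]] <- e$i
    xx[[j]] <- e$x
  }
  A <- sparseMatrix(i = unlist(ii),
                    j = rep.int(seq_len(nb), lengths(ii)),
                    x = unlist(xx),
                    dims = c(length(body_idx), nb))
  beams <- tibble(
    beam_id = sprintf("n%03d_c%s_a%d", grid$node, format(grid$collimator, trim = TRUE),
                      grid$aim),
    node = grid$node,
    collimator_mm = grid$collimator,
    aim_x = aims[grid$aim, 1L], aim_y = aims[grid$aim, 2L],
    aim_z = aims[grid$aim, 3L]
  )
  structure(
    list(A = A, beams = beams, voxel_index = body_idx, dim = phantom$dim,
         spacing_mm = phantom$spacing_mm, origin = phantom$origin,
         kernel = kernel, truncation_rel = truncation_rel),
    class = "vs_influence"
  )
}

#' @export
print.vs_influence <- function(x, ...) {
  cat(sprintf("<vs_influence> %d body voxels x %d beams, %d nonzeros (cGy/MU)\n",
              nrow(x$A), ncol(x$A), length(x$A@x)))
  invisible(x)
}

#' Dose distribution of a weight vector
#'
#' @param infl A `vs_influence`.
#' @param weights Beam weights in MU (length = number of beams), or a
#'   `vs_plan`.
#' @return Full-grid array of dose in Gy.
#' @export
dose_grid <- function(infl, weights) {
  if (inherits(weights, "vs_plan")) weights <- weights$weights
  d <- cgy_to_gy(drop(as.matrix(infl$A %*% weights)))
  out <- array(0, infl$dim)
  out[infl$voxel_index] <- d
  out
}
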