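# Shared fixtures, built in code at test time.

# A hand-built phantom-shaped object on a small grid: body is an ellipsoid
# (convex, as the ray tracer assumes), the target a small centred blob.
raw_phantom <- function(dim = c(17, 17, 17), spacing = 2,
                        body_semiaxes = NULL) {
  origin <- -(dim - 1) / 2 * spacing
  xyz <- shellplan:::voxel_coords(dim, rep(spacing, 3), origin)
  semi <- body_semiaxes %||% ((dim - 1) / 2 * spacing - spacing / 2)
  body <- (xyz[, 1]^2 / semi[1]^2 + xyz[, 2]^2 / semi[2]^2 +
             xyz[, 3]^2 / semi[3]^2) <= 1
  ptv <- rowSums(xyz^2) <= (2.5 * spacing)^2
  structure(list(
    spacing_mm = spacing, origin = origin, dim = dim,
    masks = list(body = array(body, dim), PTV = array(ptv & body, dim)),
    spec = list(head_radii_mm = semi, voxel_mm = spacing),
    ptv_centre = c(0, 0, 0), side = 1
  ), class = "vs_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal influence object for solver toys: `A_gy` maps beam weights to
# per-voxel doses in Gy (grid is a 1-D line of voxels).
toy_influence <- function(A_gy, spacing = 2) {
  n <- nrow(A_gy)
  dim3 <- c(n, 1L, 1L)
  beams <- tibble::tibble(
    beam_id = sprintf("b%02d", seq_len(ncol(A_gy))),
    node = seq_len(ncol(A_gy)), collimator_mm = 20,
    aim_x = 0, aim_y = 0, aim_z = 0)
  structure(list(
    A = methods::as(Matrix::Matrix(A_gy * 100, sparse = TRUE), "CsparseMatrix"),
    beams = beams, voxel_index = seq_len(n), dim = dim3,
    spacing_mm = spacing, origin = c(0, 0, 0),
    kernel = beam_kernel_params(), truncation_rel = 0
  ), class = "vs_influence")
}

# structure masks on the toy line grid
toy_masks <- function(n, ...) {
  sets <- list(...)
  lapply(sets, function(idx) {
    m <- array(FALSE, c(n, 1L, 1L))
    m[idx] <- TRUE
    m
  })
}

# Brute-force shell oracle: all-pairs voxel-centre distances.
brute_shell <- function(ptv, body, spacing, distance_cm, thickness_mm) {
  dim3 <- dim(ptv)
  xyz <- shellplan:::voxel_coords(dim3, rep(spacing, 3), c(0, 0, 0))
  pcoords <- xyz[which(ptv), , drop = FALSE]
  dmin <- rep(Inf, nrow(xyz))
  for (r in seq_len(nrow(pcoords))) {
    d <- sqrt(rowSums(sweep(xyz, 2, pcoords[r, ], "-")^2))
    dmin <- pmin(dmin, d)
  }
  lo <- 10 * distance_cm
  array(dmin >= lo & dmin < lo + thickness_mm, dim3) & body & !ptv
}

# random blob mask: union of a few random balls
random_blob <- function(dim3, spacing, n_balls = 3, rmax = 3 * spacing) {
  xyz <- shellplan:::voxel_coords(dim3, rep(spacing, 3), c(0, 0, 0))
  ctr_lim <- (dim3 - 1) / 2 * spacing * 0.4
  m <- rep(FALSE, nrow(xyz))
  for (b in seq_len(n_balls)) {
    ctr <- runif(3, -1, 1) * ctr_lim
    r <- runif(1, spacing, rmax)
    m <- m | sqrt(rowSums(sweep(xyz, 2, ctr, "-")^2)) <= r
  }
  array(m, dim3)
}

# A small end-to-end planning context on a coarse grid, cached per session.
mini_context <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ph <- generate_phantom(phantom_spec(ptv_volume_cc = 2.9, voxel_mm = 4,
                                        head_radii_mm = c(55, 65, 60),
                                        rng_seed = 3))
    sh_opt <- suppressWarnings(
      build_shell_set(ph$masks$PTV, ph$masks$body, ph$spacing_mm, c(1, 2, 3), 4))
    nodes <- generate_node_set(60, ph)
    infl <- build_influence_matrix(nodes, shellplan:::pick_collimators(ph, 2),
                                   beam_kernel_params(), ph)
    st <- gather_structures(ph, sh_opt)
    wl <- default_vs_wishlist(shell_distances_cm = c(1, 2, 3))
    sol <- solve_lexicographic(infl, wl, st)
    cache <<- list(ph = ph, sh_opt = sh_opt, infl = infl, st = st, wl = wl,
                   sol = sol,
                   oar = c(brainstem = 12, cochlea = 12,
                           trigeminal_nerve = 15, facial_nerve = 15))
    cache
  }
})

# brute-force exact Wilcoxon: enumerate all 2^n sign assignments directly
brute_wilcoxon_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- drop(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

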