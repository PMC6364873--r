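# Plain-R reimplementation of the cone kernel used as the brute-force
# oracle: straightforward per-voxel loop, no sparsity shortcuts, same
# geometric definitions (flat core + erfc penumbra, bisection entry depth).
oracle_beam_dose <- function(beam, kernel, phantom, n_bisect = 30L) {
  out <- array(0, phantom$dim)
  idx <- which(phantom$masks$body)
  src <- beam$source
  u <- beam$aim - src
  u <- u / sqrt(sum(u^2))
  for (v in idx) {
    pos <- shellplan:::voxel_coords(phantom$dim, rep(phantom$spacing_mm, 3),
                                    phantom$origin, v)[1, ]
    p <- pos - src
    s_ax <- sum(p * u)
    if (s_ax <= 0) next
    rho <- sqrt(max(0, sum(p^2) - s_ax^2))
    fr <- beam$collimator_diameter_mm / 2 * s_ax / kernel$sad_mm
    if (rho > fr + 4 * kernel$penumbra_sigma_mm) next
    lo <- 0; hi <- 1
    for (b in seq_len(n_bisect)) {
      mid <- (lo + hi) / 2
      if (shellplan:::points_in_mask(matrix(src + mid * (pos - src), 1),
                                     phantom, "body")) hi <- mid else lo <- mid
    }
    len <- sqrt(sum(p^2))
    depth <- (1 - (lo + hi) / 2) * len
    pen <- if (rho <= fr) 1 else 2 * pnorm(-(rho - fr) / kernel$penumbra_sigma_mm)
    out[v] <- kernel$output_cgy_per_mu * (kernel$sad_mm / len)^2 *
      exp(-kernel$mu_att_per_mm * (depth - kernel$ref_depth_mm)) * pen
  }
  out
}

test_that("node sets are on the cap sphere with positive pairwise separation", {
  ph <- raw_phantom(dim = c(21, 21, 21), spacing = 4)
  ns <- generate_node_set(179, ph, standoff_mm = 300)
  expect_equal(ns$count, 179)
  radii <- sqrt(rowSums(ns$positions^2))
  expect_equal(radii, rep(max(ph$spec$head_radii_mm) + 300, 179),
               tolerance = 1e-12)
  # polar angles stay within the cap
  polar <- acos(ns$positions[, 3] / radii) * 180 / pi
  expect_true(all(polar <= 120 + 1e-9))
  # exhaustive O(n^2) minimum pairwise angle
  dirs <- ns$positions / radii
  cosangles <- tcrossprod(dirs)
  diag(cosangles) <- -1
  expect_lt(max(cosangles), 1 - 1e-6) # min angle > 0
  # single node is the apex
  n1 <- generate_node_set(1, ph, standoff_mm = 300)
  expect_equal(drop(n1$positions), c(0, 0, max(ph$spec$head_radii_mm) + 300))
  # determinism
  expect_identical(ns$positions,
                   generate_node_set(179, ph, standoff_mm = 300)$positions)
  # nodes inside the body are refused
  expect_error(generate_node_set(10, ph, standoff_mm = -20), "inside the body")
})

test_that("an on-axis voxel at reference depth receives the calibration output", {
  dim3 <- c(11, 11, 21)
  ph <- raw_phantom(dim3, spacing = 2, body_semiaxes = c(1e6, 1e6, 1e6))
  ph$masks$body[] <- TRUE # slab body filling the whole grid
  k <- beam_kernel_params()
  # grid spans z in [-20, 20]; body membership ends at z = 21 (half voxel)
  z_top <- 21
  z_v <- z_top - k$ref_depth_mm # voxel at exactly ref depth: z = 6
  src <- c(0, 0, z_v + k$sad_mm)
  bm <- candidate_beam(1, src, c(0, 0, 0), 20)
  d <- beam_dose(bm, k, ph)
  i <- shellplan:::linear_index(matrix(c(5, 5, (z_v - ph$origin[3]) / 2), 1), dim3)
  expect_equal(d[i], k$output_cgy_per_mu, tolerance = 1e-6)
})

test_that("doses separated by one half-value layer have ratio 2", {
  dim3 <- c(9, 9, 101)
  ph <- raw_phantom(dim3, spacing = 2)
  ph$masks$body[] <- TRUE
  mu <- log(2) / 138 # half-value layer = 138 mm, a whole number of voxels
  k <- beam_kernel_params(mu_att_per_mm = mu)
  src <- c(0, 0, 2000)
  bm <- candidate_beam(1, src, c(0, 0, 0), 30)
  d <- beam_dose(bm, k, ph)
  z1 <- 60; z2 <- z1 - 138
  i1 <- shellplan:::linear_index(matrix(c(4, 4, (z1 - ph$origin[3]) / 2), 1), dim3)
  i2 <- shellplan:::linear_index(matrix(c(4, 4, (z2 - ph$origin[3]) / 2), 1), dim3)
  # remove the inverse-square correction, leaving pure attenuation
  r1 <- src[3] - z1; r2 <- src[3] - z2
  ratio <- (d[i1] * r1^2) / (d[i2] * r2^2)
  expect_equal(ratio, 2, tolerance = 1e-6)
})

test_that("the compiled kernel matches a straightforward per-voxel oracle", {
  ph <- raw_phantom(dim = c(8, 8, 8), spacing = 3)
  k <- beam_kernel_params()
  set.seed(4)
  for (rep in 1:3) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    bm <- candidate_beam(1, dir * 500, c(0, 0, 0),
                         sample(c(10, 20, 40), 1))
    expect_lt(max(abs(beam_dose(bm, k, ph) - oracle_beam_dose(bm, k, ph))),
              1e-9)
  }
})

test_that("influence matrix columns follow the node x collimator product", {
  ph <- generate_phantom(phantom_spec(voxel_mm = 4, rng_seed = 6))
  ns <- generate_node_set(179, ph)
  infl <- build_influence_matrix(ns, c(15, 25, 40), beam_kernel_params(), ph)
  expect_equal(ncol(infl$A), 537)
  expect_equal(nrow(infl$beams), 537)
  expect_true(all(infl$A@x >= 0))
  expect_equal(nrow(infl$A), sum(ph$masks$body))
})

test_that("truncation changes per-column totals by less than 1e-4 relative", {
  ph <- raw_phantom(dim = c(13, 13, 13), spacing = 3)
  ns <- generate_node_set(12, ph, standoff_mm = 300)
  k <- beam_kernel_params()
  full <- build_influence_matrix(ns, c(20), k, ph, truncation_rel = 0)
  trunc <- build_influence_matrix(ns, c(20), k, ph, truncation_rel = 1e-6)
  cs_full <- Matrix::colSums(full$A)
  cs_trunc <- Matrix::colSums(trunc$A)
  nz <- cs_full > 0
  expect_true(all(abs(cs_full[nz] - cs_trunc[nz]) / cs_full[nz] < 1e-4))
})

test_that("dose is linear in the beam weights", {
  ph <- raw_phantom(dim = c(13, 13, 13), spacing = 3)
  ns <- generate_node_set(5, ph, standoff_mm = 300)
  k <- beam_kernel_params()
  infl <- build_influence_matrix(ns, c(20), k, ph, truncation_rel = 0)
  set.seed(9)
  w <- runif(5, 0, 10)
  combined <- dose_grid(infl, w)
  accum <- array(0, ph$dim)
  for (j in 1:5) {
    bm <- candidate_beam(j, ns$positions[j, ], infl$beams$aim_x[j] * c(1, 0, 0) +
                           infl$beams$aim_y[j] * c(0, 1, 0) +
                           infl$beams$aim_z[j] * c(0, 0, 1), 20)
    accum <- accum + w[j] * beam_dose(bm, k, ph) / 100
  }
  expect_equal(combined, accum, tolerance = 1e-10)
})

test_that("dose decreases with source distance along the axis when mu ~ 0", {
  dim3 <- c(9, 9, 41)
  ph <- raw_phantom(dim3, spacing = 2)
  ph$masks$body[] <- TRUE
  k <- beam_kernel_params(mu_att_per_mm = 1e-12)
  bm <- candidate_beam(1, c(0, 0, 900), c(0, 0, 0), 25)
  d <- beam_dose(bm, k, ph)
  axis <- d[5, 5, ]
  expect_true(all(diff(axis) > 0)) # z increases toward the source
})

test_that("aim sampling is deterministic under a fixed seed", {
  ph <- generate_phantom(phantom_spec(voxel_mm = 4, rng_seed = 6))
  ns <- generate_node_set(20, ph)
  a <- build_influence_matrix(ns, c(20), beam_kernel_params(), ph,
                              aim_k = 3, aim_seed = 5)
  b <- build_influence_matrix(ns, c(20), beam_kernel_params(), ph,
                              aim_k = 3, aim_seed = 5)
  expect_identical(a$beams, b$beams)
  expect_equal(a$A, b$A)
})

test_that("degenerate beams are reported", {
  ph <- raw_phantom()
  expect_error(beam_dose(candidate_beam(1, c(0, 0, 500), c(500, 500, 500), 20),
                         beam_kernel_params(), ph), "outside the body")
  expect_error(candidate_beam(1, c(0, 0, 500), c(0, 0, 0), 45), "\\[10, 40\\]")
  # a beam pointing away from the body delivers nothing
  coords <- shellplan:::voxel_coords(ph$dim, rep(ph$spacing_mm, 3), ph$origin,
                                     which(ph$masks$body))
  bm <- structure(list(node_index = 1, source = c(0, 0, 500),
                       aim = c(0, 0, 600), collimator_diameter_mm = 20),
                  class = "vs_beam")
  expect_warning(e <- shellplan:::beam_dose_entries(bm, beam_kernel_params(),
                                                    ph, coords),
                 "misses the body")
  expect_length(e$x, 0)
})
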