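#' Specify a synthetic head phantom
#'
#' A phantom spec describes one synthetic "patient": an ellipsoidal head
#' contour enclosing a lateralized ellipsoidal target (the vestibular
#' schwannoma PTV; GTV = PTV, no margin), a vertical brainstem cylinder at a
#' prescribed surface gap from the target, a small cochlea sphere, and two
#' thin nerve tubes touching the target surface. All geometry is voxelized on
#' an isotropic grid and generation is fully determined by `rng_seed`.
#'
#' @param ptv_volume_cc Target volume in cc. The cohort generator samples
#'   this log-uniformly on \[1.0, 7.3\] cc, the range spanned by the
#'   reference clinical population (mean 2.9 cc).
#' @param voxel_mm Isotropic voxel spacing in mm (default 2; 4 is convenient
#'   for fast experimentation).
#' @param head_radii_mm Three semi-axes (mm) of the ellipsoidal head contour
#'   in (lateral, antero-posterior, cranio-caudal) order.
#' @param ptv_brainstem_gap_mm Non-negative surface gap (mm) between PTV and
#'   brainstem.
#' @param cochlea_offset_mm Lateral offset (mm) of the cochlea centre beyond
#'   the PTV's lateral extent.
#' @param rng_seed Integer seed controlling target shape, orientation, side
#'   and position jitter.
#' @return An object of class `vs_phantom_spec`.
#' @export
phantom_spec <- function(ptv_volume_cc = 2.9, voxel_mm = 2,
                         head_radii_mm = c(75, 90, 80),
                         ptv_brainstem_gap_mm = 1.5,
                         cochlea_offset_mm = 8,
                         rng_seed = 1L) {
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) abort("voxel_mm must be > 0")
  if (ptv_volume_cc <= 0) abort("ptv_volume_cc must be > 0")
  if (ptv_brainstem_gap_mm < 0) abort("ptv_brainstem_gap_mm must be >= 0")
  if (length(head_radii_mm) != 3L || any(head_radii_mm <= 0))
    abort("head_radii_mm must be three positive semi-axes")
  structure(
    list(ptv_volume_cc = ptv_volume_cc, voxel_mm = voxel_mm,
         head_radii_mm = as.double(head_radii_mm),
         ptv_brainstem_gap_mm = ptv_brainstem_gap_mm,
         cochlea_offset_mm = cochlea_offset_mm,
         rng_seed = as.integer(rng_seed)),
    class = "vs_phantom_spec"
  )
}

# Names a phantom is allowed to carry; optic structures and the like receive
# near-zero dose in this geometry and are not modelled.
phantom_structures <- function() {
  c("body", "PTV", "brainstem", "cochlea", "trigeminal_nerve", "facial_nerve")
}

# minimum spacing at which `vol_cc` is realizable (>= 10 voxels in target)
min_realizable_spacing <- function(vol_cc) (vol_cc * 1000 / 10)^(1 / 3)

# ellipsoid membership for voxel-centre coordinates `xyz` (n x 3)
ellipsoid_mask_vals <- function(xyz, centre, rot, semiaxes) {
  q <- sweep(xyz, 2L, centre, "-") %*% rot # rotate into principal frame
  rowSums(sweep(q, 2L, semiaxes, "/")^2) <= 1
}

# voxels within radius r of the segment from p0 to p0 + len * dir
tube_mask_vals <- function(xyz, p0, dir, len, r) {
  d <- sweep(xyz, 2L, p0, "-")
  t <- pmin(pmax(d %*% dir, 0), len)
  drop(rowSums(d^2) - t^2) <= r^2
}

# uniformly random proper rotation matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L))
  r <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(r) < 0) r[, 3L] <- -r[, 3L]
  r
}

#' Generate a synthetic head phantom
#'
#' Deterministically voxelizes the spec onto an isotropic grid. The PTV is a
#' randomly oriented ellipsoid at a lateral posterior-fossa-like position;
#' its voxelized volume is calibrated to the requested volume by iterative
#' rescaling, and its surface gap to the brainstem is tuned by whole-voxel
#' lateral shifts (which leave the voxel count unchanged).
#'
#' @param spec A [phantom_spec()].
#' @return A `vs_phantom`: named logical masks over one grid, plus
#'   `spacing_mm`, `origin` (physical position of voxel (0,0,0); voxel-centre
#'   convention) and the generating spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "vs_phantom_spec"))
  h <- spec$voxel_mm
  if (h > min_realizable_spacing(spec$ptv_volume_cc)) {
    abort(sprintf(
      "PTV volume %.2f cc is not realizable at %.3g mm spacing; use voxel_mm <= %.3g mm",
      spec$ptv_volume_cc, h, min_realizable_spacing(spec$ptv_volume_cc)))
  }
  radii <- spec$head_radii_mm
  half <- ceiling((radii + 2 * h) / h)
  dim3 <- 2L * as.integer(half) + 1L
  origin <- -(dim3 - 1) / 2 * h
  xyz <- voxel_coords(dim3, rep(h, 3L), origin)

  body_v <- (xyz[, 1]^2 / radii[1]^2 + xyz[, 2]^2 / radii[2]^2 +
               xyz[, 3]^2 / radii[3]^2) <= 1

  # brainstem: vertical cylinder, radius 6 mm, slightly posterior of centre
  bs_r <- 6
  bs_xy <- c(0, -10)
  bs_z <- c(-0.65, 0.45) * radii[3]
  bs_v <- ((xyz[, 1] - bs_xy[1])^2 + (xyz[, 2] - bs_xy[2])^2 <= bs_r^2) &
    xyz[, 3] >= bs_z[1] & xyz[, 3] <= bs_z[2]

  geom <- with_seed(spec$rng_seed, {
    list(rot = random_rotation(),
         ratios = c(1, runif(2L, 0.75, 1.35)),
         side = sample(c(-1, 1), 1L),
         y0 = bs_xy[2] + runif(1L, -4, 4),
         z0 = runif(1L, -15, 5))
  })
  lam <- (3 * spec$ptv_volume_cc * 1000 / (4 * pi * prod(geom$ratios)))^(1 / 3)
  semiaxes <- lam * geom$ratios
  ext_x <- sqrt(sum((geom$rot[1, ] * semiaxes)^2)) # lateral extent of ellipsoid

  centre0 <- c(geom$side * (bs_r + spec$ptv_brainstem_gap_mm + ext_x + 1),
               geom$y0, geom$z0)
  # snap to the voxel lattice so later whole-voxel shifts stay lattice-aligned
  centre0 <- origin + round((centre0 - origin) / h) * h

  # calibrate the voxel count by monotone bisection on the global scale
  # (multiplicative updates alone oscillate across the discrete counts)
  target_n <- spec$ptv_volume_cc * 1000 / h^3
  count_at <- function(s) sum(ellipsoid_mask_vals(xyz, centre0, geom$rot,
                                                  semiaxes * s))
  s_lo <- s_hi <- 1
  while (count_at(s_lo) > target_n && s_lo > 0.3) s_lo <- s_lo * 0.9
  while (count_at(s_hi) < target_n && s_hi < 3) s_hi <- s_hi * 1.1
  best <- NULL
  for (it in seq_len(25L)) {
    s_mid <- (s_lo + s_hi) / 2
    cnt <- count_at(s_mid)
    if (is.null(best) || abs(cnt - target_n) < abs(best$cnt - target_n))
      best <- list(cnt = cnt, scale = s_mid)
    if (cnt < target_n) s_lo <- s_mid else s_hi <- s_mid
  }
  for (s in c(s_lo, s_hi)) {
    cnt <- count_at(s)
    if (abs(cnt - target_n) < abs(best$cnt - target_n))
      best <- list(cnt = cnt, scale = s)
  }
  ptv_v <- ellipsoid_mask_vals(xyz, centre0, geom$rot, semiaxes * best$scale)
  if (abs(best$cnt - target_n) / target_n > 0.10) {
    abort(sprintf(
      "PTV volume %.2f cc not realizable within 10%% at %.3g mm spacing; use voxel_mm <= %.3g mm",
      spec$ptv_volume_cc, h, min_realizable_spacing(spec$ptv_volume_cc)))
  }
  semiaxes <- semiaxes * best$scale

  # tune the brainstem gap by whole-voxel lateral shifts (count-preserving)
  bs_mask <- array(bs_v, dim3)
  edt_bs <- distance_transform(bs_mask, h)
  centre <- centre0
  for (it in seq_len(12L)) {
    gap_meas <- min(edt_bs[array(ptv_v, dim3)]) - h # centre-to-centre minus one voxel
    shift_vox <- round((gap_meas - spec$ptv_brainstem_gap_mm) / h)
    if (shift_vox == 0L) break
    centre[1] <- centre[1] - geom$side * shift_vox * h
    ptv_v <- ellipsoid_mask_vals(xyz, centre, geom$rot, semiaxes)
  }

  # cochlea: small sphere lateral to the target
  co_r <- 2.8
  co_c <- centre + c(geom$side * (ext_x * best$scale + spec$cochlea_offset_mm), 0, -3)
  co_v <- rowSums(sweep(xyz, 2L, co_c, "-")^2) <= co_r^2

  # nerve tubes anchored at the target centroid, clipped to outside the PTV,
  # so each tube abuts the target surface
  d1 <- c(-geom$side * 0.40, 0.75, 0.53); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- c(-geom$side * 0.55, 0.55, -0.63); d2 <- d2 / sqrt(sum(d2^2))
  tn_v <- tube_mask_vals(xyz, centre, d1, 25, 1.7) & !ptv_v
  fn_v <- tube_mask_vals(xyz, centre, d2, 20, 1.7) & !ptv_v

  if (any(ptv_v & !body_v)) abort("internal: PTV clipped by body contour")
  if (any(ptv_v & bs_v)) abort("internal: PTV overlaps brainstem")
  co_v <- co_v & !ptv_v

  masks <- list(
    body = array(body_v, dim3),
    PTV = array(ptv_v, dim3),
    brainstem = array(bs_v & body_v, dim3),
    cochlea = array(co_v & body_v, dim3),
    trigeminal_nerve = array(tn_v & body_v, dim3),
    facial_nerve = array(fn_v & body_v, dim3)
  )
  structure(
    list(spacing_mm = h, origin = origin, dim = dim3, masks = masks,
         spec = spec, ptv_centre = centre, side = geom$side),
    class = "vs_phantom"
  )
}

#' @export
print.vs_phantom <- function(x, ...) {
  cat(sprintf("<vs_phantom> %d x %d x %d @ %g mm\n", x$dim[1], x$dim[2], x$dim[3],
              x$spacing_mm))
  for (nm in names(x$masks))
    cat(sprintf("  %-17s %6d voxels (%.2f cc)\n", nm, sum(x$masks[[nm]]),
                structure_volume_cc(x, nm)))
  invisible(x)
}

#' Volume of a phantom structure in cc
#' @param phantom A `vs_phantom`.
#' @param name Structure name.
#' @export
structure_volume_cc <- function(phantom, name) {
  sum(phantom$masks[[name]]) * phantom$spacing_mm^3 / 1000
}

#' Generate a cohort of synthetic phantoms
#'
#' Emulates the reference study population: target volumes drawn
#' log-uniformly on \[1.0, 7.3\] cc and brainstem gaps uniformly on
#' \[0, 3\] mm; every per-phantom seed is derived deterministically from
#' `seed`, so the same call always reproduces the same cohort.
#'
#' @param n Number of phantoms (>= 1).
#' @param base A [phantom_spec()] supplying all non-sampled parameters.
#' @param seed Integer cohort seed.
#' @return A list of `vs_phantom` objects (class `vs_cohort`).
#' @export
generate_cohort <- function(n, base = phantom_spec(), seed = 7L) {
  stopifnot(n >= 1)
  pars <- with_seed(seed, {
    list(vol = exp(runif(n, log(1.0), log(7.3))), gap = runif(n, 0, 3))
  })
  out <- lapply(seq_len(n), function(i) {
    sp <- base
    sp$ptv_volume_cc <- pars$vol[i]
    sp$ptv_brainstem_gap_mm <- pars$gap[i]
    sp$rng_seed <- derive_seed(seed, i)
    generate_phantom(sp)
  })
  structure(out, class = c("vs_cohort", "list"))
}
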