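# Phantom persistence: one NIfTI volume per structure mask plus a YAML
# sidecar naming the structures and recording spacing, origin and the
# generating spec. Round-trips preserve masks bitwise and spacing to float
# precision. Only isotropic voxels are supported.

write_mask_nifti <- function(mask, spacing_mm, file) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- rep(spacing_mm, 3L)
  RNifti::writeNifti(img, file)
}

read_mask_nifti <- function(file, spacing_mm) {
  img <- RNifti::readNifti(file)
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) {
    abort(sprintf("volume '%s' has anisotropic spacing (%s); only isotropic grids are supported",
                  basename(file), paste(signif(pd, 6), collapse = " x ")))
  }
  if (abs(pd[1] - spacing_mm) > 1e-6 * spacing_mm) {
    abort(sprintf("spacing mismatch for '%s': header %.6g mm, sidecar %.6g mm",
                  basename(file), pd[1], spacing_mm))
  }
  array(as.array(img) > 0, dim(img))
}

#' Write a phantom to a directory
#'
#' Each structure mask is stored as an unsigned-byte NIfTI volume
#' (`<name>.nii.gz`) and `phantom.yaml` records the structure list, spacing,
#' origin, seed and generating spec.
#'
#' @param p A `vs_phantom`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_phantom <- function(p, path) {
  stopifnot(inherits(p, "vs_phantom"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- setNames(paste0(names(p$masks), ".nii.gz"), names(p$masks))
  for (nm in names(p$masks))
    write_mask_nifti(p$masks[[nm]], p$spacing_mm, file.path(path, files[[nm]]))
  sidecar <- list(
    format = "shellplan-phantom-1",
    spacing_mm = p$spacing_mm,
    origin = as.double(p$origin),
    dim = as.integer(p$dim),
    structures = as.list(files),
    ptv_centre = as.double(p$ptv_centre),
    side = p$side,
    spec = list(
      ptv_volume_cc = p$spec$ptv_volume_cc, voxel_mm = p$spec$voxel_mm,
      head_radii_mm = as.double(p$spec$head_radii_mm),
      ptv_brainstem_gap_mm = p$spec$ptv_brainstem_gap_mm,
      cochlea_offset_mm = p$spec$cochlea_offset_mm,
      rng_seed = p$spec$rng_seed
    )
  )
  yaml::write_yaml(sidecar, file.path(path, "phantom.yaml"))
  invisible(path)
}

#' Read a phantom from a directory written by [write_phantom()]
#'
#' @param path Directory containing `phantom.yaml` and the structure volumes.
#' @return A `vs_phantom`.
#' @export
read_phantom <- function(path) {
  sc_file <- file.path(path, "phantom.yaml")
  if (!file.exists(sc_file)) abort(sprintf("no phantom.yaml under '%s'", path))
  sc <- yaml::read_yaml(sc_file)
  known <- phantom_structures()
  unknown <- setdiff(names(sc$structures), known)
  if (length(unknown) > 0)
    abort(sprintf("unknown structure name(s) in sidecar: %s (known: %s)",
                  paste(unknown, collapse = ", "), paste(known, collapse = ", ")))
  masks <- lapply(sc$structures, function(f)
    read_mask_nifti(file.path(path, f), sc$spacing_mm))
  dims <- vapply(masks, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    abort("structure volumes have mismatched grid dimensions")
  sp <- sc$spec
  spec <- phantom_spec(
    ptv_volume_cc = sp$ptv_volume_cc, voxel_mm = sp$voxel_mm,
    head_radii_mm = unlist(sp$head_radii_mm),
    ptv_brainstem_gap_mm = sp$ptv_brainstem_gap_mm,
    cochlea_offset_mm = sp$cochlea_offset_mm, rng_seed = sp$rng_seed
  )
  structure(
    list(spacing_mm = sc$spacing_mm, origin = unlist(sc$origin),
         dim = dim(masks[[1L]]), masks = masks, spec = spec,
         ptv_centre = unlist(sc$ptv_centre), side = sc$side),
    class = "vs_phantom"
  )
}
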