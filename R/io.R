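## ---------------------------------------------------------------------------
## Volume / table / image I/O: NIfTI via RNifti, YAML sidecars, CSV, TIFF
## ---------------------------------------------------------------------------

write_nifti_vol <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a property phantom to a directory
#'
#' One NIfTI volume per quantity (`gd`, `gl`, `t2`, the six tensor
#' components), integer labels as `labels.nii.gz`, and the generator
#' parameters as a YAML sidecar with the label dictionary.
#'
#' @param phantom a `property_phantom`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$spacing
  for (q in c("gd", "gl", "t2"))
    write_nifti_vol(phantom[[q]], file.path(dir, paste0(q, ".nii.gz")), sp)
  write_nifti_vol(phantom$tensors, file.path(dir, "tensors.nii.gz"), sp)
  write_nifti_vol(phantom$labels + 0L, file.path(dir, "labels.nii.gz"), sp)
  meta <- list(grid_shape = as.integer(phantom$grid_shape),
               spacing_mm = as.numeric(sp),
               density_kg_m3 = phantom$density,
               label_dictionary = as.list(region_labels()))
  yaml::write_yaml(meta, file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' Write a wave acquisition as 5-D NIfTI plus YAML sidecar
#'
#' The phase images are stored as a 5-D volume (x, y, z, encoding
#' direction, wave phase); frequency, phase offsets, displacement scale
#' and spacing go to the sidecar.
#'
#' @param acq a `wave_acquisition`.
#' @param path output path ending in `.nii.gz` (sidecar `.yaml` is placed
#'   next to it).
#' @return `path`, invisibly.
#' @export
write_wave_acquisition <- function(acq, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_nifti_vol(acq$phase_images, path, acq$spacing)
  side <- sub("\\.nii(\\.gz)?$", ".yaml", path)
  yaml::write_yaml(list(frequency_hz = acq$frequency,
                        phase_offsets_rad = as.numeric(acq$phase_offsets),
                        scale_rad_per_m = acq$scale,
                        spacing_mm = as.numeric(acq$spacing),
                        wrap_applied = acq$wrap_applied), side)
  invisible(path)
}

#' Read a wave acquisition written by [write_wave_acquisition()]
#'
#' @param path the `.nii.gz` path; the `.yaml` sidecar must sit next to
#'   it.
#' @return a `wave_acquisition`.
#' @export
read_wave_acquisition <- function(path) {
  side <- sub("\\.nii(\\.gz)?$", ".yaml", path)
  meta <- yaml::read_yaml(side)
  ph <- array(as.numeric(RNifti::readNifti(path)),
              dim = dim(RNifti::readNifti(path)))
  structure(list(phase_images = ph,
                 phase_offsets = meta$phase_offsets_rad,
                 scale = meta$scale_rad_per_m,
                 frequency = meta$frequency_hz,
                 spacing = meta$spacing_mm,
                 wrap_applied = isTRUE(meta$wrap_applied)),
            class = "wave_acquisition")
}

#' Write elastogram maps to a directory
#'
#' @param elast an `elastogram`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_elastogram <- function(elast, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- elast$spacing
  write_nifti_vol(elast$gd, file.path(dir, "gd.nii.gz"), sp)
  write_nifti_vol(elast$gl, file.path(dir, "gl.nii.gz"), sp)
  write_nifti_vol(elast$gstar, file.path(dir, "gstar.nii.gz"), sp)
  y <- elast$y; y[is.na(y)] <- 0
  write_nifti_vol(y, file.path(dir, "y.nii.gz"), sp)
  write_nifti_vol(elast$validity + 0L, file.path(dir, "validity.nii.gz"), sp)
  invisible(dir)
}

#' Write a histology image as 8-bit RGB TIFF
#'
#' @param image a `histo_image`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_histo_tiff <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(image$pixels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit RGB TIFF as a plain pixel array
#'
#' @param path `.tif` path.
#' @return height x width x 3 array of 0-255 intensities.
#' @export
read_histo_tiff <- function(path) {
  round(tiff::readTIFF(path) * 255)
}

#' Write / read a longitudinal table as tidy CSV
#'
#' @param table data.frame of longitudinal records.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_longitudinal_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_longitudinal_table
#' @export
read_longitudinal_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
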