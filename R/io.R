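# Disk formats: NIfTI-1 for volumes and 4D series (RNifti), JSON for ground
# truth and sidecars (jsonlite), YAML for protocols, PNG label images for
# histology fields.  Uncompressed .nii is written so reruns are
# byte-identical (no gzip timestamps).

.as_nifti <- function(arr, voxel_size_mm = 0.5) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxel_size_mm, 3),
                           rep(1, length(dim(arr)) - 3))
  img
}

#' Write/read a 3D or 4D array as NIfTI-1
#'
#' @param x Numeric array, [parameter_map()], [signal_stack()] or
#'   [dynamic_series()] (the value/volume array is written).
#' @param path Output path (`.nii`; uncompressed for reproducible bytes).
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   plain numeric array.
#' @export
write_volume <- function(x, path, voxel_size_mm = 0.5) {
  arr <- if (inherits(x, "signal_stack")) x$volumes
  else if (inherits(x, "dynamic_series")) x$frames
  else map_values(x)
  RNifti::writeNifti(.as_nifti(arr, voxel_size_mm), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Write/read a phantom label map as NIfTI (int16)
#'
#' @param labels A [phantom_label_map()].
#' @param path Output `.nii` path.
#' @return `read_label_map` returns a [phantom_label_map()].
#' @export
write_label_map <- function(labels, path) {
  img <- .as_nifti(labels$labels, labels$voxel_size_mm)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  phantom_label_map(array(as.integer(img), dim(img)), voxel_size_mm = vox)
}

#' Serialize ground truth to JSON
#'
#' Writes the per-ROI [ground_truth_record()]s (including solved curve
#' parameters and closed-form AUCs) with full numeric precision, so that a
#' write/read cycle is lossless.
#'
#' @param ground_truth Named list of [ground_truth_record()]s.
#' @param path Output `.json` path.
#' @return `read_ground_truth` returns the named record list.
#' @export
write_ground_truth <- function(ground_truth, path) {
  payload <- lapply(ground_truth, unclass)
  # 17 significant digits guarantee an exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(r) {
    for (f in c("t1_ms", "t2_ms", "ce_t1_ms", "adc_mm2_per_s", "m0",
                "auc30_true", "auc300_true"))
      r[[f]] <- as.numeric(r[[f]])
    r$curve_params <- lapply(r$curve_params, as.numeric)
    structure(r, class = "ground_truth_record")
  })
}

#' Write/read a histology field as PNG plus JSON sidecar
#'
#' The class image is stored as an 8-bit grayscale PNG of raw class codes
#' (lossless for the 5-class dictionary); pixel size, magnification and the
#' class map go to a `.json` sidecar next to it.
#'
#' @param field A [histology_field()].
#' @param path Output `.png` path.
#' @return `read_histology_field` returns a [histology_field()].
#' @export
write_histology_field <- function(field, path) {
  stopifnot(inherits(field, "histology_field"))
  png::writePNG(field$classes / 255, path)
  sidecar <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(pixel_size_um = field$pixel_size_um,
                            magnification = field$magnification,
                            class_map = as.list(HISTO_CLASSES)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_histology_field
#' @export
read_histology_field <- function(path) {
  cls <- round(png::readPNG(path) * 255)
  meta <- jsonlite::read_json(sub("\\.png$", ".json", path),
                              simplifyVector = TRUE)
  histology_field(matrix(as.integer(cls), nrow(cls), ncol(cls)),
                  pixel_size_um = meta$pixel_size_um,
                  magnification = meta$magnification)
}

#' Write ROI concentration curves as CSV
#'
#' @param curves Named list of `concentration_curve`s (names = ROI).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(names(curves), function(roi) {
    data.frame(time_s = curves[[roi]]$times_s,
               conc_mM = curves[[roi]]$conc_mM, roi = roi)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
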