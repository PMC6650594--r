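#' Image volume container
#'
#' A thin S3 wrapper around a numeric 3D (or 4D, for diffusion series) array
#' plus the voxel spacing in millimetres. Carrier for phantom images and
#' scalar maps (FA, MD).
#'
#' @param data numeric array, 3 or 4 dimensions.
#' @param voxel_size_mm positive numeric triple, spacing of the first three
#'   dimensions in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop_mri("image_volume requires a 3D or 4D array, got %d dims",
             length(dim(data)))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop_mri("voxel_size_mm must be a positive triple")
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = "image_volume")
}

#' Integer label map container
#'
#' @param data integer-valued array, 3 dimensions; 0 is background.
#' @param voxel_size_mm positive numeric triple (mm).
#' @param labels optional named character vector mapping label value to name.
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, voxel_size_mm = c(1, 1, 1), labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_mri("label_map requires a 3D array")
  if (any(data != round(data)) || any(data < 0))
    stop_mri("label values must be nonnegative integers")
  storage.mode(data) <- "integer"
  obj <- image_volume(data, voxel_size_mm)
  obj$labels <- labels
  class(obj) <- c("label_map", "image_volume")
  obj
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels @ %s mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_mm, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

# voxel volume in mm^3
voxel_volume <- function(vol) prod(vol$voxel_size_mm)

# Coordinates (mm) of voxel centres along one axis: (i - 0.5) * spacing,
# measured from the grid corner.
axis_coords <- function(n, spacing) (seq_len(n) - 0.5) * spacing

same_grid <- function(a, b) {
  identical(dim(a$data)[1:3], dim(b$data)[1:3]) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < 1e-6
}
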