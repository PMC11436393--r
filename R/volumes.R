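#' Material class codes for label volumes
#'
#' Integer voxel classes, ordered by X-ray attenuation: background (lumen /
#' air), soft tissue, radiolucent degradation product (MgO-like, darker than
#' the alloy), magnesium alloy, and radiodense degradation product
#' (Ca/P-salt-like, brighter than the alloy).
#'
#' @format Named integer vector.
#' @export
MATERIAL_CLASSES <- c(BACKGROUND = 0L, TISSUE = 1L, PRODUCT_LUCENT = 2L,
                      MG_ALLOY = 3L, PRODUCT_DENSE = 4L)

new_volume <- function(data, spacing, origin, class) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  check_scalar_num(spacing, "spacing", 0, strict_lower = TRUE)
  stopifnot(is.numeric(origin), length(origin) == 3)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = class)
}

#' Label and grayscale voxel volumes
#'
#' A volume is a 3D array (x, y, z; column-major, z along the device axis)
#' with isotropic voxel spacing in mm and the physical coordinate of the
#' first voxel center (`origin`, mm). `label_volume` holds integer material
#' classes from [MATERIAL_CLASSES]; `voxel_volume` holds finite grayvalues.
#'
#' @param data 3D array.
#' @param spacing Voxel edge length (mm).
#' @param origin Physical position of voxel (1,1,1) center (mm).
#' @return An object of class `label_volume` or `voxel_volume`.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  if (!all(data %in% MATERIAL_CLASSES)) {
    abort_field("labels", "labels must be drawn from MATERIAL_CLASSES (0..4)")
  }
  new_volume(data, spacing, origin, "label_volume")
}

#' @rdname label_volume
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    abort_field("grayvalues", "all grayvalues must be finite")
  }
  new_volume(data, spacing, origin, "voxel_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume %dx%dx%d @ %g mm/voxel\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$spacing))
  print(table(factor(x$data, levels = MATERIAL_CLASSES,
                     labels = names(MATERIAL_CLASSES))))
  invisible(x)
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume %dx%dx%d @ %g mm/voxel, range [%.3g, %.3g]\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$spacing,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# physical voxel-center coordinates along each axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + vol$spacing * (seq_len(dim(vol$data)[axis]) - 1L)
}
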