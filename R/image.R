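#' Construct a 3D image stack with physical voxel size
#'
#' Thin container for one channel of a confocal z-stack: a non-negative 3D
#' intensity array plus the physical voxel size in micrometres. Anisotropy is
#' expected (the z step is typically 7.8-10 um at 10x, much larger than the
#' lateral pixel size). The array is indexed `[x, y, z]` with z as depth from
#' the gel top.
#'
#' @param voxels 3D numeric array of intensities (finite, >= 0).
#' @param voxel_size Numeric length 3, `(dx, dy, dz)` in micrometres.
#' @param channel Cell type imaged in this channel (`"ALL"`, `"MSC"`, `"EC"`,
#'   or any label).
#' @param t_min Acquisition time in minutes, or `NA`.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, voxel_size, channel = "ALL", t_min = NA_real_) {
  if (length(dim(voxels)) != 3) abort("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1)) abort("all stack dimensions must be >= 1")
  if (!all(is.finite(voxels))) abort("stack intensities must be finite")
  if (any(voxels < 0)) abort("stack intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    abort("`voxel_size` must be (dx, dy, dz) in micrometres, all > 0")
  }
  structure(
    list(voxels = voxels, voxel_size = setNames(voxel_size, c("dx", "dy", "dz")),
         channel = channel, t_min = t_min),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels @ (%.2f, %.2f, %.2f) um, channel %s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$channel))
  invisible(x)
}

#' Construct a labelled segmentation volume
#'
#' @param labels 3D integer array; 0 is background, objects are labelled with
#'   positive integers.
#' @param voxel_size `(dx, dy, dz)` in micrometres.
#' @param channel Cell type of the source channel.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, voxel_size, channel = "ALL") {
  if (length(dim(labels)) != 3) abort("`labels` must be a 3D array")
  if (any(labels < 0)) abort("labels must be non-negative integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    abort("`voxel_size` must be (dx, dy, dz) in micrometres, all > 0")
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, voxel_size = setNames(voxel_size, c("dx", "dy", "dz")),
         channel = channel),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  k <- max(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d object(s), channel %s\n",
              d[1], d[2], d[3], k, x$channel))
  invisible(x)
}

#' Number of objects in a label volume
#' @param lab A [label_volume()].
#' @return Integer count of distinct positive labels.
#' @export
n_labels <- function(lab) {
  stopifnot(inherits(lab, "label_volume"))
  length(setdiff(unique(as.vector(lab$labels)), 0L))
}
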