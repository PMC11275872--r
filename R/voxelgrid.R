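# Core image containers: voxel grids and label maps.
#
# Arrays are ordered (z, y, x) throughout; voxel_size is c(z, y, x) in
# micrometres. The physical centre of voxel (i, j, k) is
# ((i - 0.5) vz, (j - 0.5) vy, (k - 0.5) vx).

#' Construct a voxel grid
#'
#' A single-channel 3D intensity volume with physical voxel dimensions, the
#' input type for both segmentation algorithms.
#'
#' @param data 3D nonnegative numeric array ordered (z, y, x); at least two
#'   z-planes.
#' @param voxel_size numeric length 3, micrometres per voxel along (z, y, x).
#'   The default (3, 1.08, 1.08) matches a common confocal acquisition with a
#'   3 um z-step and 1.08 um pixels.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size = c(3, 1.08, 1.08)) {
  abort_if(!is.array(data) || length(dim(data)) != 3,
           "`data` must be a 3D array ordered (z, y, x)")
  abort_if(dim(data)[1] < 2, "a voxel grid needs at least 2 z-planes")
  abort_if(length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
             any(voxel_size <= 0), "`voxel_size` must be 3 positive numbers")
  abort_if(any(data < 0, na.rm = TRUE), "intensities must be nonnegative")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), voxel %s um\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Construct a label map
#'
#' Integer-labeled segmentation volume; 0 is background. Shares shape and
#' voxel size with the grid it was derived from.
#'
#' @param labels 3D integer array (z, y, x); 0 = background.
#' @param voxel_size micrometres per voxel along (z, y, x).
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size = c(3, 1.08, 1.08)) {
  abort_if(!is.array(labels) || length(dim(labels)) != 3,
           "`labels` must be a 3D array ordered (z, y, x)")
  abort_if(any(labels < 0) || any(labels != round(labels)),
           "labels must be nonnegative integers")
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s voxels, %d objects\n",
              paste(dim(x$labels), collapse = " x "),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Write a stack as multi-page TIFF
#'
#' One page per z-plane, 16-bit. Intensities are stored as
#' `round(x / scale * 65535)`; `scale` defaults to the stack maximum and is
#' returned so the stack can be re-read on its original scale.
#'
#' @param grid a [voxel_grid()].
#' @param path output file.
#' @param scale intensity mapped to the 16-bit maximum; defaults to
#'   `max(grid$data)`.
#' @return invisibly, the scale used.
#' @export
write_stack_tiff <- function(grid, path, scale = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(scale)) scale <- max(grid$data, 1e-12)
  pages <- lapply(seq_len(dim(grid$data)[1]), function(i) {
    pmin(pmax(grid$data[i, , ] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Read a multi-page TIFF as a voxel grid
#'
#' @param path TIFF file with one page per z-plane.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @param scale intensity corresponding to the 16-bit maximum (the value
#'   returned by [write_stack_tiff()]); default 1 leaves data in `[0, 1]`.
#' @return a [voxel_grid()].
#' @export
read_stack_tiff <- function(path, voxel_size = c(3, 1.08, 1.08), scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  a <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]] * scale
  voxel_grid(a, voxel_size)
}

#' Write a label map as multi-page TIFF
#'
#' Labels are stored losslessly as 16-bit integers (supports up to 65535
#' objects).
#'
#' @param map a [label_map()].
#' @param path output file.
#' @export
write_labels_tiff <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  abort_if(max(map$labels) > 65535, "more than 65535 labels do not fit 16 bits")
  pages <- lapply(seq_len(dim(map$labels)[1]), function(i) {
    map$labels[i, , ] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_labels_tiff()]
#'
#' @param path TIFF file.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @return a [label_map()].
#' @export
read_labels_tiff <- function(path, voxel_size = c(3, 1.08, 1.08)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  a <- array(0L, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) a[i, , ] <- as.integer(round(pages[[i]] * 65535))
  label_map(a, voxel_size)
}

# physical (z, y, x) coordinates (um) of voxel centres given array indices
voxel_centers_um <- function(idx, voxel_size) {
  sweep(idx - 0.5, 2, voxel_size, "*")
}
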