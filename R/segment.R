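# Segmentation algorithms for the two reporter morphologies.

#' Parameters for punctate nuclear (c-Fos-like) segmentation
#'
#' @param bandpass_small,bandpass_large feature diameters (px) of the
#'   Fourier-domain bandpass; defaults 2 and 30 px follow common practice for
#'   ~1 um pixels and nuclear spots.
#' @param rolling_ball_radius rolling-ball radius (px), applied per z-plane.
#' @param maxima_radius integer length 3 (z, y, x): local-maxima neighborhood
#'   radius in voxels. Should be about one nuclear radius in-plane.
#' @param spot_threshold_fraction region-growing acceptance threshold as a
#'   fraction of the seed intensity, in (0, 1).
#' @param min_size,max_size retained object size range in voxels.
#' @param min_seed_intensity minimum intensity for a seed on the filtered
#'   image; `NULL` (default) chooses it automatically as the larger of a
#'   robust noise floor (`median + 5 * mad`) and the Otsu threshold of the
#'   filtered stack, which suppresses both noise seeds and bandpass ringing
#'   and reduces to 0 on empty images.
#' @return an object of class `cfos_params`.
#' @export
cfos_params <- function(bandpass_small = 2, bandpass_large = 30,
                        rolling_ball_radius = 50,
                        maxima_radius = c(1L, 4L, 4L),
                        spot_threshold_fraction = 0.4,
                        min_size = 20, max_size = 1e5,
                        min_seed_intensity = NULL) {
  abort_if(!(bandpass_small < bandpass_large),
           "`bandpass_small` must be < `bandpass_large`")
  abort_if(spot_threshold_fraction <= 0 || spot_threshold_fraction >= 1,
           "`spot_threshold_fraction` must be in (0, 1)")
  abort_if(length(maxima_radius) != 3 || any(maxima_radius < 0),
           "`maxima_radius` must be 3 nonnegative integers (z, y, x)")
  abort_if(min_size < 1 || max_size < min_size, "invalid size range")
  structure(list(bandpass_small = bandpass_small,
                 bandpass_large = bandpass_large,
                 rolling_ball_radius = rolling_ball_radius,
                 maxima_radius = as.integer(maxima_radius),
                 spot_threshold_fraction = spot_threshold_fraction,
                 min_size = min_size, max_size = max_size,
                 min_seed_intensity = min_seed_intensity),
            class = "cfos_params")
}

#' Parameters for soma-plus-process (eYFP-like) segmentation
#'
#' @param background_radius rolling-ball radius (px), per z-plane.
#' @param gaussian_sigma numeric length 3 (z, y, x): anisotropic Gaussian
#'   blur SD in voxels.
#' @param top_percentile fraction of brightest voxels retained by the global
#'   threshold; the default 0.005 keeps the 0.5% brightest voxels of the
#'   stack, which favors somata over thin dim processes.
#' @param h_depth minimum intensity drop (image units) separating two
#'   watershed objects; `NULL` (default) uses 5% of the dynamic range of the
#'   blurred masked image. Larger values suppress over-splitting.
#' @param min_size,max_size retained object size range in voxels.
#' @return an object of class `eyfp_params`.
#' @export
eyfp_params <- function(background_radius = 50,
                        gaussian_sigma = c(0.5, 2, 2),
                        top_percentile = 0.005,
                        h_depth = NULL,
                        min_size = 40, max_size = 1e6) {
  abort_if(top_percentile <= 0 || top_percentile >= 1,
           "`top_percentile` must be in (0, 1)")
  abort_if(length(gaussian_sigma) != 3 || any(gaussian_sigma < 0),
           "`gaussian_sigma` must be 3 nonnegative numbers (z, y, x)")
  abort_if(min_size < 1 || max_size < min_size, "invalid size range")
  structure(list(background_radius = background_radius,
                 gaussian_sigma = as.numeric(gaussian_sigma),
                 top_percentile = top_percentile, h_depth = h_depth,
                 min_size = min_size, max_size = max_size),
            class = "eyfp_params")
}

#' Segment punctate nuclear cells in 3D
#'
#' Pipeline, in fixed order: (1) Fourier-domain bandpass per z-plane
#' retaining features between the two diameters, (2) rolling-ball background
#' subtraction per z-plane, (3) 3D local-maxima seed detection within the
#' `maxima_radius` neighborhood, (4) seeded 3D region growing accepting
#' voxels at or above `spot_threshold_fraction` of the seed intensity,
#' bounded at three times the maxima radius, (5) voxel-count size filtering.
#'
#' @param grid a [voxel_grid()].
#' @param params a [cfos_params()].
#' @return a list with `labels` (a [label_map()]) and `objects` (a tibble of
#'   segmented objects sorted by `object_id`, with centroids in um,
#'   voxel counts, volumes in um^3 and mean raw intensity).
#' @export
segment_cfos <- function(grid, params = cfos_params()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "cfos_params"))
  a <- apply_planewise(grid$data, fft_bandpass,
                       small_d = params$bandpass_small,
                       large_d = params$bandpass_large)
  a <- apply_planewise(a, rolling_ball, radius = params$rolling_ball_radius)
  floor_int <- params$min_seed_intensity
  if (is.null(floor_int)) {
    floor_int <- max(stats::median(a) + 5 * stats::mad(a),
                     if (any(a > 0)) otsu_threshold(a) else 0)
  }
  seeds <- local_maxima_3d(a, params$maxima_radius,
                           min_intensity = floor_int)
  labels <- grow_spots(a, seeds, params$spot_threshold_fraction,
                       max_extent = 3L * params$maxima_radius)
  res <- measure_objects(labels, grid$data, grid$voxel_size,
                         params$min_size, params$max_size)
  list(labels = label_map(res$labels, grid$voxel_size), objects = res$objects)
}

#' Segment soma-plus-process cells in 3D
#'
#' Pipeline, in fixed order: (1) rolling-ball background subtraction per
#' z-plane, (2) anisotropic Gaussian blur, (3) global threshold at the
#' `1 - top_percentile` intensity quantile over all voxels of the stack,
#' (4) watershed of the blurred intensity restricted to the thresholded
#' mask with h-depth minima suppression, (5) voxel-count size filtering.
#' Thin processes fall below the top-percentile threshold after blurring, so
#' somata are preferentially retained.
#'
#' @param grid a [voxel_grid()].
#' @param params an [eyfp_params()].
#' @return as [segment_cfos()].
#' @export
segment_eyfp <- function(grid, params = eyfp_params()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "eyfp_params"))
  a <- apply_planewise(grid$data, rolling_ball,
                       radius = params$background_radius)
  a <- gaussian_blur3d(a, params$gaussian_sigma)
  thr <- stats::quantile(a, 1 - params$top_percentile, names = FALSE)
  mask <- a >= thr & a > 0
  labels <- array(0L, dim(a))
  if (any(mask)) {
    h <- params$h_depth
    masked <- a * mask
    if (is.null(h)) h <- 0.05 * diff(range(masked))
    labels <- watershed3d(masked, h)
  }
  res <- measure_objects(labels, grid$data, grid$voxel_size,
                         params$min_size, params$max_size)
  list(labels = label_map(res$labels, grid$voxel_size), objects = res$objects)
}

#' Apply an exclusion mask to a segmentation
#'
#' Objects whose centroid falls inside the excluded (TRUE) voxels are
#' dropped; stands in for the manual deletion of over-segmentation around
#' autofluorescent structures.
#'
#' @param seg result of [segment_cfos()] or [segment_eyfp()].
#' @param mask logical 3D array, TRUE where detections must be discarded.
#' @return the segmentation with excluded objects removed and relabeled.
#' @export
apply_exclusion_mask <- function(seg, mask) {
  stopifnot(inherits(seg$labels, "label_map"))
  abort_if(!identical(dim(mask), dim(seg$labels$labels)),
           "mask shape must match the label map")
  if (nrow(seg$objects) == 0) return(seg)
  vs <- seg$labels$voxel_size
  pos <- cbind(pmin(pmax(round(seg$objects$centroid_z_um / vs[1] + 0.5), 1),
                    dim(mask)[1]),
               pmin(pmax(round(seg$objects$centroid_y_um / vs[2] + 0.5), 1),
                    dim(mask)[2]),
               pmin(pmax(round(seg$objects$centroid_x_um / vs[3] + 0.5), 1),
                    dim(mask)[3]))
  drop <- mask[pos]
  lab <- seg$labels$labels
  lab[lab %in% seg$objects$object_id[drop]] <- 0L
  res <- measure_objects(lab, lab * 0, vs)  # relabel only
  keep_obj <- seg$objects[!drop, , drop = FALSE]
  keep_obj$object_id <- seq_len(nrow(keep_obj))
  list(labels = label_map(res$labels, vs), objects = keep_obj)
}

#' Write segmented objects as tab-separated text
#'
#' The import contract for the quantification stage: columns object_id,
#' centroid_z_um, centroid_y_um, centroid_x_um, voxel_count, volume_um3,
#' mean_intensity.
#'
#' @param objects object tibble from a segmentation result.
#' @param path output TSV.
#' @export
write_objects_tsv <- function(objects, path) {
  readr::write_tsv(objects[, c("object_id", "centroid_z_um", "centroid_y_um",
                               "centroid_x_um", "voxel_count", "volume_um3",
                               "mean_intensity")], path)
  invisible(path)
}
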