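# The slice/mouse data model: imaging metadata, imported segmentation
# tables, anatomical exclusions, and region assignment of cells.

#' Construct a slice record
#'
#' Imaging-related metadata for one imaged section: identifiers, channel
#' names, the matched anterior-posterior coordinate, imported segmentation
#' objects per channel and per-hemisphere region exclusions.
#'
#' @param slice_id unique identifier within a mouse.
#' @param ap_mm anterior-posterior coordinate of the matched plate (mm).
#' @param channels channel names (unique); the conventional labels are
#'   `ch1` (soma+process reporter), `ch2` (nuclear reporter) and `colabel`.
#' @param image_path optional path reference to the source image.
#' @return object of class `slice_record`.
#' @export
slice_record <- function(slice_id, ap_mm = NA_real_,
                         channels = c("ch1", "ch2", "colabel"),
                         image_path = NULL) {
  abort_if(anyDuplicated(channels) > 0, "channel names must be unique")
  structure(list(slice_id = slice_id, ap_mm = ap_mm, channels = channels,
                 image_path = image_path,
                 objects = stats::setNames(vector("list", length(channels)),
                                           channels),
                 exclusions = tibble::tibble(acronym = character(0),
                                             hemisphere = character(0))),
            class = "slice_record")
}

#' Construct a mouse record
#'
#' Holds subject metadata and an ordered set of [slice_record()]s.
#'
#' @param mouse_id unique subject identifier.
#' @param group experimental group label (e.g. "CT", "IS").
#' @param sex,strain,genotype optional metadata strings.
#' @return object of class `mouse_record`.
#' @export
mouse_record <- function(mouse_id, group, sex = NA_character_,
                         strain = NA_character_, genotype = NA_character_) {
  structure(list(mouse_id = mouse_id, group = group, sex = sex,
                 strain = strain, genotype = genotype, slices = list()),
            class = "mouse_record")
}

#' Add a slice to a mouse record
#'
#' @param mouse a [mouse_record()].
#' @param slice a [slice_record()]; its `slice_id` must be new to the mouse.
#' @return the updated mouse record.
#' @export
add_slice <- function(mouse, slice) {
  stopifnot(inherits(mouse, "mouse_record"), inherits(slice, "slice_record"))
  abort_if(slice$slice_id %in% names(mouse$slices),
           sprintf("slice_id '%s' already present in mouse '%s'",
                   slice$slice_id, mouse$mouse_id))
  mouse$slices[[as.character(slice$slice_id)]] <- slice
  mouse
}

#' Import segmentation object tables into a slice
#'
#' Reads tab-separated object tables (the contract written by
#' [write_objects_tsv()]) for one or more channels and attaches them to the
#' slice. Validation is strict: a missing required column or a non-numeric
#' value aborts with the offending column or row named.
#'
#' @param slice a [slice_record()].
#' @param paths named character vector or list, one TSV path per channel
#'   name.
#' @return the updated slice record.
#' @export
import_segmentation <- function(slice, paths) {
  stopifnot(inherits(slice, "slice_record"))
  abort_if(is.null(names(paths)) || any(names(paths) == ""),
           "`paths` must be named by channel")
  bad <- setdiff(names(paths), slice$channels)
  abort_if(length(bad) > 0,
           paste("unknown channels:", paste(bad, collapse = ", ")))
  need <- c("object_id", "centroid_z_um", "centroid_y_um", "centroid_x_um",
            "voxel_count", "volume_um3", "mean_intensity")
  for (ch in names(paths)) {
    abort_if(!file.exists(paths[[ch]]),
             paste("file not found:", paths[[ch]]))
    df <- readr::read_tsv(paths[[ch]], col_types = readr::cols(.default = "c"))
    missing <- setdiff(need, names(df))
    abort_if(length(missing) > 0,
             sprintf("segmentation table '%s' is missing required column(s): %s",
                     paths[[ch]], paste(missing, collapse = ", ")))
    for (col in need) {
      vals <- suppressWarnings(as.numeric(df[[col]]))
      badrow <- which(is.na(vals) & !is.na(df[[col]]))
      abort_if(length(badrow) > 0,
               sprintf("non-numeric value in column '%s' of '%s' at row %d",
                       col, paths[[ch]], badrow[1]))
      df[[col]] <- vals
    }
    slice$objects[[ch]] <- tibble::as_tibble(df)
  }
  slice
}

#' Assign imported cells to regions via warped coordinates
#'
#' Optionally warps each object's in-plane centroid (x = centroid_x_um,
#' y = centroid_y_um) through a thin-plate spline, then assigns it to the
#' first containing polygon; adds `region` and `hemisphere` columns to every
#' imported channel table.
#'
#' @param slice a [slice_record()] with imported objects.
#' @param polygons list of [region_polygon()]s for this slice's plate.
#' @param transform optional [fit_tps()] transform applied before
#'   assignment.
#' @return the updated slice record.
#' @export
assign_slice_regions <- function(slice, polygons, transform = NULL) {
  stopifnot(inherits(slice, "slice_record"))
  hemi <- vapply(polygons, function(p) p$hemisphere, character(1))
  for (ch in slice$channels) {
    obj <- slice$objects[[ch]]
    if (is.null(obj)) next
    pts <- cbind(obj$centroid_x_um, obj$centroid_y_um)
    if (!is.null(transform)) pts <- warp_points(transform, pts)
    reg <- assign_regions(pts, polygons)
    obj$region <- reg
    obj$hemisphere <- hemi[match(reg, vapply(polygons, function(p) p$acronym,
                                             character(1)))]
    slice$objects[[ch]] <- obj
  }
  slice
}

#' Exclude anatomical regions from downstream aggregation
#'
#' Marks regions (per hemisphere) as excluded for a slice or for every slice
#' of a mouse, emulating the curation of damaged or misaligned regions.
#' Unknown acronyms produce a warning, not an error, so curation lists can
#' be shared across plates.
#'
#' @param target a [slice_record()] or [mouse_record()].
#' @param acronyms character vector of region acronyms to exclude.
#' @param hemisphere "left", "right" or "both" (default).
#' @param known optional vector of valid acronyms used for the misspelling
#'   warning.
#' @return the updated record.
#' @export
exclude_anatomy <- function(target, acronyms,
                            hemisphere = c("both", "left", "right"),
                            known = NULL) {
  hemisphere <- match.arg(hemisphere)
  abort_if(length(acronyms) == 0, "`acronyms` must be nonempty")
  if (!is.null(known)) {
    unknown <- setdiff(acronyms, known)
    if (length(unknown) > 0)
      warning("unknown region acronym(s): ", paste(unknown, collapse = ", "),
              call. = FALSE)
  }
  if (inherits(target, "mouse_record")) {
    target$slices <- lapply(target$slices, exclude_anatomy, acronyms,
                            hemisphere)
    return(target)
  }
  stopifnot(inherits(target, "slice_record"))
  target$exclusions <- dplyr::distinct(dplyr::bind_rows(
    target$exclusions,
    tibble::tibble(acronym = acronyms, hemisphere = hemisphere)))
  target
}

# Is object row (region, hemisphere) excluded by the slice's exclusion list?
is_excluded <- function(region, hemisphere, exclusions) {
  if (nrow(exclusions) == 0 || length(region) == 0)
    return(rep(FALSE, length(region)))
  hemisphere[is.na(hemisphere)] <- "both"
  out <- rep(FALSE, length(region))
  for (i in seq_len(nrow(exclusions))) {
    hit <- region == exclusions$acronym[i] & !is.na(region)
    if (exclusions$hemisphere[i] != "both")
      hit <- hit & (hemisphere == exclusions$hemisphere[i] |
                      hemisphere == "both")
    out <- out | hit
  }
  out
}
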