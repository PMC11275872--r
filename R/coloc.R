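# Co-labeled cell identification by volumetric overlap between the two
# channels' label maps. Overlap is expressed relative to the channel-2
# (nuclear reporter) object volume, since the nucleus is the subset
# structure of a co-labeled cell.

#' Enumerate overlapping object pairs between two label maps
#'
#' Exhaustively reports every (channel-1 object, channel-2 object) pair
#' sharing at least one voxel. The overlap fraction uses the channel-2
#' object's voxel count as denominator.
#'
#' @param map1,map2 [label_map()]s of identical shape and voxel size.
#' @return tibble with columns id_ch1, id_ch2, overlap_voxels,
#'   overlap_fraction, sorted by (id_ch1, id_ch2).
#' @export
colocalize <- function(map1, map2) {
  stopifnot(inherits(map1, "label_map"), inherits(map2, "label_map"))
  abort_if(!identical(dim(map1$labels), dim(map2$labels)),
           "label maps must have identical shapes")
  abort_if(!isTRUE(all.equal(map1$voxel_size, map2$voxel_size)),
           "label maps must have identical voxel sizes")
  empty <- tibble::tibble(id_ch1 = integer(0), id_ch2 = integer(0),
                          overlap_voxels = integer(0),
                          overlap_fraction = numeric(0))
  both <- which(map1$labels > 0L & map2$labels > 0L)
  if (length(both) == 0) return(empty)
  l1 <- map1$labels[both]
  l2 <- map2$labels[both]
  n2 <- tabulate(map2$labels[map2$labels > 0L])
  key <- paste(l1, l2)
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  out <- tibble::tibble(
    id_ch1 = as.integer(parts[, 1]),
    id_ch2 = as.integer(parts[, 2]),
    overlap_voxels = as.integer(agg))
  out$overlap_fraction <- out$overlap_voxels / n2[out$id_ch2]
  dplyr::arrange(out, .data$id_ch1, .data$id_ch2)
}

#' Threshold and deduplicate colocalization records
#'
#' Keeps records whose overlap fraction is at least `min_fraction`; a
#' channel-2 object matched by several channel-1 objects counts as a single
#' co-labeled cell and is reported once with its largest-overlap partner.
#'
#' @param records tibble from [colocalize()].
#' @param min_fraction minimum overlap fraction in `[0, 1]`; default 0.25.
#' @return filtered tibble, one row per co-labeled channel-2 object.
#' @export
filter_coloc <- function(records, min_fraction = 0.25) {
  abort_if(min_fraction < 0 || min_fraction > 1,
           "`min_fraction` must be in [0, 1]")
  kept <- records[records$overlap_fraction >= min_fraction, , drop = FALSE]
  if (nrow(kept) == 0) return(kept)
  kept <- dplyr::arrange(kept, .data$id_ch2,
                         dplyr::desc(.data$overlap_fraction), .data$id_ch1)
  kept[!duplicated(kept$id_ch2), , drop = FALSE]
}

#' Write colocalization records as TSV
#'
#' @param records tibble from [colocalize()] or [filter_coloc()].
#' @param path output TSV with columns id_ch1, id_ch2, overlap_voxels,
#'   overlap_fraction.
#' @export
write_coloc_tsv <- function(records, path) {
  readr::write_tsv(records[, c("id_ch1", "id_ch2", "overlap_voxels",
                               "overlap_fraction")], path)
  invisible(path)
}
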