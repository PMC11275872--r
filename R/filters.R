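# Image-processing primitives for the segmentation pipelines.

#' Fourier-domain bandpass filter of one z-plane
#'
#' Difference-of-Gaussians transfer function parameterized by feature
#' diameters (px): structures smaller than `small_d` and larger than
#' `large_d` are attenuated; the DC component is removed. Matches the usual
#' FFT-bandpass preprocessing applied before spot detection.
#'
#' @param m numeric matrix (one z-plane).
#' @param small_d,large_d feature diameters in pixels, `small_d < large_d`.
#' @return filtered matrix, clipped at 0.
#' @export
fft_bandpass <- function(m, small_d, large_d) {
  abort_if(!(small_d < large_d), "`small_d` must be < `large_d`")
  d <- dim(m)
  f1 <- (seq_len(d[1]) - 1) / d[1]
  f1 <- pmin(f1, 1 - f1)
  f2 <- (seq_len(d[2]) - 1) / d[2]
  f2 <- pmin(f2, 1 - f2)
  fsq <- outer(f1^2, f2^2, "+")
  sig_s <- small_d / 2
  sig_l <- large_d / 2
  h <- exp(-2 * pi^2 * sig_s^2 * fsq) - exp(-2 * pi^2 * sig_l^2 * fsq)
  out <- Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / length(m)
  pmax(out, 0)
}

#' Rolling-ball background subtraction of one z-plane
#'
#' Estimates the smooth background as the grayscale opening with a disc
#' structuring element of the given radius and subtracts it; the classic
#' background-flattening step before intensity thresholding.
#'
#' @param m numeric matrix.
#' @param radius ball radius in pixels.
#' @return background-subtracted matrix, clipped at 0.
#' @export
rolling_ball <- function(m, radius) {
  abort_if(radius < 1, "`radius` must be >= 1 px")
  side <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  lo <- min(m)
  bg <- EBImage::opening(m - lo, brush) + lo
  pmax(m - bg, 0)
}

# Apply a per-plane (2D) filter to every z-plane of a 3D array.
apply_planewise <- function(a, f, ...) {
  for (i in seq_len(dim(a)[1])) a[i, , ] <- f(a[i, , ], ...)
  a
}

#' 3D local maxima with box suppression
#'
#' A voxel is a candidate seed when it attains the maximum of its box
#' neighborhood of per-axis radius `radius` and exceeds `min_intensity`.
#' Candidates are then greedily thinned in descending intensity order so that
#' no two retained seeds lie within one `radius` box of each other (plateau
#' de-duplication).
#'
#' @param a 3D numeric array (z, y, x).
#' @param radius integer length 3: neighborhood radius per axis (z, y, x).
#' @param min_intensity seeds must strictly exceed this value (default 0).
#' @return integer matrix with columns z, y, x and attribute `"intensity"`.
#' @export
local_maxima_3d <- function(a, radius, min_intensity = 0) {
  stopifnot(length(dim(a)) == 3, length(radius) == 3)
  mx <- box_max_filter(a, as.integer(radius))
  cand <- which(a == mx & a > min_intensity)
  if (length(cand) == 0) {
    out <- matrix(integer(0), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
    attr(out, "intensity") <- numeric(0)
    return(out)
  }
  ord <- order(a[cand], decreasing = TRUE)
  cand <- cand[ord]
  pos <- arrayInd(cand, dim(a))
  keep <- logical(length(cand))
  kept <- matrix(0L, 0, 3)
  for (i in seq_along(cand)) {
    if (nrow(kept) == 0 ||
        !any(abs(kept[, 1] - pos[i, 1]) <= radius[1] &
             abs(kept[, 2] - pos[i, 2]) <= radius[2] &
             abs(kept[, 3] - pos[i, 3]) <= radius[3])) {
      keep[i] <- TRUE
      kept <- rbind(kept, pos[i, , drop = FALSE])
    }
  }
  out <- pos[keep, , drop = FALSE]
  colnames(out) <- c("z", "y", "x")
  attr(out, "intensity") <- a[cand[keep]]
  out
}

#' Seeded 3D region growing
#'
#' Grows each seed into a spot by breadth-first search over 26-connected
#' neighbors, accepting voxels whose intensity is at least
#' `threshold_fraction` times the seed intensity and that lie within a
#' bounding box of per-axis radius `max_extent` around the seed (which
#' prevents bleed-through between touching spots). Seeds are processed in
#' descending intensity order; voxels already claimed by a brighter spot are
#' not re-assigned.
#'
#' @param a 3D numeric array.
#' @param seeds seed matrix from [local_maxima_3d()].
#' @param threshold_fraction fraction of the seed intensity, in (0, 1).
#' @param max_extent integer length 3: growth bound per axis (voxels).
#' @return integer label array of the same shape; label i corresponds to
#'   seed row i.
#' @export
grow_spots <- function(a, seeds, threshold_fraction, max_extent) {
  abort_if(threshold_fraction <= 0 || threshold_fraction >= 1,
           "`threshold_fraction` must be in (0, 1)")
  d <- dim(a)
  labels <- array(0L, d)
  if (nrow(seeds) == 0) return(labels)
  offs <- neighbor_offsets_26()
  ord <- order(attr(seeds, "intensity"), decreasing = TRUE)
  for (s in ord) {
    p <- seeds[s, ]
    if (labels[p[1], p[2], p[3]] != 0L) next
    thr <- threshold_fraction * a[p[1], p[2], p[3]]
    lo <- pmax(c(1L, 1L, 1L), p - max_extent)
    hi <- pmin(d, p + max_extent)
    labels[p[1], p[2], p[3]] <- s
    frontier <- matrix(p, 1, 3)
    while (nrow(frontier) > 0) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                       drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= lo[1] & cand[, 1] <= hi[1] &
        cand[, 2] >= lo[2] & cand[, 2] <= hi[2] &
        cand[, 3] >= lo[3] & cand[, 3] <= hi[3]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) break
      lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
      first <- !duplicated(lin)
      cand <- cand[first, , drop = FALSE]
      lin <- lin[first]
      ok <- labels[lin] == 0L & a[lin] >= thr
      cand <- cand[ok, , drop = FALSE]
      lin <- lin[ok]
      labels[lin] <- s
      frontier <- cand
    }
  }
  labels
}

#' 3D watershed with h-depth minima suppression
#'
#' Classic flood-from-maxima watershed on a 3D intensity landscape: voxels
#' with positive intensity are processed in descending order; each voxel
#' joins the adjacent (26-connected) catchment basin with the highest peak,
#' and two basins meeting at a voxel are merged whenever the shallower
#' basin's peak rises less than `h` above the meeting point (so local maxima
#' shallower than `h` never found their own object).
#'
#' @param a 3D numeric array (z, y, x); zeros are background.
#' @param h minimum intensity depth separating two objects, in image units.
#' @return integer label array of the same shape, basins numbered from 1 in
#'   order of decreasing peak intensity.
#' @export
watershed3d <- function(a, h) {
  stopifnot(length(dim(a)) == 3)
  abort_if(!(h >= 0), "`h` must be nonnegative")
  d <- dim(a)
  fg <- which(a > 0)
  out <- array(0L, d)
  if (length(fg) == 0) return(out)
  ord <- fg[order(a[fg], fg, decreasing = c(TRUE, FALSE), method = "radix")]
  pos <- arrayInd(ord, d)
  offs <- neighbor_offsets_26()
  lab <- integer(prod(d))         # region root per voxel, 0 = unvisited
  parent <- integer(0)            # union-find forest over regions
  peak <- numeric(0)              # peak intensity per region root
  n_reg <- 0L
  for (v in seq_along(ord)) {
    i <- ord[v]
    p <- pos[v, ]
    nb <- offs + rep(p, each = nrow(offs))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    roots <- lab[lin]
    roots <- unique(roots[roots > 0L])
    if (length(roots) > 0) {
      for (k in seq_along(roots)) {        # find with path halving
        r <- roots[k]
        while (parent[r] != r) {
          parent[r] <- parent[parent[r]]
          r <- parent[r]
        }
        roots[k] <- r
      }
      roots <- unique(roots)
    }
    if (length(roots) == 0) {
      n_reg <- n_reg + 1L
      parent[n_reg] <- n_reg
      peak[n_reg] <- a[i]
      lab[i] <- n_reg
    } else if (length(roots) == 1) {
      lab[i] <- roots
    } else {
      best <- roots[which.max(peak[roots])]
      for (r in roots) {
        if (r != best && peak[r] - a[i] < h) parent[r] <- best
      }
      lab[i] <- best
    }
  }
  # resolve roots and renumber by decreasing peak intensity
  final <- lab[fg]
  for (k in seq_along(final)) {
    r <- final[k]
    while (parent[r] != r) {
      parent[r] <- parent[parent[r]]
      r <- parent[r]
    }
    final[k] <- r
  }
  roots <- unique(final)
  roots <- roots[order(peak[roots], decreasing = TRUE)]
  renum <- integer(n_reg)
  renum[roots] <- seq_along(roots)
  out[fg] <- renum[final]
  out
}

# Summarize labeled objects: centroids (um), voxel counts, volumes, mean
# intensity measured on `intensity` (usually the raw grid). Applies the
# [min_size, max_size] voxel-count filter and relabels surviving objects
# 1..n in ascending original label order, rewriting `labels` in place.
measure_objects <- function(labels, intensity, voxel_size,
                            min_size = 1, max_size = Inf) {
  d <- dim(labels)
  idx <- which(labels > 0L)
  empty <- tibble::tibble(object_id = integer(0), centroid_z_um = numeric(0),
                          centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                          voxel_count = integer(0), volume_um3 = numeric(0),
                          mean_intensity = numeric(0))
  if (length(idx) == 0) return(list(labels = labels, objects = empty))
  lab <- labels[idx]
  counts <- tabulate(lab)
  keep_ids <- which(counts >= min_size & counts <= max_size)
  if (length(keep_ids) == 0) return(list(labels = array(0L, d), objects = empty))
  new_id <- integer(length(counts))
  new_id[keep_ids] <- seq_along(keep_ids)
  keep <- new_id[lab] > 0L
  labels[idx[!keep]] <- 0L
  labels[idx[keep]] <- new_id[lab[keep]]
  idx <- idx[keep]
  lab <- new_id[lab[keep]]
  pos <- arrayInd(idx, d)
  cz <- rowsum((pos[, 1] - 0.5) * voxel_size[1], lab)
  cy <- rowsum((pos[, 2] - 0.5) * voxel_size[2], lab)
  cx <- rowsum((pos[, 3] - 0.5) * voxel_size[3], lab)
  mi <- rowsum(intensity[idx], lab)
  n <- tabulate(lab)
  vvol <- prod(voxel_size)
  objects <- tibble::tibble(
    object_id = seq_along(n),
    centroid_z_um = as.vector(cz) / n,
    centroid_y_um = as.vector(cy) / n,
    centroid_x_um = as.vector(cx) / n,
    voxel_count = n,
    volume_um3 = n * vvol,
    mean_intensity = as.vector(mi) / n)
  list(labels = labels, objects = objects)
}
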