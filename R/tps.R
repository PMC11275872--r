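# Thin-plate-spline warping of 2D coordinates fitted to correspondence
# points, as used to deform section coordinates onto a reference plane.

#' Construct a correspondence set
#'
#' Paired (source, target) 2D points in micrometres, the input to
#' [fit_tps()]. Needs at least 3 non-collinear, non-duplicated source points.
#'
#' @param source,target numeric matrices (or data frames) with columns x, y,
#'   one row per correspondence pair.
#' @return an object of class `correspondence_set`.
#' @export
correspondence_set <- function(source, target) {
  source <- as.matrix(source)[, 1:2, drop = FALSE]
  target <- as.matrix(target)[, 1:2, drop = FALSE]
  abort_if(nrow(source) != nrow(target),
           "`source` and `target` must have the same number of points")
  abort_if(nrow(source) < 3, "at least 3 correspondence pairs are required")
  abort_if(anyDuplicated(round(source, 9)) > 0,
           "duplicate source points are not allowed")
  structure(list(source = unname(source), target = unname(target)),
            class = "correspondence_set")
}

# TPS radial kernel U(r) = r^2 log r, with U(0) = 0.
tps_kernel <- function(r) {
  out <- r * r * log(r)
  out[r == 0] <- 0
  out
}

#' Fit an interpolating thin-plate spline
#'
#' Standard 2D TPS with kernel U(r) = r^2 log(r) and zero smoothing, solved
#' from the linear system with the side conditions that the warping
#' coefficients sum to zero and are orthogonal to the coordinates. The
#' resulting transform maps every control source point exactly onto its
#' target.
#'
#' @param cset a [correspondence_set()].
#' @return object of class `tps_transform`: affine part plus one warping
#'   coefficient pair per control point, with the control points retained.
#' @export
fit_tps <- function(cset) {
  stopifnot(inherits(cset, "correspondence_set"))
  src <- cset$source
  n <- nrow(src)
  # Solve in similarity-normalized coordinates for conditioning. With the
  # side conditions (warp coefficients orthogonal to 1, x, y) the TPS
  # interpolant is invariant under a similarity transform of the
  # coordinates, so this changes nothing but the numerics.
  s_center <- colMeans(src)
  s_scale <- sqrt(mean(rowSums(sweep(src, 2, s_center)^2)))
  if (!(s_scale > 0)) s_scale <- 1
  t_center <- colMeans(cset$target)
  src_n <- sweep(src, 2, s_center) / s_scale
  tgt_n <- sweep(cset$target, 2, t_center) / s_scale
  P <- cbind(1, src_n)
  abort_if(qr(P)$rank < 3,
           "control points are collinear; a 2D thin-plate spline is undefined")
  K <- tps_kernel(as.matrix(stats::dist(src_n)))
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(tgt_n, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop("thin-plate spline system is singular (degenerate control points): ",
         conditionMessage(e), call. = FALSE))
  structure(list(control = src_n,
                 warp = coef[seq_len(n), , drop = FALSE],
                 affine = coef[n + 1:3, , drop = FALSE],
                 s_center = s_center, s_scale = s_scale, t_center = t_center),
            class = "tps_transform")
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("<tps_transform> %d control points\n", nrow(x$control)))
  invisible(x)
}

#' Warp 2D points through a fitted thin-plate spline
#'
#' Applies the affine part plus the radial-kernel terms; deterministic and
#' order-preserving. Control source points map exactly onto their targets.
#'
#' @param transform a [tps_transform()] from [fit_tps()].
#' @param points numeric matrix (or data frame) with columns x, y in um; may
#'   have zero rows.
#' @return matrix of warped points, same number of rows as `points`.
#' @export
warp_points <- function(transform, points) {
  stopifnot(inherits(transform, "tps_transform"))
  pts <- as.matrix(points)
  if (nrow(pts) == 0) return(matrix(numeric(0), 0, 2))
  pts <- pts[, 1:2, drop = FALSE]
  pn <- sweep(pts, 2, transform$s_center) / transform$s_scale
  d <- sqrt(outer(pn[, 1], transform$control[, 1], "-")^2 +
              outer(pn[, 2], transform$control[, 2], "-")^2)
  U <- tps_kernel(d)
  out <- cbind(1, pn) %*% transform$affine + U %*% transform$warp
  unname(sweep(out * transform$s_scale, 2, transform$t_center, "+"))
}
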