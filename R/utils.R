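# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the caller's `.Random.seed` afterwards so that all
#' randomness in the package flows through explicitly passed seeds and no
#' hidden global state leaks between calls.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# assert helper: stop with the offending argument named
abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x == round(x)

# Shift a 3D array along one axis by `by` voxels, padding with `fill`.
shift_array <- function(a, axis, by, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (by >= 0) {
    dst[[axis]] <- (1 + by):n
    src[[axis]] <- 1:(n - by)
  } else {
    dst[[axis]] <- 1:(n + by)
    src[[axis]] <- (1 - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# Separable running-max filter over a box of per-axis radius r = c(rz, ry, rx).
box_max_filter <- function(a, r) {
  out <- a
  for (axis in 1:3) {
    if (r[axis] == 0) next
    acc <- out
    for (by in seq_len(r[axis])) {
      acc <- pmax(acc, shift_array(out, axis, by), shift_array(out, axis, -by))
    }
    out <- acc
  }
  out
}

# Gaussian kernel of standard deviation sigma (voxels), radius ceil(3*sigma).
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a 1D kernel, renormalizing the
# truncated kernel at the borders (so flat regions stay flat).
convolve_axis <- function(a, k, axis) {
  nk <- length(k)
  if (nk == 1) return(a * k)
  r <- (nk - 1) / 2
  num <- array(0, dim(a))
  den <- array(0, dim(a))
  ones <- array(1, dim(a))
  for (i in seq_along(k)) {
    by <- i - 1 - r
    num <- num + k[i] * shift_array(a, axis, by, fill = 0)
    den <- den + k[i] * shift_array(ones, axis, by, fill = 0)
  }
  num / den
}

#' Anisotropic 3D Gaussian blur
#'
#' Separable Gaussian filtering with per-axis standard deviations in voxels,
#' border-renormalized so constant images are preserved.
#'
#' @param a 3D numeric array ordered (z, y, x).
#' @param sigma length-3 numeric, standard deviation in voxels per axis.
#' @return blurred array of the same shape.
#' @export
gaussian_blur3d <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3, length(sigma) == 3, all(sigma >= 0))
  for (axis in 1:3) {
    if (sigma[axis] > 0) a <- convolve_axis(a, gauss_kernel(sigma[axis]), axis)
  }
  a
}

# Otsu threshold: maximizes between-class variance on a binned histogram.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  bin <- pmin(levels, 1L + floor((x - rng[1]) / diff(rng) * levels))
  h <- as.numeric(tabulate(bin, levels))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(levels))
  tot <- w[levels]
  between <- (mu[levels] * w - mu * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- 0
  rng[1] + which.max(between) / levels * diff(rng)
}

# 26-connected neighbor offsets (z, y, x), excluding the center.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
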