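# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph) wherever they are used to
# check a package computation.

# Pearson r between two vectors, from first principles.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  xm <- x - mean(x); ym <- y - mean(y)
  den <- sqrt(sum(xm^2) * sum(ym^2))
  if (den == 0) return(NA_real_)
  sum(xm * ym) / den
}

# Two-sample KS statistic: sup over pooled points of the ECDF difference.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Fan-triangulation polygon area (convex polygons).
oracle_fan_area <- function(v) {
  s <- 0
  for (i in 2:(nrow(v) - 1)) {
    a <- v[i, ] - v[1, ]; b <- v[i + 1, ] - v[1, ]
    s <- s + (a[1] * b[2] - a[2] * b[1]) / 2
  }
  abs(s)
}

# Independent ray-casting point-in-polygon (horizontal ray to +x), boundary
# handled by an explicit on-segment test.
oracle_point_in_poly <- function(pt, v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- v[j, ] - v[i, ]
    len2 <- sum(d^2)
    t <- if (len2 == 0) 0 else sum((pt - v[i, ]) * d) / len2
    t <- min(max(t, 0), 1)
    if (sqrt(sum((v[i, ] + t * d - pt)^2)) < 1e-9) return(TRUE)
  }
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    yi <- v[i, 2]; yj <- v[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xint <- v[i, 1] + (pt[2] - yi) / (yj - yi) * (v[j, 1] - v[i, 1])
      if (xint > pt[1]) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# All-pairs shortest-path lengths by Floyd-Warshall on a binary adjacency
# matrix (Inf where unreachable).
oracle_fw_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Exact betweenness by shortest-path counting: BFS per source for distances
# and path multiplicities, then pair-dependency accumulation.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  dist_all <- vector("list", n)
  sig_all <- vector("list", n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- numeric(n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sig[w] <- sig[w] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist_all[[s]] <- dist; sig_all[[s]] <- sig
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || is.infinite(dist_all[[s]][t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (dist_all[[s]][v] + dist_all[[t]][v] == dist_all[[s]][t]) {
        btw[v] <- btw[v] + (sig_all[[s]][v] * sig_all[[t]][v]) / sig_all[[s]][t]
      }
    }
  }
  btw
}

# Local clustering coefficient: triangles over possible neighbor pairs.
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
}

# Newman modularity of a hard partition on a binary adjacency matrix.
oracle_modularity <- function(A, comm) {
  k <- rowSums(A)
  two_m <- sum(k)
  sum((A - outer(k, k) / two_m) * outer(comm, comm, "==")) / two_m
}

# Best bipartition modularity by exhaustive enumeration (up to ~12 nodes).
oracle_best_bipartition <- function(A) {
  n <- nrow(A)
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    comm <- as.integer(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    best <- max(best, oracle_modularity(A, comm))
  }
  best
}

# Random blobby label map pair for colocalization oracles.
random_label_maps <- function(d = c(3, 16, 16), n1 = 3, n2 = 3,
                              voxel_size = c(3, 1.08, 1.08)) {
  mk <- function(n) {
    a <- array(0L, d)
    for (k in seq_len(n)) {
      ctr <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
      r <- sample(2:4, 1)
      for (z in max(1, ctr[1] - 1):min(d[1], ctr[1] + 1))
        for (y in max(1, ctr[2] - r):min(d[2], ctr[2] + r))
          for (x in max(1, ctr[3] - r):min(d[3], ctr[3] + r))
            if (a[z, y, x] == 0L) a[z, y, x] <- k
    }
    a
  }
  list(label_map(mk(n1), voxel_size), label_map(mk(n2), voxel_size))
}

# Brute-force double-loop colocalization records.
oracle_coloc <- function(m1, m2) {
  l1 <- m1$labels; l2 <- m2$labels
  out <- NULL
  for (i in setdiff(unique(as.vector(l1)), 0L)) {
    for (j in setdiff(unique(as.vector(l2)), 0L)) {
      ov <- sum(l1 == i & l2 == j)
      if (ov > 0) {
        out <- rbind(out, data.frame(id_ch1 = i, id_ch2 = j,
                                     overlap_voxels = ov,
                                     overlap_fraction = ov / sum(l2 == j)))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(id_ch1 = integer(0), id_ch2 = integer(0),
                      overlap_voxels = integer(0),
                      overlap_fraction = numeric(0)))
  }
  out[order(out$id_ch1, out$id_ch2), , drop = FALSE]
}

# Build a correlation_matrix object directly from r/p matrices (for network
# tests that need full control of the thresholding inputs).
fake_corr <- function(r, p, n = 6, group = "G", channel = "ch1") {
  regions <- rownames(r)
  defined <- !is.na(r) & !is.na(p)
  diag(defined) <- FALSE
  structure(list(regions = regions, r = r, p = p,
                 n = matrix(n, nrow(r), ncol(r), dimnames = dimnames(r)),
                 defined = defined, group = group, channel = channel),
            class = "correlation_matrix")
}

# Adjacency matrix -> correlation_matrix whose build_network() thresholding
# at (r_min = 0.9, alpha = 0.01) reproduces exactly that graph.
corr_from_adjacency <- function(A, regions = NULL) {
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(A)))
  dimnames(A) <- list(regions, regions)
  r <- ifelse(A > 0, 0.95, 0.1)
  diag(r) <- 1
  p <- ifelse(A > 0, 1e-4, 0.9)
  diag(p) <- NA_real_
  dimnames(r) <- dimnames(p) <- dimnames(A)
  fake_corr(r, p)
}
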