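# Correlation matrices, thresholded networks, topology metrics, permutation
# tests, and community detection.

random_count_table <- function(n_regions = 8, groups = c(CT = 5L, IS = 6L),
                               seed = 1) {
  generate_count_table(count_table_spec(
    groups = groups, regions = paste0("R", seq_len(n_regions)), seed = seed))
}

test_that("correlation p-values follow the t distribution", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(round(correlation_pvalue(0.88, 6), 2), 0.02)
  expect_equal(correlation_pvalue(1, 6), 0)
  expect_equal(correlation_pvalue(-1, 6), 0)
  expect_error(correlation_pvalue(0.5, 2), ">= 3")
  set.seed(10)
  for (i in 1:200) {
    r <- runif(1, -0.999, 0.999)
    n <- sample(3:40, 1)
    tt <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
    # numerical integration of the t density as an independent oracle
    oracle <- 2 * integrate(function(u) dt(u, df = n - 2), tt, Inf,
                            rel.tol = 1e-12)$value
    expect_equal(correlation_pvalue(r, n), oracle, tolerance = 1e-8)
  }
})

test_that("correlation matrices match a per-pair brute-force loop", {
  tab <- random_count_table(n_regions = 10, seed = 13)
  # introduce missingness to exercise pairwise completion
  drop <- sample(nrow(tab), 8)
  tab$normalized[drop] <- NA
  for (g in c("CT", "IS")) {
    cm <- correlation_matrix(tab, g, "ch1")
    expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
    expect_true(all(diag(cm$r) == 1))
    sub <- tab[tab$group == g, ]
    wide <- tidyr::pivot_wider(sub[, c("mouse_id", "region", "normalized")],
                               names_from = "region",
                               values_from = "normalized")
    for (i in seq_along(cm$regions)) for (j in seq_along(cm$regions)) {
      if (i == j) next
      x <- wide[[cm$regions[i]]]; y <- wide[[cm$regions[j]]]
      want_r <- oracle_pearson(x, y)
      want_n <- sum(!is.na(x) & !is.na(y))
      expect_equal(cm$n[i, j], want_n)
      if (is.na(want_r)) {
        expect_false(cm$defined[i, j])
      } else {
        expect_equal(cm$r[i, j], want_r, tolerance = 1e-12)
      }
    }
  }
})

test_that("correlation matrices are invariant under mouse reordering", {
  tab <- random_count_table(seed = 14)
  cm1 <- correlation_matrix(tab, "IS", "ch1")
  tab2 <- tab[rev(seq_len(nrow(tab))), ]
  cm2 <- correlation_matrix(tab2, "IS", "ch1")
  expect_equal(cm1$r, cm2$r[cm1$regions, cm1$regions], tolerance = 1e-12)
})

test_that("perfect linear dependence and zero variance are flagged", {
  tab <- tibble::tibble(
    mouse_id = rep(paste0("m", 1:6), 3),
    group = "CT",
    region = rep(c("A", "B", "C"), each = 6),
    channel = "ch1", raw_count = NA_real_, volume_mm3 = NA_real_,
    normalized = c(1:6, 2 * (1:6) + 3, rep(7, 6)))
  cm <- correlation_matrix(tab, "CT", "ch1")
  expect_equal(cm$r["A", "B"], 1)
  expect_equal(cm$p["A", "B"], 0)
  expect_false(cm$defined["A", "C"])   # zero-variance region
  net <- build_network(cm, r_min = 0.9, alpha = 0.05)
  edges <- network_edges(net)
  expect_false(any(edges$from == "C" | edges$to == "C"))
})

test_that("network thresholding follows the |r| and alpha rules", {
  regions <- paste0("R", 1:5)
  r <- matrix(0.95, 5, 5, dimnames = list(regions, regions)); diag(r) <- 1
  p <- matrix(1e-4, 5, 5, dimnames = list(regions, regions))
  diag(p) <- NA
  net <- build_network(fake_corr(r, p), r_min = 0.9, alpha = 0.01)
  expect_equal(igraph::ecount(net$graph), 10)   # complete graph on 5 nodes
  # insignificant pair drops out
  p2 <- p; p2["R1", "R2"] <- p2["R2", "R1"] <- 0.5
  net2 <- build_network(fake_corr(r, p2), r_min = 0.9, alpha = 0.01)
  expect_equal(igraph::ecount(net2$graph), 9)
  # anticorrelated edge survives with a negative sign flag
  r3 <- r; r3["R1", "R2"] <- r3["R2", "R1"] <- -0.95
  net3 <- build_network(fake_corr(r3, p), r_min = 0.9, alpha = 0.01)
  e <- network_edges(net3)
  neg <- e[(e$from == "R1" & e$to == "R2") | (e$from == "R2" & e$to == "R1"), ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$sign, -1L)
  # every edge re-tests against the thresholds (round trip)
  for (i in seq_len(nrow(e))) {
    expect_gt(abs(r3[e$from[i], e$to[i]]), 0.9)
    expect_lt(p[e$from[i], e$to[i]], 0.01)
  }
})

test_that("topology metrics match closed forms on canonical graphs", {
  A <- matrix(1, 3, 3); diag(A) <- 0
  net <- build_network(corr_from_adjacency(A), 0.9, 0.01)
  m <- node_metrics(net)
  expect_equal(m$nodes$degree, rep(2L, 3))
  expect_equal(m$nodes$clustering, rep(1, 3))
  expect_equal(m$nodes$betweenness, rep(0, 3))
  expect_equal(m$nodes$efficiency, rep(1, 3))
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  mp <- node_metrics(build_network(corr_from_adjacency(path), 0.9, 0.01))
  expect_equal(mp$nodes$betweenness, c(0, 1, 0))
  expect_equal(mp$nodes$efficiency, c((1 + 0.5) / 2, 1, (1 + 0.5) / 2))
})

test_that("all four metrics match brute-force oracles on random graphs", {
  set.seed(15)
  for (i in 1:5) {
    n <- 30
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.12)
    A <- A + t(A)
    m <- node_metrics(build_network(corr_from_adjacency(A), 0.9, 0.01))
    expect_equal(m$nodes$degree, as.integer(rowSums(A)))
    expect_equal(m$nodes$clustering, oracle_clustering(A), tolerance = 1e-12)
    D <- oracle_fw_distances(A)
    inv <- 1 / D; diag(inv) <- 0; inv[is.infinite(D)] <- 0
    expect_equal(m$nodes$efficiency, rowSums(inv) / (n - 1),
                 tolerance = 1e-12)
    expect_equal(m$nodes$betweenness, oracle_betweenness(A),
                 tolerance = 1e-9)
    expect_equal(sum(m$nodes$degree), 2 * m$network$n_edges)
    # relabeling invariance of the means
    perm <- sample(n)
    mperm <- node_metrics(build_network(
      corr_from_adjacency(A[perm, perm]), 0.9, 0.01))
    expect_equal(mperm$network, m$network, tolerance = 1e-12)
  }
})

test_that("threshold sweeps are monotone and reduce to single calls", {
  tab <- random_count_table(n_regions = 8, seed = 16)
  ca <- correlation_matrix(tab, "CT", "ch1")
  cb <- correlation_matrix(tab, "IS", "ch1")
  sw <- threshold_sweep(ca, cb, alphas = c(0.001, 0.01, 0.05, 0.5, 1),
                        r_min = 0.3)
  for (g in c("CT", "IS")) {
    expect_true(all(diff(sw$n_edges[sw$group == g]) >= 0))
  }
  # singleton alpha equals the direct build + metrics composition
  one <- threshold_sweep(ca, cb, alphas = 0.05, r_min = 0.3)
  direct <- node_metrics(build_network(ca, r_min = 0.3, alpha = 0.05))$network
  expect_equal(one[one$group == "CT", names(direct)], direct)
  # alpha = 1, r_min = 0 keeps every defined pair
  full <- threshold_sweep(ca, cb, alphas = 1, r_min = 0)
  expect_equal(full$n_edges[full$group == "CT"],
               sum(ca$defined[upper.tri(ca$defined)] & abs(ca$r[upper.tri(ca$r)]) > 0))
})

test_that("KS comparison of correlation distributions matches the ECDF oracle", {
  tab <- random_count_table(n_regions = 9, seed = 17)
  ca <- correlation_matrix(tab, "CT", "ch1")
  cb <- correlation_matrix(tab, "IS", "ch1")
  same <- compare_correlation_distributions(ca, ca, "R1")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  got <- compare_correlation_distributions(ca, cb, "R3")
  i <- match("R3", ca$regions)
  a <- ca$r[i, ca$defined[i, ]]
  b <- cb$r[i, cb$defined[i, ]]
  expect_equal(got$statistic, oracle_ks_d(a, b), tolerance = 1e-12)
  # disjoint supports give D = 1
  regions <- paste0("R", 1:5)
  rlo <- matrix(seq(-0.4, 0, length.out = 25), 5, 5,
                dimnames = list(regions, regions))
  rlo <- (rlo + t(rlo)) / 2
  rhi <- rlo + 0.8
  diag(rlo) <- diag(rhi) <- 1
  pmat <- matrix(0.5, 5, 5, dimnames = list(regions, regions))
  d <- compare_correlation_distributions(fake_corr(rlo, pmat),
                                         fake_corr(rhi, pmat), "R1")
  expect_equal(d$statistic, 1)
})

test_that("identical groups give zero differences and p = 1", {
  base <- random_count_table(groups = c(A = 4L, B = 4L), n_regions = 5,
                             seed = 18)
  a <- base[base$group == "A", ]
  b <- a
  b$group <- "B"
  b$mouse_id <- sub("^A", "B", a$mouse_id)
  res <- permute_correlation_differences(rbind(a, b), "A", "B", "ch1",
                                         n_perm = 200, seed = 1)
  expect_true(all(abs(res$diff) < 1e-12))
  expect_true(all(res$p_value == 1))
})

test_that("3v3 Monte-Carlo permutation agrees with exhaustive enumeration", {
  tab <- random_count_table(groups = c(A = 3L, B = 3L), n_regions = 4,
                            seed = 19)
  ex <- permute_correlation_differences(tab, "A", "B", "ch1",
                                        method = "exhaustive")
  expect_true(all(ex$n_valid == choose(6, 3)))
  expect_true(all(ex$p_value >= 1 / 20 & ex$p_value <= 1))
  # independent enumeration oracle over the 20 assignments
  wide <- tidyr::pivot_wider(tab[, c("mouse_id", "group", "region",
                                     "normalized")],
                             names_from = "region",
                             values_from = "normalized")
  wide <- wide[order(wide$group != "A"), ]
  m <- as.matrix(wide[, -(1:2)])
  for (k in seq_len(nrow(ex))) {
    x <- m[, ex$region_a[k]]; y <- m[, ex$region_b[k]]
    obs <- oracle_pearson(x[4:6], y[4:6]) - oracle_pearson(x[1:3], y[1:3])
    cnt <- 0
    for (s in asplit(combn(6, 3), 2)) {
      d <- oracle_pearson(x[-s], y[-s]) - oracle_pearson(x[s], y[s])
      if (abs(d) >= abs(obs) - 1e-12) cnt <- cnt + 1
    }
    expect_equal(ex$p_value[k], cnt / 20)
    expect_equal(ex$diff[k], obs, tolerance = 1e-12)
  }
  # auto switches to exhaustive at this size, and MC converges to it
  auto <- permute_correlation_differences(tab, "A", "B", "ch1",
                                          n_perm = 1000, seed = 3)
  expect_identical(auto$method[1], "exhaustive")
  mc <- permute_correlation_differences(tab, "A", "B", "ch1", n_perm = 1000,
                                        seed = 4, method = "monte_carlo")
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 1000)
  expect_true(all(abs(mc$p_value - ex$p_value) <= 3 * se + 2 / 1001))
  # determinism in the seed
  mc2 <- permute_correlation_differences(tab, "A", "B", "ch1", n_perm = 1000,
                                         seed = 4, method = "monte_carlo")
  expect_identical(mc, mc2)
  expect_error(permute_correlation_differences(tab, "A", "B", "ch1",
                                               n_perm = 0), "n_perm")
})

test_that("significant-difference filtering applies both thresholds", {
  res <- tibble::tibble(
    region_a = c("A", "A", "B", "C"), region_b = c("B", "C", "C", "D"),
    r_a = 0, r_b = 0,
    diff = c(1.2, 0.4, -1.5, 1.1),
    p_value = c(0.005, 0.001, 0.009, 0.2),
    n_valid = 924, method = "exhaustive")
  keep <- significant_differences(res)
  expect_setequal(paste(keep$region_a, keep$region_b), c("A B", "B C"))
  set.seed(20)
  rnd <- tibble::tibble(region_a = "X", region_b = paste0("Y", 1:50),
                        r_a = 0, r_b = 0, diff = runif(50, -2, 2),
                        p_value = runif(50), n_valid = 924,
                        method = "exhaustive")
  got <- significant_differences(rnd, alpha = 0.05, min_abs_diff = 0.8)
  want <- rnd[abs(rnd$diff) >= 0.8 & rnd$p_value < 0.05, ]
  expect_equal(got, want)
})

test_that("type-I error of the permutation test is calibrated under the null", {
  set.seed(21)
  fr <- numeric(50)
  for (i in 1:50) {
    tab <- random_count_table(n_regions = 8, groups = c(CT = 5L, IS = 6L),
                              seed = 3000 + i)
    res <- permute_correlation_differences(tab, "CT", "IS", "ch1",
                                           n_perm = 1000, seed = i)
    fr[i] <- mean(res$p_value < 0.05)
  }
  expect_lt(abs(mean(fr) - 0.05), 0.02)
})

test_that("leading-eigenvector split recovers planted communities", {
  # two 4-cliques joined by one edge: split exactly by clique, modularity
  # equal to the exhaustive-maximum bipartition
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  net <- build_network(corr_from_adjacency(A), 0.9, 0.01)
  cm <- detect_communities(net)
  expect_equal(cm$nodes$community[1:4], rep(cm$nodes$community[1], 4))
  expect_equal(cm$nodes$community[5:8], rep(cm$nodes$community[5], 4))
  expect_false(cm$nodes$community[1] == cm$nodes$community[5])
  expect_equal(cm$modularity, oracle_best_bipartition(A), tolerance = 1e-9)
  expect_gte(cm$modularity, 0)   # never worse than the trivial community
  # complete graph: no positive eigenvalue, single community
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  ck <- detect_communities(build_network(corr_from_adjacency(K5), 0.9, 0.01))
  expect_equal(unique(ck$nodes$community), 1L)
  # two disconnected triangles split by component
  Tt <- matrix(0, 6, 6)
  Tt[1:3, 1:3] <- 1; Tt[4:6, 4:6] <- 1; diag(Tt) <- 0
  ct <- detect_communities(build_network(corr_from_adjacency(Tt), 0.9, 0.01))
  expect_equal(length(unique(ct$nodes$community[1:3])), 1)
  expect_equal(length(unique(ct$nodes$community[4:6])), 1)
  expect_false(ct$nodes$community[1] == ct$nodes$community[4])
  expect_equal(ct$modularity, oracle_best_bipartition(Tt), tolerance = 1e-9)
  # edgeless graph errors
  E0 <- matrix(0, 4, 4)
  expect_error(detect_communities(build_network(corr_from_adjacency(E0),
                                                0.9, 0.01)), "edge")
})
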