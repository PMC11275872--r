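# Import, exclusion, aggregation, outlier cleaning, proportions and group
# comparisons.

# build a slice whose objects already carry region/hemisphere assignments
slice_with_objects <- function(slice_id, assignments) {
  sl <- slice_record(slice_id, channels = unique(assignments$channel))
  for (ch in unique(assignments$channel)) {
    sub <- assignments[assignments$channel == ch, ]
    sl$objects[[ch]] <- tibble::tibble(
      object_id = seq_len(nrow(sub)),
      centroid_z_um = 0, centroid_y_um = 0, centroid_x_um = 0,
      voxel_count = 1L, volume_um3 = 3.5, mean_intensity = 1,
      region = sub$region, hemisphere = sub$hemisphere)
  }
  sl
}

mouse_fixture <- function() {
  m <- mouse_record("m1", group = "CT")
  a1 <- data.frame(channel = c(rep("ch1", 4), rep("ch2", 3)),
                   region = c("dDG", "dDG", "AI", "cc", "dDG", "AI", "AI"),
                   hemisphere = c("left", "right", "left", "left",
                                  "left", "left", "right"))
  a2 <- data.frame(channel = rep("ch1", 5),
                   region = c("dDG", "dDG", "dDG", "AI", "VL"),
                   hemisphere = c("left", "left", "right", "right", "left"))
  m <- add_slice(m, slice_with_objects("s1", a1))
  add_slice(m, slice_with_objects("s2", a2))
}

volumes <- data.frame(region = c("dDG", "AI"), volume_mm3 = c(0.009, 0.004))

test_that("import validates the TSV contract strictly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("object_id", "centroid_z_um", "centroid_y_um",
                 "centroid_x_um", "voxel_count", "volume_um3",
                 "mean_intensity"), collapse = "\t")
  writeLines(hdr, path)
  sl <- import_segmentation(slice_record("s", channels = "ch1"),
                            c(ch1 = path))
  expect_equal(nrow(sl$objects$ch1), 0)
  writeLines(c(hdr, "1\t3\t4\t5\t10\t35\t99", "2\t6\t7\t8\t12\t42\t88"), path)
  sl <- import_segmentation(slice_record("s", channels = "ch1"),
                            c(ch1 = path))
  expect_equal(sl$objects$ch1$volume_um3, c(35, 42))
  # missing column named in the error
  writeLines(c("object_id\tvoxel_count", "1\t10"), path)
  expect_error(import_segmentation(slice_record("s", channels = "ch1"),
                                   c(ch1 = path)), "centroid_z_um")
  # non-numeric cell cited by row
  writeLines(c(hdr, "1\t3\t4\t5\t10\tbroken\t99"), path)
  expect_error(import_segmentation(slice_record("s", channels = "ch1"),
                                   c(ch1 = path)), "row 1")
})

test_that("aggregation counts per region and channel and normalizes by volume", {
  tab <- aggregate_and_normalize(mouse_fixture(), volumes)
  # dDG ch1: 2 (slice1) + 3 (slice2); cc and VL always dropped
  expect_equal(tab$raw_count[tab$region == "dDG" & tab$channel == "ch1"], 5)
  expect_equal(tab$normalized[tab$region == "dDG" & tab$channel == "ch1"],
               5 / 0.009)
  expect_equal(tab$raw_count[tab$region == "AI" & tab$channel == "ch2"], 2)
  expect_false(any(tab$region %in% c("cc", "VL")))
  # split-across-slices equals the flat per-(region, channel) tally
  m <- mouse_fixture()
  flat <- do.call(rbind, lapply(m$slices, function(sl) {
    do.call(rbind, lapply(names(sl$objects), function(ch) {
      o <- sl$objects[[ch]]
      if (is.null(o)) return(NULL)
      data.frame(region = o$region, channel = ch)
    }))
  }))
  flat <- flat[!flat$region %in% noncellular_acronyms(), ]
  want <- as.data.frame(table(flat$region, flat$channel),
                        stringsAsFactors = FALSE)
  want <- want[want$Freq > 0, ]
  for (i in seq_len(nrow(want))) {
    expect_equal(tab$raw_count[tab$region == want$Var1[i] &
                                 tab$channel == want$Var2[i]], want$Freq[i])
  }
})

test_that("a counted region without positive volume is an error", {
  expect_error(aggregate_and_normalize(mouse_fixture(),
                                       data.frame(region = "dDG",
                                                  volume_mm3 = 0.009)),
               "AI")
})

test_that("hemisphere exclusions are honored before pooling", {
  m <- mouse_fixture()
  m <- exclude_anatomy(m, "dDG", hemisphere = "left")
  tab <- aggregate_and_normalize(m, volumes)
  # dDG left contributes 2 (s1) + 2 (s2) ch1 cells; right ones remain
  expect_equal(tab$raw_count[tab$region == "dDG" & tab$channel == "ch1"], 2)
  expect_false("dDG" %in% tab$region[tab$channel == "ch2"])
  m2 <- exclude_anatomy(mouse_fixture(), "AI")  # both hemispheres
  tab2 <- aggregate_and_normalize(m2, volumes)
  expect_false("AI" %in% tab2$region)
  expect_warning(exclude_anatomy(mouse_fixture(), "dgg", known = c("dDG")),
                 "dgg")
})

test_that("outlier cleaning applies the single-pass two-SD rule", {
  base <- tibble::tibble(
    mouse_id = paste0("m", 1:10), group = "CT", region = "dDG",
    channel = "ch1", raw_count = NA_real_, volume_mm3 = NA_real_,
    normalized = c(rep(1, 9), 100))
  res <- clean_outliers(base, k = 2)
  expect_equal(res$dropped$normalized, 100)
  expect_equal(nrow(res$table), 9)
  # hand check: mean 10.9, sample SD ~= 31.31, |100 - 10.9| > 2 SD
  expect_gt(abs(100 - mean(base$normalized)), 2 * sd(base$normalized))
  same <- base
  same$normalized <- rep(5, 10)
  expect_equal(nrow(clean_outliers(same)$dropped), 0)
  # a value exactly at k SD is retained: the rule is strict inequality
  x <- c(1, 1, 1, 1, 1, 2)
  exact <- base[1:6, ]
  exact$normalized <- x
  k_boundary <- abs(2 - mean(x)) / sd(x)
  expect_equal(nrow(clean_outliers(exact, k = k_boundary * (1 + 1e-12))$dropped),
               0)
  expect_equal(clean_outliers(exact, k = k_boundary - 1e-9)$dropped$normalized,
               2)
})

test_that("only regions present in both groups survive the filter", {
  tab <- tibble::tibble(
    mouse_id = c("a1", "a2", "b1", "b2", "a1", "b1"),
    group = c("CT", "CT", "IS", "IS", "CT", "IS"),
    region = c("AI", "AI", "AI", "AI", "dDG", "RSP"),
    channel = "ch1", raw_count = 1, volume_mm3 = 1, normalized = 1)
  got <- both_groups_filter(tab)
  expect_setequal(unique(got$region), "AI")
  # random presence patterns match the set-intersection oracle per channel
  set.seed(8)
  for (i in 1:5) {
    n <- 40
    tab <- tibble::tibble(
      mouse_id = sample(paste0("m", 1:6), n, TRUE),
      group = sample(c("CT", "IS"), n, TRUE),
      region = sample(c("A", "B", "C", "D"), n, TRUE),
      channel = sample(c("ch1", "ch2"), n, TRUE),
      raw_count = 1, volume_mm3 = 1, normalized = 1)
    tab <- tab[!duplicated(tab[, c("mouse_id", "region", "channel")]), ]
    got <- both_groups_filter(tab)
    for (ch in c("ch1", "ch2")) {
      want <- intersect(
        unique(tab$region[tab$group == "CT" & tab$channel == ch]),
        unique(tab$region[tab$group == "IS" & tab$channel == ch]))
      expect_setequal(unique(got$region[got$channel == ch]), want)
    }
  }
})

test_that("reactivation proportions divide co-labeled by denominator counts", {
  mk <- function(mouse, region, ch, raw) {
    tibble::tibble(mouse_id = mouse, group = "CT", region = region,
                   channel = ch, raw_count = raw, volume_mm3 = 0.01,
                   normalized = raw / 0.01)
  }
  tab <- rbind(mk("m1", "AI", "ch1", 50), mk("m1", "AI", "colabel", 0),
               mk("m1", "dDG", "ch1", 30), mk("m1", "dDG", "colabel", 30),
               mk("m2", "AI", "ch1", 0), mk("m2", "AI", "colabel", 0),
               mk("m2", "dDG", "ch1", 40), mk("m2", "dDG", "colabel", 10))
  expect_message(pr <- reactivation_proportions(tab, "ch1"), "skipped")
  expect_equal(unique(pr$channel), "colabel_over_ch1")
  expect_equal(pr$normalized[pr$mouse_id == "m1" & pr$region == "AI"], 0)
  expect_equal(pr$normalized[pr$mouse_id == "m1" & pr$region == "dDG"], 1)
  expect_equal(pr$normalized[pr$mouse_id == "m2" & pr$region == "dDG"], 0.25)
  expect_false(any(pr$mouse_id == "m2" & pr$region == "AI"))
  expect_true(all(pr$normalized >= 0 & pr$normalized <= 1))
  bad <- rbind(mk("m1", "AI", "ch1", 5), mk("m1", "AI", "colabel", 6))
  expect_error(reactivation_proportions(bad, "ch1"), "subset")
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  got <- p_adjust_holm_sidak(p)
  # direct application of 1 - (1 - p_(i))^(m - i + 1) with cummax
  want <- cummax(1 - (1 - p)^(4:1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= p))
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(1:8, 1))
    adj <- p_adjust_holm_sidak(p)
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))   # monotone in rank order
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
  expect_equal(p_adjust_holm_sidak(0.07), 0.07)  # m = 1: adjusted = raw
})

test_that("group comparison computes per-region t-tests with correction", {
  mk <- function(mouse, group, region, v) {
    tibble::tibble(mouse_id = mouse, group = group, region = region,
                   channel = "ch1", raw_count = NA_real_,
                   volume_mm3 = NA_real_, normalized = v)
  }
  tab <- rbind(
    mk(paste0("c", 1:4), "CT", "AI", c(10, 12, 9, 11)),
    mk(paste0("i", 1:4), "IS", "AI", c(10, 12, 9, 11)),
    mk(paste0("c", 1:4), "CT", "dDG", c(10, 11, 10, 11)),
    mk(paste0("i", 1:4), "IS", "dDG", c(30, 33, 29, 31)))
  res <- compare_groups(tab, "ch1", correction = "holm_sidak")
  ai <- res[res$region == "AI", ]
  expect_equal(ai$t, 0, tolerance = 1e-12)
  expect_equal(ai$p_raw, 1, tolerance = 1e-12)
  # cross-check the dDG row against a direct pooled t-test
  tt <- t.test(c(30, 33, 29, 31), c(10, 11, 10, 11), var.equal = TRUE)
  expect_equal(res$p_raw[res$region == "dDG"], tt$p.value)
  expect_equal(res$p_adj, p_adjust_holm_sidak(res$p_raw), tolerance = 1e-12)
  # single region: adjusted equals raw under both corrections
  one <- rbind(mk(paste0("c", 1:4), "CT", "AI", c(1, 2, 3, 4)),
               mk(paste0("i", 1:4), "IS", "AI", c(2, 3, 4, 6)))
  for (corr in c("holm_sidak", "bh_fdr")) {
    r1 <- compare_groups(one, "ch1", correction = corr)
    expect_equal(r1$p_adj, r1$p_raw)
  }
  # under-filled regions are skipped with a message
  sparse <- rbind(mk("c1", "CT", "RSP", 1),
                  mk(paste0("i", 1:3), "IS", "RSP", c(1, 2, 3)))
  expect_message(res2 <- compare_groups(rbind(tab, sparse), "ch1"), "RSP")
  expect_false("RSP" %in% res2$region)
})
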