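# Aggregation to region count tables, normalization to cells/mm^3, outlier
# cleaning, reactivation proportions, and group comparisons with
# multiplicity control.

#' Structure acronyms never counted
#'
#' Fiber tracts and ventricular spaces are not expected to contain
#' IEG-labeled somata, so counts landing there are always dropped during
#' aggregation.
#'
#' @return character vector of acronyms.
#' @export
noncellular_acronyms <- function() {
  c("fiber tracts", "cc", "fxs", "fx", "int", "arb", "scwm", "cing", "alv",
    "fi", "opt", "och", "st", "mtt", "ml", "cpd", "py",
    "VL", "V3", "V4", "AQ", "SEZ", "chpl", "VS")
}

#' Construct/validate a region count table
#'
#' The long-format quantification product: one row per
#' (mouse, region, channel) with raw counts, region volume and
#' volume-normalized counts.
#'
#' @param df data frame with columns mouse_id, group, region, channel,
#'   raw_count, volume_mm3, normalized.
#' @return a tibble with those columns, validated.
#' @export
region_count_table <- function(df) {
  need <- c("mouse_id", "group", "region", "channel", "raw_count",
            "volume_mm3", "normalized")
  missing <- setdiff(need, names(df))
  abort_if(length(missing) > 0,
           paste("region count table is missing columns:",
                 paste(missing, collapse = ", ")))
  out <- tibble::as_tibble(df)[, need]
  bad <- !is.na(out$volume_mm3) & out$volume_mm3 > 0 & !is.na(out$raw_count) &
    !is.na(out$normalized) &
    abs(out$normalized - out$raw_count / out$volume_mm3) >
      1e-6 * pmax(1, abs(out$normalized))
  abort_if(any(bad), "normalized must equal raw_count / volume_mm3")
  out
}

#' Aggregate a mouse's cells to a normalized region count table
#'
#' Counts imported objects per (region, channel) over all slices of the
#' mouse, honoring per-slice hemisphere exclusions, always dropping fiber
#' tracts and ventricles, and normalizes by the supplied region volumes to
#' cells/mm^3.
#'
#' @param mouse a [mouse_record()] whose slices carry region-assigned
#'   objects (see [assign_slice_regions()], or tables with a `region`
#'   column).
#' @param region_volumes data frame with columns region, volume_mm3 (> 0 for
#'   every counted region), e.g. built with [region_volume()].
#' @param drop_acronyms structure acronyms dropped unconditionally; default
#'   [noncellular_acronyms()].
#' @return a [region_count_table()] tibble.
#' @export
aggregate_and_normalize <- function(mouse, region_volumes,
                                    drop_acronyms = noncellular_acronyms()) {
  stopifnot(inherits(mouse, "mouse_record"))
  abort_if(!all(c("region", "volume_mm3") %in% names(region_volumes)),
           "`region_volumes` needs columns region, volume_mm3")
  rows <- list()
  for (slice in mouse$slices) {
    for (ch in slice$channels) {
      obj <- slice$objects[[ch]]
      if (is.null(obj) || nrow(obj) == 0) next
      abort_if(!("region" %in% names(obj)),
               sprintf("objects of slice '%s' channel '%s' have no region column; run assign_slice_regions() first",
                       slice$slice_id, ch))
      hemi <- if ("hemisphere" %in% names(obj)) obj$hemisphere
              else rep("both", nrow(obj))
      keep <- !is.na(obj$region) & !(obj$region %in% drop_acronyms) &
        !is_excluded(obj$region, hemi, slice$exclusions)
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- tibble::tibble(region = obj$region[keep],
                                                 channel = ch)
    }
  }
  if (length(rows) == 0) {
    return(region_count_table(tibble::tibble(
      mouse_id = character(0), group = character(0), region = character(0),
      channel = character(0), raw_count = numeric(0),
      volume_mm3 = numeric(0), normalized = numeric(0))))
  }
  counts <- dplyr::count(dplyr::bind_rows(rows), .data$region, .data$channel,
                         name = "raw_count")
  counts <- dplyr::left_join(counts, tibble::as_tibble(region_volumes),
                             by = "region")
  nov <- is.na(counts$volume_mm3) | counts$volume_mm3 <= 0
  abort_if(any(nov),
           paste("regions with counts but no positive volume:",
                 paste(unique(counts$region[nov]), collapse = ", ")))
  region_count_table(tibble::tibble(
    mouse_id = mouse$mouse_id, group = mouse$group,
    region = counts$region, channel = counts$channel,
    raw_count = as.numeric(counts$raw_count),
    volume_mm3 = counts$volume_mm3,
    normalized = counts$raw_count / counts$volume_mm3))
}

#' Remove outlier counts by the k-standard-deviation rule
#'
#' Within each (group, region, channel) cell, rows whose normalized value
#' lies strictly more than `k` sample standard deviations from the cell mean
#' are dropped. A single pass is applied: the mean and SD include the
#' candidate outlier, and values exactly at the boundary are retained.
#'
#' @param table a [region_count_table()] tibble.
#' @param k SD multiplier; default 2.
#' @return list with `table` (surviving rows) and `dropped` (audit of
#'   removed rows).
#' @export
clean_outliers <- function(table, k = 2) {
  abort_if(!(k > 0), "`k` must be positive")
  tab <- tibble::as_tibble(table)
  grp <- dplyr::group_by(tab, .data$group, .data$region, .data$channel)
  flagged <- dplyr::mutate(
    grp,
    .n = dplyr::n(),
    .mu = mean(.data$normalized),
    .sd = stats::sd(.data$normalized),
    .out = .data$.n >= 3 & !is.na(.data$.sd) & .data$.sd > 0 &
      abs(.data$normalized - .data$.mu) > k * .data$.sd)
  flagged <- dplyr::ungroup(flagged)
  keep <- !flagged$.out
  drop_cols <- c(".n", ".mu", ".sd", ".out")
  list(table = tab[keep, , drop = FALSE],
       dropped = tab[!keep, , drop = FALSE],
       audit = flagged[!keep, setdiff(names(flagged), ".out")])
}

#' Keep only regions represented in both groups
#'
#' For each channel, a region must have at least one surviving mouse in each
#' of the two groups to be analyzed; other rows are removed.
#'
#' @param table a [region_count_table()] tibble with exactly two groups.
#' @return the filtered tibble.
#' @export
both_groups_filter <- function(table) {
  tab <- tibble::as_tibble(table)
  groups <- unique(tab$group)
  abort_if(length(groups) != 2, "exactly two groups are required")
  pres <- dplyr::distinct(tab, .data$group, .data$region, .data$channel)
  both <- dplyr::count(pres, .data$region, .data$channel)
  both <- both[both$n == 2, c("region", "channel")]
  dplyr::semi_join(tab, both, by = c("region", "channel"))
}

#' Reactivation proportions of co-labeled cells
#'
#' Divides per-(mouse, region) co-labeled raw counts by the chosen
#' denominator channel's raw counts, emitting rows on channel
#' `colabel_over_ch1` or `colabel_over_ch2` with the proportion stored in
#' `normalized`. Co-labeled cells are a subset of either single channel, so
#' a co-labeled count exceeding its denominator is an error; zero
#' denominators are skipped with a message.
#'
#' @param table a [region_count_table()] tibble containing `colabel` and the
#'   denominator channel.
#' @param denominator "ch1" or "ch2".
#' @return tibble of proportion rows (same columns as the input table).
#' @export
reactivation_proportions <- function(table, denominator = c("ch1", "ch2")) {
  denominator <- match.arg(denominator)
  tab <- tibble::as_tibble(table)
  co <- tab[tab$channel == "colabel", ]
  de <- tab[tab$channel == denominator, ]
  merged <- dplyr::inner_join(
    co, de[, c("mouse_id", "region", "raw_count")],
    by = c("mouse_id", "region"), suffix = c("", ".den"))
  abort_if(any(merged$raw_count > merged$raw_count.den, na.rm = TRUE),
           "co-labeled counts exceed the denominator channel counts; co-labeled cells must be a subset")
  zero <- !is.na(merged$raw_count.den) & merged$raw_count.den == 0
  if (any(zero)) {
    message(sum(zero), " (mouse, region) pair(s) skipped: zero ",
            denominator, " count")
    merged <- merged[!zero, , drop = FALSE]
  }
  tibble::tibble(
    mouse_id = merged$mouse_id, group = merged$group, region = merged$region,
    channel = paste0("colabel_over_", denominator),
    raw_count = merged$raw_count, volume_mm3 = NA_real_,
    normalized = merged$raw_count / merged$raw_count.den)
}

#' Step-down Holm-Sidak adjusted p-values
#'
#' Orders the raw p-values ascending, sets
#' `p_adj_(i) = 1 - (1 - p_(i))^(m - i + 1)` and enforces monotone
#' nondecreasing adjusted values in rank order.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare group means per region
#'
#' Two-sided two-sample Student t-tests (equal variance by default) on the
#' normalized values of one channel, region by region, with familywise
#' (Holm-Sidak) or false-discovery-rate (Benjamini-Hochberg) correction
#' across regions. Regions with fewer than two mice in either group are
#' skipped with a message.
#'
#' @param table a [region_count_table()] tibble with two groups.
#' @param channel channel to test.
#' @param correction "holm_sidak" (default), "bh_fdr" or "none".
#' @param var_equal use the pooled-variance t-test (default TRUE); FALSE
#'   gives Welch.
#' @return tibble with one row per tested region: group means, the
#'   difference, t, df, p_raw and p_adj, sorted by p_adj.
#' @export
compare_groups <- function(table, channel,
                           correction = c("holm_sidak", "bh_fdr", "none"),
                           var_equal = TRUE) {
  correction <- match.arg(correction)
  tab <- tibble::as_tibble(table)
  tab <- tab[tab$channel == channel & !is.na(tab$normalized), ]
  groups <- sort(unique(tab$group))
  abort_if(length(groups) != 2, "exactly two groups are required")
  res <- list()
  skipped <- character(0)
  for (reg in unique(tab$region)) {
    a <- tab$normalized[tab$region == reg & tab$group == groups[1]]
    b <- tab$normalized[tab$region == reg & tab$group == groups[2]]
    if (length(a) < 2 || length(b) < 2) {
      skipped <- c(skipped, reg)
      next
    }
    tt <- stats::t.test(b, a, var.equal = var_equal)
    res[[reg]] <- tibble::tibble(
      region = reg, n_1 = length(a), n_2 = length(b),
      mean_1 = mean(a), mean_2 = mean(b), diff = mean(b) - mean(a),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value)
  }
  if (length(skipped) > 0)
    message("skipped (fewer than 2 mice per group): ",
            paste(skipped, collapse = ", "))
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(out)
  out$p_adj <- switch(correction,
                      holm_sidak = p_adjust_holm_sidak(out$p_raw),
                      bh_fdr = stats::p.adjust(out$p_raw, method = "BH"),
                      none = out$p_raw)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  names(out)[names(out) == "n_1"] <- paste0("n_", groups[1])
  names(out)[names(out) == "n_2"] <- paste0("n_", groups[2])
  dplyr::arrange(out, .data$p_adj, .data$p_raw)
}
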