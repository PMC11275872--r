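# Label-shuffle permutation test on between-group correlation differences.

# All group-label assignments for exhaustive enumeration: which mice carry
# the group-A label. Returns a list of index vectors.
all_label_assignments <- function(n_total, n_a) {
  asplit(utils::combn(n_total, n_a), 2)
}

#' Permutation test of correlation differences between groups
#'
#' For every region pair, the observed statistic is the correlation in group
#' B minus the correlation in group A. The null is built by reshuffling the
#' mouse group labels (preserving group sizes) and recomputing the
#' difference each shuffle; the two-sided Monte-Carlo p-value is
#' `(#\{|null| >= |observed|\} + 1) / (valid shuffles + 1)`. Shuffles where a
#' pair's correlation is undefined on either side are skipped for that pair
#' but still count as drawn. With `method = "exhaustive"` (or `"auto"` when
#' the number of distinct assignments does not exceed `n_perm`), every
#' label assignment is enumerated once and the p-value is the exact fraction
#' `#\{|null| >= |observed|\} / assignments`, the identity assignment
#' included.
#'
#' @param table a [region_count_table()]-style tibble.
#' @param group_a,group_b group labels; the statistic is r_B - r_A.
#' @param channel channel to analyze.
#' @param n_perm number of Monte-Carlo shuffles; default 1000.
#' @param seed integer seed driving the shuffles.
#' @param method "auto" (default), "monte_carlo" or "exhaustive".
#' @param value column holding the analyzed value.
#' @return tibble with one row per defined region pair: region_a, region_b,
#'   r_a, r_b, diff, p_value, n_valid, method.
#' @export
permute_correlation_differences <- function(table, group_a, group_b, channel,
                                            n_perm = 1000, seed = 1L,
                                            method = c("auto", "monte_carlo",
                                                       "exhaustive"),
                                            value = "normalized") {
  method <- match.arg(method)
  abort_if(!is_count(n_perm) || n_perm < 1, "`n_perm` must be >= 1")
  tab <- tibble::as_tibble(table)
  tab <- tab[tab$channel == channel & tab$group %in% c(group_a, group_b), ]
  wide <- tidyr::pivot_wider(tab[, c("mouse_id", "group", "region", value)],
                             names_from = "region", values_from = dplyr::all_of(value))
  groups <- wide$group
  m <- as.matrix(wide[, setdiff(names(wide), c("mouse_id", "group")),
                      drop = FALSE])
  n_a <- sum(groups == group_a)
  n_b <- sum(groups == group_b)
  abort_if(n_a < 3 || n_b < 3, "both groups need at least 3 mice")
  # mice ordered group A first so assignments are index sets
  ord <- order(groups != group_a)
  m <- m[ord, , drop = FALSE]
  n_tot <- n_a + n_b

  pair_diff <- function(idx_a) {
    ra <- suppressWarnings(stats::cor(m[idx_a, , drop = FALSE],
                                      use = "pairwise.complete.obs"))
    rb <- suppressWarnings(stats::cor(m[-idx_a, , drop = FALSE],
                                      use = "pairwise.complete.obs"))
    list(diff = rb - ra, ra = ra, rb = rb)
  }
  obs <- pair_diff(seq_len(n_a))
  ut <- which(upper.tri(obs$diff), arr.ind = TRUE)
  obs_d <- obs$diff[upper.tri(obs$diff)]

  n_assign <- choose(n_tot, n_a)
  if (method == "auto")
    method <- if (n_assign <= n_perm) "exhaustive" else "monte_carlo"

  exceed <- numeric(length(obs_d))
  valid <- numeric(length(obs_d))
  if (method == "exhaustive") {
    for (idx_a in all_label_assignments(n_tot, n_a)) {
      nd <- pair_diff(idx_a)$diff[upper.tri(obs$diff)]
      ok <- !is.na(nd)
      valid <- valid + ok
      exceed <- exceed + (ok & abs(nd) >= abs(obs_d) - 1e-12)
    }
    p <- ifelse(valid > 0, exceed / valid, NA_real_)
  } else {
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        idx_a <- sample.int(n_tot, n_a)
        nd <- pair_diff(idx_a)$diff[upper.tri(obs$diff)]
        ok <- !is.na(nd)
        valid <- valid + ok
        exceed <- exceed + (ok & abs(nd) >= abs(obs_d) - 1e-12)
      }
    })
    p <- (exceed + 1) / (valid + 1)
  }

  regions <- colnames(obs$diff)
  out <- tibble::tibble(
    region_a = regions[ut[, 1]], region_b = regions[ut[, 2]],
    r_a = obs$ra[upper.tri(obs$ra)], r_b = obs$rb[upper.tri(obs$rb)],
    diff = obs_d, p_value = p, n_valid = valid, method = method)
  out[!is.na(out$diff), , drop = FALSE]
}

#' Filter permutation results to large, significant differences
#'
#' Keeps region pairs whose absolute correlation difference is at least
#' `min_abs_diff` and whose permutation p-value is below `alpha`. No
#' multiplicity correction is applied at this exploratory stage.
#'
#' @param results tibble from [permute_correlation_differences()].
#' @param alpha significance threshold; default 0.01.
#' @param min_abs_diff minimum |r_B - r_A|; default 1.
#' @return the filtered tibble.
#' @export
significant_differences <- function(results, alpha = 0.01, min_abs_diff = 1) {
  abort_if(nrow(results) == 0, "`results` is empty")
  results[abs(results$diff) >= min_abs_diff &
            !is.na(results$p_value) & results$p_value < alpha, , drop = FALSE]
}
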