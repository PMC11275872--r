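# Pairwise regional Pearson correlation matrices with asymptotic p-values.

#' Asymptotic two-sided p-value of a Pearson correlation
#'
#' From the t statistic `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom. The degenerate case |r| = 1 returns 0, its limit.
#'
#' @param r Pearson coefficient(s), |r| <= 1.
#' @param n sample size(s), >= 3.
#' @return two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  abort_if(any(abs(r) > 1 + 1e-12, na.rm = TRUE), "|r| must be <= 1")
  abort_if(any(n < 3, na.rm = TRUE), "`n` must be >= 3")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0, {
    tt <- abs(r) * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  })
  unname(p)
}

#' Regional Pearson correlation matrix for one group and channel
#'
#' Pairwise-complete Pearson correlations of the chosen value across mice,
#' for every region pair, with the per-pair sample size and the asymptotic
#' two-sided p-value. Pairs with fewer than 3 complete mice or a
#' zero-variance member are undefined (NA r/p, flagged by `defined`).
#'
#' @param table a [region_count_table()]-style tibble.
#' @param group group label to subset.
#' @param channel channel to subset.
#' @param value column holding the analyzed value (default "normalized").
#' @return object of class `correlation_matrix`: list with `regions`, `r`,
#'   `p`, `n`, `defined` matrices and the group/channel labels.
#' @export
correlation_matrix <- function(table, group, channel, value = "normalized") {
  tab <- tibble::as_tibble(table)
  tab <- tab[tab$group == group & tab$channel == channel, ]
  abort_if(nrow(tab) == 0, "no rows for that group/channel")
  abort_if(length(unique(tab$mouse_id)) < 3,
           "at least 3 mice are required for correlations")
  wide <- tidyr::pivot_wider(tab[, c("mouse_id", "region", value)],
                             names_from = "region", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$mouse_id
  regions <- colnames(m)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  ok <- !is.na(m)
  n <- crossprod(ok)
  defined <- !is.na(r) & n >= 3
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  idx <- which(defined)
  p[idx] <- correlation_pvalue(r[idx], n[idx])
  diag(p) <- NA_real_
  diag(defined) <- FALSE
  structure(list(regions = regions, r = r, p = p,
                 n = matrix(as.numeric(n), nrow(n), dimnames = dimnames(r)),
                 defined = defined, group = group, channel = channel),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %s / %s: %d regions, %d defined pairs\n",
              x$group, x$channel, length(x$regions),
              sum(x$defined[upper.tri(x$defined)])))
  invisible(x)
}

#' Correlation matrix as a long tibble
#'
#' One row per unordered region pair (upper triangle).
#'
#' @param corr a [correlation_matrix()].
#' @return tibble with region_a, region_b, r, p, n, defined.
#' @export
correlation_long <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  ut <- which(upper.tri(corr$r), arr.ind = TRUE)
  tibble::tibble(
    region_a = corr$regions[ut[, 1]], region_b = corr$regions[ut[, 2]],
    r = corr$r[ut], p = corr$p[ut], n = corr$n[ut],
    defined = corr$defined[ut])
}
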