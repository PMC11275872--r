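# Synthetic per-mouse, per-region normalized count tables with a known
# between-region correlation structure, emulating a mapped dual-ensemble
# dataset (two groups of 5-6 mice, ~100 regions, counts/mm3).

#' Default region acronyms for synthetic count tables
#'
#' About a hundred region codes in the style of the Allen mouse brain
#' ontology (isocortical, hippocampal, amygdalar, thalamic, hypothalamic and
#' midbrain structures). Purely a naming vocabulary for simulation.
#'
#' @return character vector of region acronyms.
#' @export
default_region_acronyms <- function() {
  c("ACA", "AI", "RSP", "PL", "ILA", "ORB", "FRP", "MOp", "MOs",
    "SSp-m", "SSp-ll", "SSp-bfd", "SSp-ul", "SSp-n", "SSp-tr", "SSs",
    "AUDp", "AUDd", "AUDv", "VISp", "VISl", "VISam", "TEa", "ECT", "PERI",
    "ENTl", "ENTm", "PIR", "CLA", "EPd", "GU", "VISC", "PTLp",
    "dDG", "vDG", "dCA1", "dCA2", "dCA3", "vCA1", "vCA2", "vCA3",
    "SUB", "ProS", "PAR", "POST", "PRE", "IG",
    "LA", "BLA", "BMA", "CEA", "MEA", "PAA", "COA", "IA", "AAA",
    "ACB", "CP", "LS", "SH", "MS", "NDB", "SI", "GPe", "GPi", "FS", "OT",
    "BST", "TT", "DP",
    "VM", "VAL", "VPM", "VPL", "PO", "LP", "LD", "LGd", "MG", "RT", "RE",
    "PVT", "CM", "MD", "AV", "AM", "AD",
    "LHA", "ZI", "PVH", "DMH", "VMH", "AHN", "MM", "SUM", "TU", "PH",
    "STN", "SNr", "SNc", "VTA", "MRN", "SCm", "SCs", "PAG", "RN", "PPN",
    "DR", "NI")
}

#' Specify a synthetic regional count table
#'
#' @param groups named integer vector: mice per group, e.g.
#'   `c(CT = 5, IS = 6)` (two groups, at least 3 mice each).
#' @param regions character vector of region acronyms.
#' @param base_mean,base_sd mean and SD of the normalized counts
#'   (cells/mm^3) before truncation at zero. Defaults (4000, 1200) are in the
#'   range typical of immediate-early-gene densities in cortex.
#' @param correlated_pairs tibble/data.frame with columns `group`,
#'   `region_a`, `region_b`, `r`: target Pearson correlations induced via a
#'   Gaussian copula before truncation. Unlisted pairs are independent.
#' @param group_effects tibble/data.frame with columns `group`, `region`,
#'   `shift`: additive mean shifts (cells/mm^3).
#' @param channel channel label stamped on the rows.
#' @param seed integer controlling all randomness.
#' @return an object of class `count_table_spec`.
#' @export
count_table_spec <- function(groups = c(CT = 5L, IS = 6L),
                             regions = default_region_acronyms(),
                             base_mean = 4000, base_sd = 1200,
                             correlated_pairs = NULL,
                             group_effects = NULL,
                             channel = "ch1",
                             seed = 1L) {
  abort_if(length(groups) != 2 || is.null(names(groups)),
           "`groups` must be a named vector of two group sizes")
  abort_if(any(groups < 3), "at least 3 mice per group are required")
  abort_if(anyDuplicated(regions) > 0, "region acronyms must be unique")
  if (!is.null(correlated_pairs)) {
    correlated_pairs <- tibble::as_tibble(correlated_pairs)
    abort_if(!all(c("group", "region_a", "region_b", "r") %in%
                    names(correlated_pairs)),
             "`correlated_pairs` needs columns group, region_a, region_b, r")
    abort_if(any(abs(correlated_pairs$r) > 1),
             "target correlations must satisfy |r| <= 1")
    bad <- setdiff(c(correlated_pairs$region_a, correlated_pairs$region_b),
                   regions)
    abort_if(length(bad) > 0,
             paste("correlated pair regions not in `regions`:",
                   paste(bad, collapse = ", ")))
  }
  if (!is.null(group_effects)) {
    group_effects <- tibble::as_tibble(group_effects)
    abort_if(!all(c("group", "region", "shift") %in% names(group_effects)),
             "`group_effects` needs columns group, region, shift")
  }
  structure(list(groups = groups, regions = regions, base_mean = base_mean,
                 base_sd = base_sd, correlated_pairs = correlated_pairs,
                 group_effects = group_effects, channel = channel,
                 seed = as.integer(seed)),
            class = "count_table_spec")
}

#' Generate a synthetic regional count table
#'
#' Per group, draws one latent standard-normal vector per mouse across
#' regions from a multivariate normal whose off-diagonal entries are the
#' target correlations of `correlated_pairs` (a Gaussian copula), scales to
#' `base_mean + shift + base_sd * z`, and truncates at zero. Counts for
#' regions not listed in any pair are independent.
#'
#' @param spec a [count_table_spec()].
#' @return a tibble with columns mouse_id, group, region, channel,
#'   raw_count (NA for simulated tables), volume_mm3 (NA), normalized
#'   (cells/mm^3), compatible with [region_count_table()].
#' @export
generate_count_table <- function(spec) {
  stopifnot(inherits(spec, "count_table_spec"))
  with_seed(spec$seed, {
    out <- lapply(names(spec$groups), function(g) {
      n <- spec$groups[[g]]
      m <- length(spec$regions)
      sigma <- diag(m)
      dimnames(sigma) <- list(spec$regions, spec$regions)
      cp <- spec$correlated_pairs
      if (!is.null(cp)) {
        cp <- cp[cp$group == g, , drop = FALSE]
        for (i in seq_len(nrow(cp))) {
          sigma[cp$region_a[i], cp$region_b[i]] <- cp$r[i]
          sigma[cp$region_b[i], cp$region_a[i]] <- cp$r[i]
        }
      }
      ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
      abort_if(min(ev) < -1e-8,
               sprintf("correlation targets for group %s are jointly infeasible (matrix not positive semidefinite)", g))
      z <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = sigma, tol = 1e-6)
      z <- matrix(z, nrow = n)
      mu <- rep(spec$base_mean, m)
      ge <- spec$group_effects
      if (!is.null(ge)) {
        ge <- ge[ge$group == g, , drop = FALSE]
        mu <- mu + ifelse(spec$regions %in% ge$region,
                          ge$shift[match(spec$regions, ge$region)], 0)
        mu[is.na(mu)] <- spec$base_mean
      }
      vals <- pmax(sweep(z * spec$base_sd, 2, mu, "+"), 0)
      tibble::tibble(
        mouse_id = rep(sprintf("%s_%02d", g, seq_len(n)), times = m),
        group = g,
        region = rep(spec$regions, each = n),
        channel = spec$channel,
        raw_count = NA_real_,
        volume_mm3 = NA_real_,
        normalized = as.vector(vals))
    })
    dplyr::bind_rows(out)
  })
}
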