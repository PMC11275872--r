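# Validation of automated detections against reference (manual) counts.

#' Precision, recall and F1 of a detection set against reference points
#'
#' Detections and references are matched one-to-one greedily by ascending
#' centroid distance; pairs within `tolerance` micrometres are true
#' positives, unmatched detections false positives, unmatched references
#' false negatives. F1 is the harmonic mean of precision and recall,
#' 1/F1 = (1/P + 1/R)/2.
#'
#' @param detected tibble with columns centroid_z_um, centroid_y_um,
#'   centroid_x_um (e.g. a segmentation `objects` table), or a 3-column
#'   matrix of (z, y, x) in um.
#' @param reference reference points: tibble with z_um, y_um, x_um columns
#'   or a 3-column matrix.
#' @param tolerance maximum matching distance in micrometres.
#' @return object of class `detection_metrics`: list with tp, fp, fn,
#'   precision, recall, f1 and `precision_defined` (FALSE when there were no
#'   detections but references existed, in which case precision is reported
#'   as 0).
#' @export
detection_metrics <- function(detected, reference, tolerance) {
  abort_if(!(tolerance > 0), "`tolerance` must be positive")
  as_pts <- function(x, cols) {
    if (is.matrix(x)) return(x)
    if (nrow(x) == 0) return(matrix(numeric(0), 0, 3))
    got <- intersect(cols, names(x))
    abort_if(length(got) != 3,
             paste("point table must have columns", paste(cols, collapse = ", ")))
    as.matrix(x[, cols])
  }
  det <- as_pts(detected, c("centroid_z_um", "centroid_y_um", "centroid_x_um"))
  ref <- as_pts(reference, c("z_um", "y_um", "x_um"))
  nd <- nrow(det); nr <- nrow(ref)
  if (nd == 0 && nr == 0) {
    return(structure(list(tp = 0L, fp = 0L, fn = 0L, precision = 1,
                          recall = 1, f1 = 1, precision_defined = TRUE),
                     class = "detection_metrics"))
  }
  tp <- 0L
  if (nd > 0 && nr > 0) {
    dmat <- sqrt(outer(det[, 1], ref[, 1], "-")^2 +
                   outer(det[, 2], ref[, 2], "-")^2 +
                   outer(det[, 3], ref[, 3], "-")^2)
    cand <- which(dmat <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_d <- logical(nd); used_r <- logical(nr)
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]; ri <- cand[i, 2]
        if (!used_d[di] && !used_r[ri]) {
          used_d[di] <- TRUE; used_r[ri] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- nd - tp
  fn <- nr - tp
  metrics_from_counts(tp, fp, fn, precision_defined = nd > 0)
}

# Build the metrics object from raw TP/FP/FN counts.
metrics_from_counts <- function(tp, fp, fn, precision_defined = TRUE) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  f1 <- f1_score(precision, recall)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = precision, recall = recall, f1 = f1,
                 precision_defined = precision_defined),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | P %.3f%s  R %.3f  F1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision,
              if (x$precision_defined) "" else " (undefined: no detections)",
              x$recall, x$f1))
  invisible(x)
}

#' Harmonic-mean F1 score
#'
#' `1/F1 = (1/P + 1/R)/2`; returns 0 when either input is 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  abort_if(precision < 0 || precision > 1 || recall < 0 || recall > 1,
           "precision and recall must be in [0, 1]")
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Estimated true-positive count from manual and automated totals
#'
#' The mean of two derivations of the same quantity:
#' (manual total - false negatives) and (automated total - false positives).
#'
#' @param manual_total,auto_total total manual and automated counts.
#' @param fn,fp false-negative and false-positive counts
#'   (`fn <= manual_total`, `fp <= auto_total`).
#' @return estimated TP (can be fractional).
#' @export
estimate_tp <- function(manual_total, auto_total, fn, fp) {
  abort_if(any(c(manual_total, auto_total, fn, fp) < 0),
           "counts must be nonnegative")
  abort_if(fn > manual_total, "`fn` cannot exceed `manual_total`")
  abort_if(fp > auto_total, "`fp` cannot exceed `auto_total`")
  ((manual_total - fn) + (auto_total - fp)) / 2
}
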