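## Scoring: threshold-based 3D object counting against sphere ground truth,
## plus histogram-restoration diagnostics.  Mirrors the standard FIJI
## 3D-object-counter workflow: binarize at a single operating point, label
## 26-connected components, drop small ones, and measure each object.

#' Count 3D objects above a threshold
#'
#' Binarizes at `value > threshold`, labels 26-connected components, drops
#' components smaller than `min_size`, and measures each surviving object on
#' the original intensities.
#'
#' @param x an `image_stack` or 3D array.
#' @param threshold intensity threshold (ADU).
#' @param min_size minimum voxel count (default 5).
#' @return data.frame: id, x, y, z (intensity-weighted centroid, voxels),
#'   voxel_count, mean_intensity, integrated_intensity, max_intensity.
#' @export
count_objects_3d <- function(x, threshold, min_size = 5) {
  arr <- if (inherits(x, "image_stack")) stack_to_array(x) else x
  lab <- label_components(arr > threshold)
  n <- max(lab)
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), voxel_count = integer(0),
                      mean_intensity = numeric(0),
                      integrated_intensity = numeric(0),
                      max_intensity = numeric(0))
  if (n == 0) return(empty)
  idx <- which(lab > 0)
  li <- lab[idx]
  v <- arr[idx]
  d <- dim(arr)
  ai <- arrayInd(idx, d)
  size <- tabulate(li, n)
  keep <- which(size >= min_size)
  if (length(keep) == 0) return(empty)
  gf <- factor(li, levels = seq_len(n))   # keep numeric label order
  tot <- tapply(v, gf, sum)
  wx <- tapply(v * ai[, 2], gf, sum) / tot   # columns = x
  wy <- tapply(v * ai[, 1], gf, sum) / tot   # rows = y
  wz <- tapply(v * ai[, 3], gf, sum) / tot
  mx <- tapply(v, gf, max)
  out <- data.frame(id = seq_along(keep),
                    x = as.numeric(wx[keep]), y = as.numeric(wy[keep]),
                    z = as.numeric(wz[keep]),
                    voxel_count = size[keep],
                    mean_intensity = as.numeric(tot[keep]) / size[keep],
                    integrated_intensity = as.numeric(tot[keep]),
                    max_intensity = as.numeric(mx[keep]))
  rownames(out) <- NULL
  out
}

#' Match detections to ground-truth spheres
#'
#' Greedy one-to-one matching by ascending centroid-to-center distance;
#' pairs closer than `max_dist` are true positives, unmatched detections
#' false positives, unmatched truths false negatives. Because object
#' detection has no defined negative count, the false-positive axis is
#' reported as the false-discovery fraction fp / n_detected.
#'
#' @param detected data.frame from [count_objects_3d()].
#' @param truth ground-truth data.frame (columns x, y, z, id).
#' @param max_dist matching radius in voxels.
#' @return list: counts (`n_true`, `n_detected`, `tp`, `fp`, `fn`), rates
#'   (`tpr`, `fdr`), and `matches` (data.frame truth_id, det_id, dist).
#' @export
match_to_truth <- function(detected, truth, max_dist) {
  stopifnot(max_dist > 0)
  nd <- nrow(detected); nt <- nrow(truth)
  matches <- data.frame(truth_id = integer(0), det_id = integer(0),
                        dist = numeric(0))
  if (nd > 0 && nt > 0) {
    dmat <- outer(detected$x, truth$x, "-")^2 +
      outer(detected$y, truth$y, "-")^2 +
      outer(detected$z, truth$z, "-")^2
    dmat <- sqrt(dmat)
    cand <- which(dmat <= max_dist, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dmat[cand])
      used_d <- logical(nd); used_t <- logical(nt)
      for (r in ord) {
        di <- cand[r, 1]; ti <- cand[r, 2]
        if (!used_d[di] && !used_t[ti]) {
          used_d[di] <- TRUE; used_t[ti] <- TRUE
          matches <- rbind(matches,
                           data.frame(truth_id = truth$id[ti],
                                      det_id = detected$id[di],
                                      dist = dmat[di, ti]))
        }
      }
    }
  }
  tp <- nrow(matches)
  list(n_true = nt, n_detected = nd, tp = tp, fp = nd - tp, fn = nt - tp,
       tpr = if (nt > 0) tp / nt else NA_real_,
       fdr = if (nd > 0) (nd - tp) / nd else 0,
       matches = matches)
}

#' Relative mean absolute error of detected sphere statistics
#'
#' For spheres that are true positives in both the test comparison and the
#' reference (undistorted) comparison, the mean absolute difference of each
#' detection statistic, divided by the reference mean of that statistic.
#'
#' @param test_cmp,ref_cmp results of [match_to_truth()] on the test and
#'   reference stacks (same truth, same `max_dist`).
#' @param test_det,ref_det the corresponding [count_objects_3d()] tables.
#' @return named numeric vector: voxel_count, mean_intensity,
#'   integrated_intensity, centroid_dist (all relative except
#'   centroid_dist, in voxels); `NA` when there are no common true
#'   positives, plus attribute `n_common`.
#' @export
mae_vs_reference <- function(test_cmp, ref_cmp, test_det, ref_det) {
  common <- intersect(test_cmp$matches$truth_id, ref_cmp$matches$truth_id)
  stats_names <- c("voxel_count", "mean_intensity", "integrated_intensity")
  if (length(common) == 0) {
    out <- stats::setNames(rep(NA_real_, 4), c(stats_names, "centroid_dist"))
    attr(out, "n_common") <- 0L
    return(out)
  }
  t_ids <- test_cmp$matches$det_id[match(common, test_cmp$matches$truth_id)]
  r_ids <- ref_cmp$matches$det_id[match(common, ref_cmp$matches$truth_id)]
  trow <- test_det[match(t_ids, test_det$id), ]
  rrow <- ref_det[match(r_ids, ref_det$id), ]
  out <- vapply(stats_names, function(s) {
    mean(abs(trow[[s]] - rrow[[s]])) / mean(rrow[[s]])
  }, 0)
  cd <- mean(sqrt((trow$x - rrow$x)^2 + (trow$y - rrow$y)^2 +
                    (trow$z - rrow$z)^2))
  out <- c(out, centroid_dist = cd)
  attr(out, "n_common") <- length(common)
  out
}

#' Earth-mover distance between min-max-matched intensity histograms
#'
#' Each stack is rescaled linearly to [0, 1] by its own min/max (so global
#' scale drops out), histogrammed on `bins` shared bins, and the 1D
#' earth-mover (Wasserstein-1) distance between the normalized histograms is
#' returned. A constant stack puts all mass in one bin.
#'
#' @param a,b `image_stack`s or 3D arrays of the same dimensions.
#' @param bins number of shared bins (default 256).
#' @return nonnegative scalar (in units of the [0, 1] rescaled intensity).
#' @export
histogram_distance <- function(a, b, bins = 256) {
  va <- as.vector(if (inherits(a, "image_stack")) stack_to_array(a) else a)
  vb <- as.vector(if (inherits(b, "image_stack")) stack_to_array(b) else b)
  rescale <- function(v) {
    r <- range(v)
    if (r[2] == r[1]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  breaks <- seq(0, 1, length.out = bins + 1)
  ha <- tabulate(pmin(findInterval(rescale(va), breaks, all.inside = TRUE),
                      bins), bins)
  hb <- tabulate(pmin(findInterval(rescale(vb), breaks, all.inside = TRUE),
                      bins), bins)
  pa <- ha / sum(ha); pb <- hb / sum(hb)
  sum(abs(cumsum(pa - pb))) / bins
}

#' Otsu threshold of an intensity volume
#'
#' Maximizes between-class variance on a 256-bin histogram of the min-max
#' rescaled volume (one global operating point for the whole stack, as a
#' user choosing a single FIJI threshold would).
#'
#' @param x `image_stack` or array.
#' @param bins histogram bins (default 256).
#' @return threshold on the original intensity scale.
#' @export
otsu_threshold <- function(x, bins = 256) {
  v <- as.vector(if (inherits(x, "image_stack")) stack_to_array(x) else x)
  r <- range(v)
  if (r[2] == r[1]) return(r[1])
  h <- tabulate(pmin(findInterval((v - r[1]) / (r[2] - r[1]),
                                  seq(0, 1, length.out = bins + 1),
                                  all.inside = TRUE), bins), bins)
  p <- h / sum(h)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  r[1] + (k / bins) * (r[2] - r[1])
}
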