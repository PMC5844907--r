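## Tissue-vs-medium segmentation.
##
## Light-sheet planes of cleared tissue contain large regions of imaging
## medium that must not be "corrected": dividing medium by a background
## estimate drawn from tissue creates border artifacts, and medium pixels
## would contaminate the background quantiles.  Each plane is classified
## independently: per-pixel features -> PCA (2 components) -> 2-cluster fit
## (Gaussian mixture EM or k-means); the cluster with the higher mean raw
## intensity is tissue, because imaging medium is darker than autofluorescent
## tissue.

#' Tissue-detection configuration
#'
#' @param method `"gmm_em"`, `"kmeans"`, or `"none"` (mask all-true).
#' @param downsample_factor integer >= 1; the plane is subsampled by this
#'   stride before feature extraction (default 8 keeps detection cheap on
#'   large planes).
#' @param feature_window odd window (pixels, on the downsampled grid) for the
#'   local mean / standard-deviation features.
#' @param min_component_area connected components (8-connectivity) smaller
#'   than this (full-resolution pixels) are removed; `NULL` = 0.1% of plane.
#' @param dilation_radius binary dilation radius (pixels) applied last, to
#'   keep the media/tissue border inside the mask; `NULL` = SFS/4 is filled
#'   in by the normalizer.
#' @param seed integer seed for the clustering.
#' @return a `tissue_config` list.
#' @export
tissue_config <- function(method = c("none", "gmm_em", "kmeans"),
                          downsample_factor = 8L,
                          feature_window = 9L,
                          min_component_area = NULL,
                          dilation_radius = NULL,
                          seed = 1L) {
  method <- match.arg(method)
  feature_window <- coerce_odd(feature_window)
  if (feature_window < 3) stop("feature_window must be >= 3")
  if (downsample_factor < 1) stop("downsample_factor must be >= 1")
  structure(list(method = method,
                 downsample_factor = as.integer(downsample_factor),
                 feature_window = as.integer(feature_window),
                 min_component_area = min_component_area,
                 dilation_radius = dilation_radius,
                 seed = as.integer(seed)),
            class = "tissue_config")
}

## Box-filtered local mean and sd with edge replication.
local_moments <- function(x, window) {
  k <- (window - 1L) %/% 2L
  pad <- function(m) {
    m <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), , drop = FALSE]
    m[, c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
  }
  box1 <- function(m) {
    # running sum over window along columns
    cs <- apply(m, 2, cumsum)
    rbind(cs[window, , drop = FALSE],
          cs[(window + 1):nrow(cs), , drop = FALSE] -
            cs[1:(nrow(cs) - window), , drop = FALSE])
  }
  boxsum <- function(m) t(box1(t(box1(pad(m)))))
  n <- window^2
  mu <- boxsum(x) / n
  ex2 <- boxsum(x^2) / n
  v <- pmax(ex2 - mu^2, 0)
  list(mean = mu, sd = sqrt(v))
}

#' Extract standardized per-pixel features
#'
#' For each pixel of the (strided) downsampled plane: local mean intensity,
#' local standard deviation, and raw intensity, each column standardized to
#' zero mean and unit variance (constant columns map to all-zero).
#'
#' @param plane numeric matrix.
#' @param cfg a [tissue_config()].
#' @return list with `features` (n x 3 matrix), `raw` (raw intensities),
#'   `ds_dim` (downsampled grid dimension).
#' @export
extract_pixel_features <- function(plane, cfg) {
  f <- cfg$downsample_factor
  ds <- plane[seq(1, nrow(plane), by = f), seq(1, ncol(plane), by = f),
              drop = FALSE]
  mom <- local_moments(ds, cfg$feature_window)
  feats <- cbind(local_mean = as.vector(mom$mean),
                 local_sd = as.vector(mom$sd),
                 raw = as.vector(ds))
  std <- apply(feats, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  list(features = std, raw = as.vector(ds), ds_dim = dim(ds))
}

## Two-cluster fit on the PCA scores.  The Gaussian-mixture EM uses
## equal-covariance models (EEE, then EII): per-cluster covariances latch
## onto the spread-out media/tissue boundary band and split the background
## mode instead of separating tissue from medium.
cluster_two <- function(pc, method, seed) {
  if (method == "gmm_em") {
    fit <- withr::with_seed(seed, {
      bic <- mclust::mclustBIC(pc, G = 2, modelNames = c("EEE", "EII"),
                               verbose = FALSE)
      mclust::Mclust(pc, G = 2, x = bic, verbose = FALSE)
    })
    if (is.null(fit)) return(NULL)
    fit$classification
  } else {
    withr::with_seed(seed,
      stats::kmeans(pc, centers = 2, nstart = 10, iter.max = 100))$cluster
  }
}

#' Detect tissue pixels in a plane
#'
#' PCA (2 components) on standardized local features, 2-cluster fit with the
#' configured method; the cluster with the higher mean raw intensity is
#' labeled tissue. The downsampled labeling is upsampled to full resolution
#' (nearest neighbor) and post-processed with [postprocess_mask()].
#' Deterministic for a fixed seed; because the tissue label is assigned by
#' relative intensity, the result is invariant to cluster-index permutation
#' and to global affine rescaling of the plane.
#'
#' @param plane numeric matrix.
#' @param cfg a [tissue_config()] with `method != "none"`.
#' @return list: `mask` (logical matrix), `tissue_fraction`, `warning`
#'   (character or NULL).
#' @export
detect_tissue <- function(plane, cfg) {
  stopifnot(cfg$method != "none")
  if (max(plane) == min(plane)) {
    return(list(mask = matrix(TRUE, nrow(plane), ncol(plane)),
                tissue_fraction = 1,
                warning = "degenerate plane (constant); mask set all-true"))
  }
  fx <- extract_pixel_features(plane, cfg)
  keep <- apply(fx$features, 2, function(c) any(c != 0))
  feats <- fx$features[, keep, drop = FALSE]
  npc <- min(2L, ncol(feats))
  pc <- stats::prcomp(feats, center = FALSE, scale. = FALSE)$x[, seq_len(npc),
                                                               drop = FALSE]
  cl <- cluster_two(pc, cfg$method, cfg$seed)
  if (is.null(cl) || length(unique(cl)) < 2) {
    return(list(mask = matrix(TRUE, nrow(plane), ncol(plane)),
                tissue_fraction = 1,
                warning = "clustering degenerate; mask set all-true"))
  }
  mean_raw <- tapply(fx$raw, cl, mean)
  tissue_label <- as.integer(names(which.max(mean_raw)))
  ds_mask <- matrix(cl == tissue_label, fx$ds_dim[1], fx$ds_dim[2])
  # nearest-neighbor upsampling back to the full grid
  f <- cfg$downsample_factor
  ri <- pmin(fx$ds_dim[1], (seq_len(nrow(plane)) - 1L) %/% f + 1L)
  ci <- pmin(fx$ds_dim[2], (seq_len(ncol(plane)) - 1L) %/% f + 1L)
  raw_mask <- ds_mask[ri, ci, drop = FALSE]
  postprocess_mask(raw_mask, cfg)
}

#' Clean up a raw tissue mask
#'
#' Fill holes, remove connected components (8-connectivity) smaller than
#' `min_component_area`, then dilate by `dilation_radius` so the media/tissue
#' border stays inside the mask. Idempotent when the dilation radius is 0.
#'
#' @param raw logical matrix.
#' @param cfg a [tissue_config()].
#' @return list: `mask`, `tissue_fraction`, `warning`.
#' @export
postprocess_mask <- function(raw, cfg) {
  min_area <- cfg$min_component_area
  if (is.null(min_area)) min_area <- ceiling(0.001 * length(raw))
  dil <- cfg$dilation_radius
  if (is.null(dil)) dil <- 0L
  m <- fill_holes(raw)
  if (any(m) && min_area > 1) {
    lab <- label_components(m)
    sizes <- tabulate(lab)
    m <- array(lab > 0 & sizes[pmax(lab, 1L)] >= min_area, dim = dim(m))
  }
  if (any(m) && dil > 0) {
    m <- EBImage::dilate(m * 1L, EBImage::makeBrush(2L * as.integer(dil) + 1L,
                                                    "disc")) > 0
  }
  warning_msg <- NULL
  if (!any(m)) {
    warning_msg <- "mask empty after cleanup; plane treated as no-tissue"
  }
  list(mask = m, tissue_fraction = mean(m), warning = warning_msg)
}

#' Detect tissue for every plane of a stack
#'
#' @param stack an `image_stack`.
#' @param cfg a [tissue_config()]; method `"none"` yields all-true masks.
#' @return list with `masks` (list of logical matrices) and `warnings`.
#' @export
detect_tissue_stack <- function(stack, cfg) {
  warnings <- character(0)
  masks <- vector("list", stack$z_count)
  for (z in seq_len(stack$z_count)) {
    if (cfg$method == "none") {
      masks[[z]] <- matrix(TRUE, stack$height, stack$width)
    } else {
      cfg_z <- cfg
      cfg_z$seed <- substream_seed(cfg$seed, "tissue", z)
      res <- detect_tissue(stack$planes[[z]], cfg_z)
      masks[[z]] <- res$mask
      if (!is.null(res$warning)) {
        warnings <- c(warnings, sprintf("plane %d: %s", z, res$warning))
      }
    }
  }
  list(masks = masks, warnings = warnings)
}
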