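## XY normalization: the per-plane core of the method.
##
## The background of a fluorescence plane is assumed smooth at the scale of
## the spatial filter, while signal is sparse (<1% of pixels in typical
## stacks).  Signal pixels (above the plane's maximum background intensity,
## MBI) are deleted and re-filled by resampling the observed background
## distribution; a Savitzky-Golay surface fitted to the signal-free plane
## becomes the background mask M, and the plane is corrected by division,
## N(x) = I(x) / M(x), then rescaled so pure background stays at its typical
## ADU level.

#' Normalization configuration
#'
#' The full user contract for a normalization run.
#'
#' @param mbi maximum background intensity (ADU): the highest pixel value
#'   attributed to background on the reference plane. Pixels above the
#'   per-plane propagated MBI are treated as signal during background
#'   estimation.
#' @param sfs spatial filter size (pixels): Savitzky-Golay window; should be
#'   at least twice the largest signal structure so the mask keeps only
#'   background-scale gradients. Even values are coerced up to odd.
#' @param reference_plane_index 1-based plane on which `mbi` was chosen.
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param z_mode cross-stack harmonization: `"none"`, `"upper_quantile"`,
#'   `"contrast_stretch"`, or `"semi_quantile"`.
#' @param lower_quantile_rank lower anchor for contrast stretch (default 0.10).
#' @param quantile_count number of recorded quantiles per plane (default 10000).
#' @param tissue a [tissue_config()].
#' @param seed master seed; all randomness (background infill, clustering)
#'   derives per-plane substreams from it.
#' @param mask_floor minimum mask value (ADU, default 1) preventing division
#'   blow-up in empty corners.
#' @param bg_passes background-fit passes (default 3). The first pass
#'   removes signal at the propagated MBI; each further pass removes
#'   residual signal features left under the MBI (pixels more than 3 robust
#'   standard deviations above the current mask -- e.g. the sub-MBI skirts
#'   of bright objects in strongly attenuated regions, which a single
#'   plane-wide threshold cannot catch) and refits the mask.
#' @param workers number of processes for the per-plane loop (results are
#'   identical for any worker count).
#' @return a `norm_config` list.
#' @export
norm_config <- function(mbi, sfs, reference_plane_index = 1L,
                        sg_order = 3L,
                        z_mode = c("semi_quantile", "upper_quantile",
                                   "contrast_stretch", "none"),
                        lower_quantile_rank = 0.10,
                        quantile_count = 10000L,
                        tissue = tissue_config("none"),
                        seed = 1L, mask_floor = 1,
                        workers = 1L, bg_passes = 3L) {
  z_mode <- match.arg(z_mode)
  if (mbi <= 0) stop("mbi must be > 0")
  sfs <- coerce_odd(sfs)
  if (sg_order < 1) stop("sg_order must be >= 1")
  if (sfs < sg_order + 2) stop("sfs must be >= sg_order + 2")
  if (lower_quantile_rank <= 0 || lower_quantile_rank >= 1) {
    stop("lower_quantile_rank must be in (0, 1)")
  }
  structure(list(mbi = mbi, sfs = as.integer(sfs),
                 reference_plane_index = as.integer(reference_plane_index),
                 sg_order = as.integer(sg_order), z_mode = z_mode,
                 lower_quantile_rank = lower_quantile_rank,
                 quantile_count = as.integer(quantile_count),
                 tissue = tissue, seed = as.integer(seed),
                 mask_floor = mask_floor, workers = as.integer(workers),
                 bg_passes = as.integer(bg_passes)),
            class = "norm_config")
}

#' Propagate the MBI across the stack
#'
#' The user picks the MBI on one reference plane. Each plane receives as
#' its own MBI the user's value scaled by the ratio of its median tissue
#' intensity to the reference plane's: the median tracks the background
#' (signal is sparse) and is equivariant under per-plane multiplicative
#' dimming -- exactly the artifact being corrected -- while staying
#' insensitive to plane-to-plane fluctuations in signal content, which
#' would drag a quantile-rank-matched threshold into the signal range on
#' signal-rich planes. The user's quantile rank q* (the continuous rank of
#' the MBI on the reference plane's piecewise-linear empirical quantile
#' function) is also recorded; it defines the upper quantile for Z
#' normalization.
#'
#' @param stack an `image_stack`.
#' @param masks per-plane logical tissue masks.
#' @param cfg a [norm_config()].
#' @return list: `uq_rank` (the shared rank q*), `mbi` (numeric vector, NA
#'   for planes with no tissue pixels, flagged in `skip`).
#' @export
propagate_mbi <- function(stack, masks, cfg) {
  ref <- cfg$reference_plane_index
  if (ref < 1 || ref > stack$z_count) stop("reference_plane_index out of range")
  ref_pix <- stack$planes[[ref]][masks[[ref]]]
  if (length(ref_pix) == 0) stop("reference plane has no tissue pixels")
  med_ref <- stats::median(ref_pix)
  mbi <- rep(NA_real_, stack$z_count)
  ranks <- rep(NA_real_, stack$z_count)
  skip <- logical(stack$z_count)
  for (z in seq_len(stack$z_count)) {
    pix <- stack$planes[[z]][masks[[z]]]
    if (length(pix) == 0) { skip[z] <- TRUE; next }
    mbi[z] <- if (med_ref > 0) {
      cfg$mbi * stats::median(pix) / med_ref
    } else {
      cfg$mbi
    }
    ranks[z] <- empirical_rank(pix, mbi[z])
  }
  # the shared upper-quantile rank is the smallest per-plane rank of the
  # propagated MBI: ranks at or below it are background on EVERY plane, so
  # cross-plane quantile matching never mixes one plane's background tail
  # with another plane's signal shoulder
  q_star <- min(ranks, na.rm = TRUE)
  list(uq_rank = q_star, mbi = mbi, skip = skip)
}

#' Delete signal pixels and re-fill from the background distribution
#'
#' Tissue pixels above `mbi_i` are replaced by values drawn independently,
#' uniformly with replacement, from the plane's own sub-MBI tissue pixels,
#' so the infill follows the observed background law with no parametric
#' assumption. When `window` is given, each pixel draws from the sub-MBI
#' tissue pixels inside the window centered on it (falling back to the
#' whole plane if that neighborhood is empty): under a lateral background
#' gradient -- the very artifact being corrected -- local donors keep the
#' infill consistent with the background around the deleted pixel instead
#' of biasing it toward the plane-wide median. Non-tissue pixels are
#' untouched.
#'
#' @param plane numeric matrix.
#' @param mbi_i the plane's propagated MBI.
#' @param mask logical tissue mask.
#' @param seed substream seed for the resampling draw.
#' @param window odd side length of the local donor neighborhood (pixels),
#'   or `NULL` for plane-wide donors.
#' @return list: `plane` (signal-free), `n_replaced`.
#' @export
remove_signal <- function(plane, mbi_i, mask, seed = 1L, window = NULL) {
  over <- mask & plane > mbi_i
  sub <- mask & plane <= mbi_i
  if (!any(sub)) {
    stop("MBI below all tissue pixels; raise MBI")
  }
  list(plane = refill_pixels(plane, over, sub, seed, window),
       n_replaced = sum(over))
}

## Replace `over` pixels by donor draws from `sub` pixels (within `window`
## when given, plane-wide fallback).  Donor values are always originals.
refill_pixels <- function(plane, over, sub, seed, window = NULL) {
  n <- sum(over)
  if (n == 0) return(plane)
  donors <- plane[sub]
  withr::with_seed(seed, {
    if (is.null(window)) {
      plane[over] <- donors[sample.int(length(donors), n, replace = TRUE)]
    } else {
      h <- (coerce_odd(window) - 1L) %/% 2L
      coords <- which(over, arr.ind = TRUE)
      nr <- nrow(plane); nc <- ncol(plane)
      for (i in seq_len(n)) {
        r <- coords[i, 1]; c <- coords[i, 2]
        rs <- max(1L, r - h):min(nr, r + h)
        cs <- max(1L, c - h):min(nc, c + h)
        local <- plane[rs, cs][sub[rs, cs]]
        plane[r, c] <- if (length(local) > 0) {
          local[sample.int(length(local), 1L)]
        } else {
          donors[sample.int(length(donors), 1L)]
        }
      }
    }
    plane
  })
}

#' Estimate the background mask of a plane
#'
#' Non-tissue pixels are filled with the median tissue intensity (so the
#' smoother sees no media/tissue step), the filled plane is smoothed by a
#' separable 2D Savitzky-Golay filter of window SFS, and the surface is
#' floored at `mask_floor`. The result is the strictly positive divisor M.
#'
#' @param signal_free numeric matrix from [remove_signal()].
#' @param mask logical tissue mask.
#' @param cfg a [norm_config()].
#' @return list: `grid` (the mask M), `floor_applied` (logical).
#' @export
compute_background_mask <- function(signal_free, mask, cfg) {
  filled <- signal_free
  if (!all(mask)) filled[!mask] <- stats::median(signal_free[mask])
  m <- sg_smooth_2d(filled, cfg$sfs, cfg$sg_order)
  floored <- any(m < cfg$mask_floor)
  if (floored) m <- pmax(m, cfg$mask_floor)
  list(grid = m, floor_applied = floored)
}

#' Correct a plane by mask division
#'
#' Tissue pixels become `I(x) / M(x) * s` with standardization scale
#' `s = median(M over tissue)`: division flattens the background gradients,
#' and the median-of-mask rescale restores the ADU range so pure background
#' maps back to its typical level instead of ~1 (preventing artificial
#' overexposure when converting to integers). Non-tissue pixels are copied
#' unchanged. The result stays real-valued; clipping to the bit-depth range
#' happens only at write time.
#'
#' @param plane numeric matrix (the original plane, signal included).
#' @param mask_img background mask from [compute_background_mask()].
#' @param tissue logical tissue mask.
#' @return list: `plane` (corrected), `scale` (s).
#' @export
normalize_plane <- function(plane, mask_img, tissue) {
  m <- mask_img$grid
  if (any(m <= 0)) stop("internal error: background mask not strictly positive")
  if (!any(tissue)) return(list(plane = plane, scale = NA_real_))
  s <- stats::median(m[tissue])
  out <- plane
  out[tissue] <- plane[tissue] / m[tissue] * s
  list(plane = out, scale = s)
}

## Skirt-free pilot background: a running 2D median ignores compact bright
## features as long as they cover less than half the window.
median_surface <- function(x, radius) {
  hi <- max(x)
  radius <- min(radius, (min(dim(x)) - 1L) %/% 2L)
  if (hi <= 0 || radius < 1L) return(x)
  EBImage::medianFilter(x / hi, radius) * hi
}

normalize_one_plane <- function(plane, mbi_i, tissue, cfg, plane_seed) {
  rs <- remove_signal(plane, mbi_i, tissue, seed = plane_seed,
                      window = cfg$sfs)
  n_replaced <- rs$n_replaced
  sf <- rs$plane
  # refinement passes: residual signal features that survived the
  # plane-wide MBI (sub-MBI point-spread skirts, especially in attenuated
  # regions) are removed against a running-median pilot surface, which is
  # unbiased by such compact features. The outlier cut scales with the
  # local background level: noise is multiplicative across the gradient,
  # so a dim region needs a proportionally lower absolute cut.
  radius <- max(3L, (cfg$sfs - 1L) %/% 4L)
  for (pass in seq_len(max(0L, cfg$bg_passes - 1L))) {
    pilot <- median_surface(sf, radius)
    level <- pmax(pilot, cfg$mask_floor)
    scale <- level / stats::median(level[tissue])
    sigma <- stats::mad((sf[tissue] - pilot[tissue]) / scale[tissue])
    over <- tissue & (sf - pilot > 2 * sigma * scale)
    if (!any(over)) break
    sf <- refill_pixels(sf, over, tissue & !over,
                        substream_seed(plane_seed, "pass", pass),
                        window = cfg$sfs)
    n_replaced <- n_replaced + sum(over)
  }
  bg <- compute_background_mask(sf, tissue, cfg)
  np <- normalize_plane(plane, bg, tissue)
  list(plane = np$plane, mask_grid = bg$grid, scale = np$scale,
       n_replaced = n_replaced, floor_applied = bg$floor_applied)
}

#' XY-normalize every plane of a stack
#'
#' Runs tissue detection (if enabled), MBI propagation, then per plane:
#' signal removal, background-mask estimation, and division. Planes are
#' independent given their propagated MBI, so the loop parallelizes; results
#' are bit-identical for any worker count or plane order because each plane
#' draws from a substream keyed by (seed, plane index).
#'
#' @param stack an `image_stack`.
#' @param cfg a [norm_config()].
#' @param masks optional precomputed tissue masks (list of logical matrices);
#'   default runs `cfg$tissue`.
#' @return list: `planes` (real-valued corrected planes), `masks`,
#'   `bg_masks` (the per-plane background masks M), `records` (per-plane
#'   data.frame), `profiles` (quantile profiles for Z normalization),
#'   `uq_rank`, `warnings`.
#' @export
normalize_stack_xy <- function(stack, cfg, masks = NULL) {
  warnings <- character(0)
  if (is.null(masks)) {
    det <- detect_tissue_stack(stack, cfg$tissue)
    masks <- det$masks
    warnings <- c(warnings, det$warnings)
  }
  prop <- propagate_mbi(stack, masks, cfg)
  worker <- function(z) {
    if (prop$skip[z]) return(NULL)
    normalize_one_plane(stack$planes[[z]], prop$mbi[z], masks[[z]], cfg,
                        substream_seed(cfg$seed, "xy", z))
  }
  zs <- seq_len(stack$z_count)
  results <- if (cfg$workers > 1) {
    parallel::mclapply(zs, worker, mc.cores = cfg$workers)
  } else {
    lapply(zs, worker)
  }
  planes <- vector("list", stack$z_count)
  bg_masks <- vector("list", stack$z_count)
  records <- data.frame(plane_index = zs, mbi_i = prop$mbi,
                        mbi_quantile_rank = prop$uq_rank,
                        n_signal_pixels_replaced = NA_integer_,
                        standardization_scale = NA_real_,
                        skipped = prop$skip)
  for (z in zs) {
    if (prop$skip[z]) {
      planes[[z]] <- stack$planes[[z]]
      warnings <- c(warnings, sprintf("plane %d: no tissue pixels; skipped", z))
      next
    }
    planes[[z]] <- results[[z]]$plane
    bg_masks[[z]] <- results[[z]]$mask_grid
    records$n_signal_pixels_replaced[z] <- results[[z]]$n_replaced
    records$standardization_scale[z] <- results[[z]]$scale
  }
  # certified-background rank: every pixel the background fit replaced (MBI
  # cut plus refinement passes) was classified signal, so ranks at or below
  # 1 - replaced fraction are background on that plane; the stack-wide
  # upper-quantile rank is the minimum over planes, keeping the Z-matching
  # anchors out of the signal range even where sub-MBI signal skirts exist
  n_tissue <- vapply(masks, sum, 0L)
  live <- !prop$skip & n_tissue > 0
  if (any(live)) {
    certified <- 1 - records$n_signal_pixels_replaced[live] / n_tissue[live]
    prop$uq_rank <- max(min(prop$uq_rank, certified),
                        cfg$lower_quantile_rank + 1e-3)
  }
  profiles <- build_profiles(planes, masks, prop, cfg)
  list(planes = planes, masks = masks, bg_masks = bg_masks,
       records = records, profiles = profiles, uq_rank = prop$uq_rank,
       skip = prop$skip, warnings = warnings)
}
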