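## Z normalization: harmonize corrected planes across the stack.
##
## Each plane is treated as a separate data sample (Z step size is
## arbitrary and the axial point spread function differs from the lateral
## one).  The sufficient statistic per plane is its quantile profile:
## 10,000 recorded quantiles of the tissue pixels plus the upper-quantile
## rank q* inherited from MBI propagation.  Three modes, all monotone per
## plane:
##   upper_quantile  - multiply so the upper quantile matches the target;
##   contrast_stretch- affine map anchored at the 10th percentile and the
##                     upper quantile;
##   semi_quantile   - full quantile matching below the upper quantile,
##                     linear stretch (UQ, max) -> (target UQ, target max)
##                     above it; the branches meet at the upper quantile.

#' Build per-plane quantile profiles
#'
#' Quantiles are computed over tissue pixels only, on the rank grid
#' k/(Q+1), k = 1..Q, with linear interpolation between order statistics.
#' Skipped planes (no tissue) get `NULL`.
#'
#' @param planes list of corrected real-valued planes.
#' @param masks per-plane logical tissue masks.
#' @param prop result of [propagate_mbi()].
#' @param cfg a [norm_config()].
#' @return list of profiles; each has `plane_index`, `quantiles`, `uq_rank`,
#'   `uq_value`, `lq_value`, `max_value`.
#' @export
build_profiles <- function(planes, masks, prop, cfg) {
  ranks <- quantile_ranks(cfg$quantile_count)
  lapply(seq_along(planes), function(z) {
    if (prop$skip[z]) return(NULL)
    pix <- planes[[z]][masks[[z]]]
    list(plane_index = z,
         quantiles = empirical_quantile(pix, ranks),
         uq_rank = prop$uq_rank,
         uq_value = empirical_quantile(pix, prop$uq_rank),
         lq_value = empirical_quantile(pix, cfg$lower_quantile_rank),
         max_value = max(pix))
  })
}

#' Build the cross-stack matching target
#'
#' Target levels (upper quantile, lower quantile, maximum, and in
#' semi-quantile mode the full quantile vector) are the means over all
#' non-skipped planes' profiles, keeping the stack's global brightness
#' centered.
#'
#' @param profiles list from [build_profiles()].
#' @param mode one of the Z modes.
#' @return list: `mode`, `target_uq`, `target_lq`, `target_max`,
#'   `target_quantiles` (semi-quantile mode only).
#' @export
build_target <- function(profiles, mode) {
  live <- Filter(Negate(is.null), profiles)
  if (length(live) == 0) stop("no planes with a quantile profile")
  tq <- NULL
  if (mode == "semi_quantile") {
    tq <- Reduce(`+`, lapply(live, `[[`, "quantiles")) / length(live)
  }
  list(mode = mode,
       target_uq = mean(vapply(live, `[[`, 0, "uq_value")),
       target_lq = mean(vapply(live, `[[`, 0, "lq_value")),
       target_max = mean(vapply(live, `[[`, 0, "max_value")),
       target_quantiles = tq)
}

#' Upper-quantile Z normalization of one plane
#'
#' Multiplies tissue pixels by `target_uq / uq_value`, shifting the whole
#' intensity histogram so the plane's upper quantile matches the stack-wide
#' target.
#'
#' @param plane corrected plane.
#' @param profile the plane's quantile profile.
#' @param target the [build_target()] result.
#' @param tissue logical tissue mask.
#' @return list: `plane`, `skipped` (TRUE when uq_value is 0).
#' @export
apply_upper_quantile <- function(plane, profile, target, tissue) {
  if (profile$uq_value <= 0) {
    return(list(plane = plane, skipped = TRUE))
  }
  plane[tissue] <- plane[tissue] * (target$target_uq / profile$uq_value)
  list(plane = plane, skipped = FALSE)
}

#' Contrast-stretch Z normalization of one plane
#'
#' Affine map sending (lower quantile, upper quantile) to the target pair,
#' applied to all tissue pixels (extrapolated outside the anchor interval);
#' negative results are floored at 0. When the two anchors coincide the
#' plane falls back to upper-quantile mode.
#'
#' @inheritParams apply_upper_quantile
#' @return list: `plane`, `fallback` (TRUE when anchors coincide).
#' @export
apply_contrast_stretch <- function(plane, profile, target, tissue) {
  lq <- profile$lq_value; uq <- profile$uq_value
  if (uq <= lq) {
    res <- apply_upper_quantile(plane, profile, target, tissue)
    return(list(plane = res$plane, fallback = TRUE))
  }
  slope <- (target$target_uq - target$target_lq) / (uq - lq)
  plane[tissue] <- pmax(target$target_lq + (plane[tissue] - lq) * slope, 0)
  list(plane = plane, fallback = FALSE)
}

## Monotone piecewise-linear map from a plane's sub-UQ quantiles to the
## target's, with the junction knot (uq_value -> target_uq) appended.
semi_quantile_map <- function(profile, target) {
  nq <- length(profile$quantiles)
  keep <- quantile_ranks(nq) <= profile$uq_rank
  # a stable slope for extrapolating below the lowest knot: fitted over the
  # wide span from the lowest knot to the 10th-percentile knot (adjacent
  # knots can nearly coincide and would give a wild local slope)
  j10 <- min(max(2L, round(0.10 * (nq + 1))), sum(keep))
  xk <- c(profile$quantiles[keep], profile$uq_value)
  yk <- c(target$target_quantiles[keep], target$target_uq)
  dx10 <- xk[j10] - xk[1]
  slope_low <- if (is.finite(dx10) && dx10 > 0) (yk[j10] - yk[1]) / dx10 else 1
  drop <- xk >= profile$uq_value & seq_along(xk) < length(xk)
  xk <- xk[!drop]; yk <- yk[!drop]
  # collapse duplicated knot positions, keeping the last (largest) image so
  # flat donor stretches map to a single well-defined level
  last <- !duplicated(xk, fromLast = TRUE)
  xk <- xk[last]; yk <- yk[last]
  if (length(xk) == 1) {
    function(v) rep(yk, length(v))
  } else {
    # below the lowest recorded quantile the map continues with the stable
    # lower-tail slope (clamping there would crush the lower noise tail);
    # results are floored at 0
    function(v) {
      out <- stats::approx(xk, yk, xout = v, rule = 2)$y
      lowv <- v < xk[1]
      if (any(lowv)) out[lowv] <- yk[1] + (v[lowv] - xk[1]) * slope_low
      pmax(out, 0)
    }
  }
}

#' Semi-quantile Z normalization of one plane
#'
#' Tissue pixels at or below the plane's upper quantile are mapped by
#' monotone piecewise-linear interpolation of the plane's recorded quantiles
#' onto the target quantiles (full histogram matching of the background);
#' pixels above it -- assumed to be signal -- are mapped by the linear
#' stretch of slope `target_uq / uq_value` continued from the upper
#' quantile: `v -> target_uq + (v - uq_value) * target_uq / uq_value`. Both
#' branches send the upper quantile to the target upper quantile, so the
#' composite map is continuous and monotone, and the above-UQ slope is the
#' plane's overall brightness ratio -- bounded even for planes whose maximum
#' barely exceeds the upper quantile (planes without signal), where
#' anchoring on the plane maximum would wildly amplify the background's
#' noise tail.
#'
#' @inheritParams apply_upper_quantile
#' @return list: `plane`.
#' @export
apply_semi_quantile <- function(plane, profile, target, tissue) {
  v <- plane[tissue]
  low <- v <= profile$uq_value
  out <- v
  out[low] <- semi_quantile_map(profile, target)(v[low])
  if (any(!low)) {
    slope <- if (profile$uq_value > 0) {
      target$target_uq / profile$uq_value
    } else {
      1
    }
    out[!low] <- target$target_uq + (v[!low] - profile$uq_value) * slope
  }
  plane[tissue] <- out
  list(plane = plane)
}

#' Z-normalize a corrected stack
#'
#' Applies the configured mode plane-by-plane against one shared target
#' built from all non-skipped profiles. Mode `"none"` returns the input
#' (XY-only correction). A single-plane stack is its own target, so every
#' mode is the identity there.
#'
#' @param planes list of corrected real-valued planes (from
#'   [normalize_stack_xy()]).
#' @param profiles per-plane profiles ([build_profiles()]).
#' @param masks per-plane tissue masks.
#' @param cfg a [norm_config()].
#' @return list: `planes`, `target`, `warnings`.
#' @export
normalize_stack_z <- function(planes, profiles, masks, cfg) {
  if (cfg$z_mode == "none") {
    return(list(planes = planes, target = NULL, warnings = character(0)))
  }
  target <- build_target(profiles, cfg$z_mode)
  warnings <- character(0)
  out <- planes
  for (z in seq_along(planes)) {
    pr <- profiles[[z]]
    if (is.null(pr)) next
    res <- switch(cfg$z_mode,
      upper_quantile = apply_upper_quantile(planes[[z]], pr, target, masks[[z]]),
      contrast_stretch = apply_contrast_stretch(planes[[z]], pr, target, masks[[z]]),
      semi_quantile = apply_semi_quantile(planes[[z]], pr, target, masks[[z]]))
    out[[z]] <- res$plane
    if (isTRUE(res$skipped)) {
      warnings <- c(warnings, sprintf("plane %d: zero upper quantile; skipped", z))
    }
    if (isTRUE(res$fallback)) {
      warnings <- c(warnings,
                    sprintf("plane %d: degenerate anchors; upper-quantile fallback", z))
    }
  }
  list(planes = out, target = target, warnings = warnings)
}
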