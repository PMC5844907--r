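## End-to-end runs: read -> tissue detect -> XY normalize -> Z normalize ->
## write, with a manifest sufficient to re-run bit-identically; plus the
## sphere-validation harness that scores restoration quality on the phantom.

#' Normalize an image stack in memory
#'
#' The full pipeline on an in-memory stack: tissue detection (if enabled),
#' XY normalization, Z normalization. Deterministic for a fixed seed and
#' any worker count.
#'
#' @param stack an `image_stack`.
#' @param cfg a [norm_config()].
#' @return list: `stack` (corrected, real-valued planes; quantize on
#'   write), `masks`, `records`, `profiles`, `target`, `uq_rank`,
#'   `warnings`.
#' @export
normalize_stack <- function(stack, cfg) {
  xy <- normalize_stack_xy(stack, cfg)
  z <- normalize_stack_z(xy$planes, xy$profiles, xy$masks, cfg)
  out <- stack
  out$planes <- z$planes
  list(stack = out, masks = xy$masks, records = xy$records,
       profiles = xy$profiles, target = z$target, uq_rank = xy$uq_rank,
       warnings = c(xy$warnings, z$warnings))
}

#' Normalize a TIFF series on disk
#'
#' Reads the series, runs [normalize_stack()], and writes the corrected
#' series, the support (tissue-mask) images in a distinct subfolder, the
#' per-plane quantile log, the per-plane record table, and a JSON run
#' manifest (config snapshot, version, seed, timings, warnings).
#'
#' @param input_dir directory of the input TIFF series.
#' @param output_dir output directory (created).
#' @param cfg a [norm_config()].
#' @param pattern input filename glob.
#' @return invisibly, the manifest list.
#' @export
run_normalize <- function(input_dir, output_dir, cfg, pattern = "*.tif*") {
  t0 <- Sys.time()
  stack <- read_stack(input_dir, pattern)
  res <- normalize_stack(stack, cfg)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(res$stack, output_dir, suffix = "_N3D")
  write_support_masks(res$masks, file.path(output_dir, "support"),
                      source_names = stack$source_names)
  write_quantile_log(res$profiles, file.path(output_dir, "quantile_log.txt"),
                     source_names = stack$source_names)
  utils::write.table(res$records, file.path(output_dir, "plane_records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    tool = "intensify3d",
    version = as.character(utils::packageVersion("intensify3d")),
    config = cfg[setdiff(names(cfg), "tissue")],
    tissue = unclass(cfg$tissue),
    seed = cfg$seed,
    z_count = stack$z_count,
    uq_rank = res$uq_rank,
    warnings = res$warnings,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (w in res$warnings) message("note: ", w)
  invisible(manifest)
}

default_phantom_config <- function(mbi, ref, spec, z_mode, seed,
                                   workers = 1L) {
  # SFS: twice the largest sphere diameter (diameter ~ 6 sigma after PSF)
  sfs <- coerce_odd(ceiling(2 * 6 * max(spec$sphere_sigma_range)))
  norm_config(mbi = mbi, sfs = sfs, reference_plane_index = ref,
              z_mode = z_mode, tissue = tissue_config("none"),
              seed = seed, workers = workers)
}

#' Emulate the user's MBI choice on a phantom stack
#'
#' The method is user-guided: the maximum background intensity is picked by
#' the user as the highest pixel value of the background on a
#' representative (middle) plane. On the phantom that value is known
#' analytically -- the background level times the distortion factor at the
#' plane's brightest point, plus the upper noise excursion (4 sigma, also
#' attenuated) -- so the harness supplies exactly what a competent user
#' reading the plane's histogram would.
#'
#' @param spec the [phantom_spec()].
#' @param field the applied distortion field (3D array).
#' @param ref reference plane index.
#' @return the MBI in ADU.
#' @export
phantom_user_mbi <- function(spec, field, ref) {
  gmax <- max(field[, , ref])
  (spec$background_level + 4 * spec$noise_sigma) * gmax
}

#' Run the sphere-restoration validation for one distortion
#'
#' Generates (or reuses) the undistorted phantom, distorts it with one
#' field, corrects the distorted stack with the full pipeline, and scores
#' distorted vs. corrected against the undistorted stack: detection rates
#' (threshold = Otsu on the undistorted stack, applied after min-max
#' matching to its range), relative MAE of true-positive sphere statistics,
#' and min-max-matched histogram distance.
#'
#' @param kind distortion kind (see [evaluate_field()]).
#' @param spec a [phantom_spec()].
#' @param z_mode Z-normalization mode for the correction (default
#'   semi-quantile, the mode that best restores the background histogram).
#' @param phantom optional precomputed [generate_phantom()] result.
#' @param reference optional precomputed reference detection (list with
#'   `det`, `cmp`, `threshold`, `max_dist`) from a previous call, to avoid
#'   re-detecting the undistorted stack.
#' @param workers worker count for the per-plane loop.
#' @return list of scores; see Details in the package vignette.
#' @export
sphere_validation <- function(kind, spec = phantom_spec(),
                              z_mode = "semi_quantile",
                              phantom = NULL, reference = NULL,
                              workers = 1L) {
  if (is.null(phantom)) phantom <- generate_phantom(spec)
  if (is.null(reference)) {
    thr <- otsu_threshold(phantom$stack)
    max_dist <- 2 * mean(spec$sphere_sigma_range)
    ref_det <- count_objects_3d(phantom$stack, thr)
    ref_cmp <- match_to_truth(ref_det, phantom$truth, max_dist)
    reference <- list(det = ref_det, cmp = ref_cmp, threshold = thr,
                      max_dist = max_dist)
  }
  dist <- apply_distortion(phantom, spec, kind)
  ref_plane <- max(1L, spec$dims[3] %/% 2L)
  cfg <- default_phantom_config(phantom_user_mbi(spec, dist$field, ref_plane),
                                ref_plane, spec, z_mode, spec$seed,
                                workers = workers)
  corr <- normalize_stack(dist$stack, cfg)
  ref_arr <- stack_to_array(phantom$stack)
  score_stack <- function(stk) {
    arr <- stack_to_array(stk)
    # min-max match to the undistorted range before applying the shared
    # operating point, as when all images are displayed at the same levels
    r_ref <- range(ref_arr); r <- range(arr)
    arr_m <- (arr - r[1]) / (r[2] - r[1]) * (r_ref[2] - r_ref[1]) + r_ref[1]
    det <- count_objects_3d(arr_m, reference$threshold)
    cmp <- match_to_truth(det, phantom$truth, reference$max_dist)
    mae <- mae_vs_reference(cmp, reference$cmp, det, reference$det)
    list(det = det, cmp = cmp, mae = mae,
         emd = histogram_distance(arr, ref_arr))
  }
  list(kind = kind,
       reference = reference,
       distorted = score_stack(dist$stack),
       corrected = score_stack(corr$stack),
       config = cfg)
}
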