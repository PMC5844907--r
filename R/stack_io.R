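## TIFF series I/O.  A stack is a Z-ordered folder of single-channel planes,
## one file per plane, ordered lexicographically (zero-padded names required).

#' Construct an image stack
#'
#' An `image_stack` is an ordered list of same-shaped 2D intensity matrices
#' (rows = Y, columns = X) with bit-depth metadata. It is the unit of
#' normalization.
#'
#' @param planes list of numeric matrices, all the same dimension.
#' @param bit_depth 8 or 16.
#' @param source_names character vector of plane identifiers (one per plane);
#'   defaults to zero-padded `"plane_0001"` style names.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(planes, bit_depth = 16,
                        source_names = sprintf("plane_%04d", seq_along(planes))) {
  stopifnot(is.list(planes), length(planes) >= 1)
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  d <- dim(planes[[1]])
  for (p in planes) {
    if (!identical(dim(p), d)) stop("inconsistent stack: plane shapes differ")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 2^bit_depth - 1)) {
      stop("plane values must be finite, >= 0 and <= 2^bit_depth - 1")
    }
  }
  if (length(source_names) != length(planes)) {
    stop("source_names must match number of planes")
  }
  structure(
    list(planes = planes, height = d[1], width = d[2],
         z_count = length(planes), bit_depth = as.integer(bit_depth),
         source_names = source_names),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d planes of %d x %d, %d-bit\n",
              x$z_count, x$height, x$width, x$bit_depth))
  invisible(x)
}

#' Convert an image stack to a 3D array
#'
#' @param stack an `image_stack`.
#' @return numeric array of dimension (height, width, z_count).
#' @export
stack_to_array <- function(stack) {
  arr <- array(0, dim = c(stack$height, stack$width, stack$z_count))
  for (z in seq_len(stack$z_count)) arr[, , z] <- stack$planes[[z]]
  arr
}

#' Convert a 3D array to an image stack
#'
#' @param arr numeric array (height, width, z).
#' @param bit_depth 8 or 16.
#' @param source_names optional plane names.
#' @return an `image_stack`.
#' @export
array_to_stack <- function(arr, bit_depth = 16, source_names = NULL) {
  planes <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z])
  if (is.null(source_names)) {
    source_names <- sprintf("plane_%04d", seq_along(planes))
  }
  image_stack(planes, bit_depth = bit_depth, source_names = source_names)
}

infer_bit_depth <- function(info) {
  b <- attr(info, "bits.per.sample")
  if (is.null(b)) b <- 16L
  if (!b %in% c(8L, 16L)) stop("unsupported bit depth: ", b)
  as.integer(b)
}

read_plane_file <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = TRUE)
  if (!is.list(img)) img <- list(img)
  lapply(img, function(pg) {
    if (length(dim(pg)) == 3) {
      if (dim(pg)[3] > 1) stop("not single-channel: ", path)
      pg <- pg[, , 1]
    }
    matrix(as.numeric(pg), nrow(pg), ncol(pg))  # drop TIFF tag attributes
  })
}

#' Read a Z-ordered TIFF series
#'
#' Reads all grayscale TIFFs in `directory` matching `pattern`, in
#' lexicographic filename order (zero-padded names are the expected
#' convention). A single multi-page TIFF is also accepted, its pages taken as
#' planes.
#'
#' @param directory path containing the series.
#' @param pattern filename glob, default `"*.tif*"`.
#' @return an `image_stack`; bit depth is inferred from the file dtype.
#' @export
read_stack <- function(directory, pattern = "*.tif*") {
  files <- sort(list.files(directory, pattern = utils::glob2rx(pattern),
                           full.names = TRUE))
  if (length(files) == 0) stop("no input images in ", directory)
  first <- tiff::readTIFF(files[1], as.is = TRUE, info = TRUE)
  bit_depth <- infer_bit_depth(first)
  planes <- list()
  names_out <- character(0)
  for (f in files) {
    pages <- read_plane_file(f)
    base <- sub("\\.tiff?$", "", basename(f), ignore.case = TRUE)
    nm <- if (length(pages) == 1) base else sprintf("%s_p%04d", base, seq_along(pages))
    planes <- c(planes, pages)
    names_out <- c(names_out, nm)
  }
  d <- dim(planes[[1]])
  for (p in planes) {
    if (!identical(dim(p), d)) stop("inconsistent stack: plane shapes differ")
  }
  image_stack(planes, bit_depth = bit_depth, source_names = names_out)
}

#' Write an image stack as a TIFF series
#'
#' One TIFF per plane; values are rounded half-up, clipped to the bit-depth
#' range, and stored at the stack's bit depth (never silently promoted to
#' float). Integer-valued stacks round-trip bit-exactly.
#'
#' @param stack an `image_stack` (planes may be real-valued).
#' @param directory output directory (created if needed).
#' @param suffix tag appended to each source name, default `"_N3D"`.
#' @return invisibly, the character vector of written paths.
#' @export
write_stack <- function(stack, directory, suffix = "_N3D") {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  hi <- 2^stack$bit_depth - 1
  paths <- character(stack$z_count)
  for (z in seq_len(stack$z_count)) {
    q <- quantize_adu(stack$planes[[z]], stack$bit_depth)
    paths[z] <- file.path(directory,
                          paste0(stack$source_names[z], suffix, ".tif"))
    tiff::writeTIFF(q / hi, paths[z],
                    bits.per.sample = stack$bit_depth)
  }
  invisible(paths)
}

#' Write per-plane tissue masks as support images
#'
#' Masks are written as 8-bit TIFFs (tissue = 255, medium = 0) into a
#' subfolder distinct from the normalized output images, mirroring the
#' support-image folder of the original tool.
#'
#' @param masks list of logical matrices, index-aligned with a stack.
#' @param directory output directory for the support images.
#' @param source_names optional plane names, defaults to zero-padded indices.
#' @return invisibly, written paths.
#' @export
write_support_masks <- function(masks, directory,
                                source_names = sprintf("plane_%04d", seq_along(masks))) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(masks))
  for (z in seq_along(masks)) {
    m <- masks[[z]]
    stopifnot(is.logical(m) || all(m %in% c(0, 1)))
    paths[z] <- file.path(directory, paste0(source_names[z], "_support.tif"))
    tiff::writeTIFF((m * 255) / 255, paths[z], bits.per.sample = 8L)
  }
  invisible(paths)
}

#' Read support masks back as logical matrices
#'
#' @param directory folder of support images written by
#'   [write_support_masks()].
#' @return list of logical matrices (threshold at 128).
#' @export
read_support_masks <- function(directory) {
  files <- sort(list.files(directory, pattern = "_support\\.tif$",
                           full.names = TRUE))
  lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE) >= 128)
}

#' Write the per-plane quantile log
#'
#' A plain-text table with one row per plane: plane name, the recorded
#' quantiles, the plane's propagated maximum background intensity (MBI) and
#' its quantile rank. Logging these sufficient statistics (rather than whole
#' planes) is what keeps Z normalization memory-light.
#'
#' @param profiles list of quantile profiles (see [build_profiles()]).
#' @param path output file path.
#' @param source_names plane names.
#' @return invisibly, `path`.
#' @export
write_quantile_log <- function(profiles, path,
                               source_names = sprintf("plane_%04d", seq_along(profiles))) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (is.null(p)) {
      writeLines(paste(source_names[i], "SKIPPED", sep = "\t"), con)
    } else {
      writeLines(paste(c(source_names[i],
                         formatC(p$uq_value, format = "g", digits = 10),
                         formatC(p$uq_rank, format = "g", digits = 10),
                         formatC(p$quantiles, format = "g", digits = 8)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
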