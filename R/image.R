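#' Construct a grayscale image object
#'
#' @param pixels numeric matrix of intensities, rows top-to-bottom.
#' @param source_depth original bit depth (e.g. 8 or 16) when known, else `NA`.
#' @return an object of class `"grayscale_image"`.
#' @export
grayscale_image <- function(pixels, source_depth = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("invalid image: zero-size pixel array", call. = FALSE)
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("invalid image: pixel values must be finite and nonnegative",
         call. = FALSE)
  }
  structure(list(pixels = pixels, source_depth = as.integer(source_depth)),
            class = "grayscale_image")
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("Grayscale image: %d x %d, values in [%.4g, %.4g]%s\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels),
              if (is.na(x$source_depth)) ""
              else sprintf(", %d-bit source", x$source_depth)))
  invisible(x)
}

#' @export
dim.grayscale_image <- function(x) dim(x$pixels)

#' Load a grayscale image from PNG, TIFF or JPEG
#'
#' Multi-channel (RGB/RGBA) inputs are collapsed to a single luminance
#' channel with the Rec. 709 weights (0.2126, 0.7152, 0.0722); an alpha
#' channel is dropped. Decoded intensities are on the `[0, 1]` scale.
#' JPEG decoding requires the EBImage package.
#'
#' @param path path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return a `"grayscale_image"` with values in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = read_jpeg_ebimage(path),
    stop(sprintf("unsupported image format '%s' (expected png/tiff/jpeg)",
                 ext), call. = FALSE)
  )
  depth <- guess_bit_depth(arr)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  grayscale_image(as.matrix(arr), source_depth = depth)
}

read_jpeg_ebimage <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("JPEG input requires the EBImage package", call. = FALSE)
  }
  img <- EBImage::readImage(path)
  a <- as.array(img)
  # EBImage stores images x-by-y; transpose to row-major (rows = image rows)
  if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
}

guess_bit_depth <- function(arr) {
  mx <- max(arr)
  if (mx <= 1) 8L else if (mx <= 255) 8L else 16L
}

#' Normalize integer intensities to double precision in [0, 1]
#'
#' Divides integer-valued pixels by `2^depth - 1`. Input that is already on
#' the `[0, 1]` scale is returned unchanged, so the operation is idempotent.
#'
#' @param image a `"grayscale_image"`.
#' @param depth bit depth used for the scaling; defaults to the image's
#'   recorded `source_depth`, or to the smallest of 8/16 bits that covers the
#'   observed maximum.
#' @return a `"grayscale_image"` with values in `[0, 1]`.
#' @export
to_double <- function(image, depth = NULL) {
  stopifnot(inherits(image, "grayscale_image"))
  px <- image$pixels
  if (max(px) <= 1) {
    return(image)
  }
  if (is.null(depth)) {
    depth <- if (!is.na(image$source_depth)) image$source_depth
             else if (max(px) <= 255) 8L else 16L
  }
  full <- 2^depth - 1
  if (max(px) > full) {
    stop(sprintf("pixel values exceed %d-bit range", depth), call. = FALSE)
  }
  grayscale_image(px / full, source_depth = image$source_depth)
}

#' Flatten an image into a 1D signal by row concatenation
#'
#' Rows are appended top-to-bottom, each read left-to-right, so element
#' `r * W + c + 1` of the signal is the pixel at (row r, column c),
#' zero-based. An H x W image yields a signal of length `T = H * W`.
#'
#' @param image a `"grayscale_image"`.
#' @return numeric vector of length `nrow * ncol`.
#' @export
concatenate_rows <- function(image) {
  stopifnot(inherits(image, "grayscale_image"))
  as.vector(t(image$pixels))
}

#' Extract the generalized Hurst feature vector from an image
#'
#' The full feature-extraction pipeline: normalize to `[0, 1]`
#' ([to_double()]), flatten by row concatenation ([concatenate_rows()]),
#' tabulate structure functions K_q(d) and fit the Hurst spectrum
#' ([estimate_hurst()]). With the defaults (q = 1..6, d = 1..19) the result
#' is the six-component feature vector H(1), ..., H(6).
#'
#' @param image a `"grayscale_image"`, or a file path accepted by
#'   [load_image()].
#' @inheritParams structure_function_table
#' @return a `"hurst_spectrum"`; its `H` element is the feature vector.
#' @export
extract_features <- function(image, q_values = 1:6, d_max = 19L) {
  if (is.character(image)) image <- load_image(image)
  stopifnot(inherits(image, "grayscale_image"))
  signal <- concatenate_rows(to_double(image))
  if (length(signal) < d_max + 2L) {
    stop(sprintf(
      "image too small: row concatenation gives %d samples, need >= %d for d_max = %d",
      length(signal), d_max + 2L, d_max), call. = FALSE)
  }
  hurst_spectrum(signal, q_values = q_values, d_max = d_max)
}

#' Extract feature vectors from a batch of image files
#'
#' Images that fail to load or process are skipped with a warning; the run
#' continues. An error is raised only if every image fails.
#'
#' @param paths character vector of image file paths.
#' @param labels optional vector of class labels (+1 / -1), recycled checked
#'   against `paths`.
#' @inheritParams structure_function_table
#' @return data frame with columns `image_id`, `H1`, ..., and `label` when
#'   labels were supplied.
#' @export
extract_features_batch <- function(paths, q_values = 1:6, d_max = 19L,
                                   labels = NULL) {
  if (length(paths) == 0L) stop("no input images", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(paths)) {
    stop("labels must match paths in length", call. = FALSE)
  }
  rows <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    h <- tryCatch(extract_features(paths[i], q_values, d_max)$H,
                  error = function(e) {
                    warning(sprintf("skipping %s: %s",
                                    paths[i], conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(h)) {
      row <- as.data.frame(as.list(h))
      names(row) <- paste0("H", seq_along(q_values))
      row <- cbind(data.frame(image_id = basename(paths[i]),
                              stringsAsFactors = FALSE), row)
      if (!is.null(labels)) row$label <- labels[i]
      rows[[i]] <- row
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("feature extraction failed for every input image", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
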