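#' Core raster conventions
#'
#' Images are plain numeric arrays of dimension H x W x 3 with intensities in
#' \[0, 255\] (row-major view: first index is the image row, origin top-left).
#' Grayscale planes are H x W matrices on the same scale; binary masks are
#' H x W logical matrices aligned to their source image.
#'
#' @name raster-conventions
NULL

# ---- conversion between the package convention and EBImage ----

# H x W x 3 [0,255] -> EBImage Image (x, y, c) in [0,1]
as_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

from_ebimage <- function(eb) {
  d <- dim(eb)
  a <- as.numeric(eb)
  if (length(d) == 2L) {
    a <- array(rep(a, 3L), dim = c(d[1L], d[2L], 3L))
  } else if (d[3L] > 3L) {
    a <- array(a, dim = d)[, , 1:3, drop = FALSE]
  } else {
    a <- array(a, dim = d)
  }
  aperm(a, c(2L, 1L, 3L)) * 255
}

validate_rgb_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(arg, " must be an H x W x 3 array", call. = FALSE)
  if (any(dim(img)[1:2] < 1L))
    stop(arg, " has zero size", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(arg, " intensities must be in [0, 255]", call. = FALSE)
  invisible(img)
}

validate_mask <- function(mask, img = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(arg, " must be a logical H x W matrix", call. = FALSE)
  if (!is.null(img) && !identical(dim(mask), dim(img)[1:2]))
    stop(arg, " dimensions do not match its source image", call. = FALSE)
  invisible(mask)
}

#' Load an RGB image
#'
#' Reads a JPEG/PNG/TIFF file into the package's H x W x 3 integer raster
#' convention. Grayscale inputs are replicated to three channels; an alpha
#' channel is dropped.
#'
#' @param path Path to an image file.
#' @return Numeric H x W x 3 array with intensities in \[0, 255\].
#' @export
load_rgb_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  eb <- tryCatch(EBImage::readImage(path),
                 error = function(e) stop("cannot read image: ", path, " (",
                                          conditionMessage(e), ")", call. = FALSE))
  if (length(dim(eb)) == 3L && dim(eb)[3L] > 3L)
    eb <- eb[, , 1:3]
  img <- round(from_ebimage(eb))
  img <- clamp(img, 0, 255)
  if (any(dim(img)[1:2] < 1L)) stop("zero-size image: ", path, call. = FALSE)
  img
}

#' Write an RGB image or binary mask as PNG
#'
#' Masks are written as 0/255 grayscale PNG so that round trips are bit-exact.
#'
#' @param img H x W x 3 array in \[0,255\], or for `write_mask_png` a logical
#'   H x W matrix.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_image_png <- function(img, path) {
  validate_rgb_image(img)
  EBImage::writeImage(as_ebimage(clamp(round(img), 0, 255)), path, type = "png")
  invisible(path)
}

#' @rdname write_image_png
#' @param mask Logical H x W matrix.
#' @export
write_mask_png <- function(mask, path) {
  validate_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path, type = "png")
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  eb <- EBImage::readImage(path)
  if (length(dim(eb)) == 3L) eb <- eb[, , 1L]
  t(EBImage::imageData(eb)) > 0.5
}

# ---- per-sample result record ----

#' Construct a per-image quantification record
#'
#' @param image_id Image identifier (usually the file stem).
#' @param marker Marker label (e.g. "K10"), or `NA`.
#' @param rotation_deg Applied rotation, degrees.
#' @param tissue_px Tissue area in pixels (after crop).
#' @param ap_percent Average-proportion statistic, percent.
#' @param is_positive Gate decision.
#' @param k_clusters Number of k-means clusters used (0 for negatives).
#' @param dab_percent Percent of tissue area occupied by DAB (0 for negatives).
#' @return A `sample_result` list.
#' @export
sample_result <- function(image_id, marker = NA_character_, rotation_deg = 0,
                          tissue_px = 0L, ap_percent = 0, is_positive = FALSE,
                          k_clusters = 0L, dab_percent = 0) {
  if (!is_positive && (dab_percent != 0 || k_clusters != 0L))
    stop("negative samples must report dab_percent = 0 and k_clusters = 0",
         call. = FALSE)
  if (dab_percent < 0 || dab_percent > 100)
    stop("dab_percent must be in [0, 100]", call. = FALSE)
  structure(list(image_id = as.character(image_id),
                 marker = as.character(marker),
                 rotation_deg = as.numeric(rotation_deg),
                 tissue_px = as.integer(tissue_px),
                 ap_percent = as.numeric(ap_percent),
                 is_positive = isTRUE(is_positive),
                 k_clusters = as.integer(k_clusters),
                 dab_percent = as.numeric(dab_percent)),
            class = "sample_result")
}

report_columns <- c("image_id", "marker", "rotation_deg", "tissue_px",
                    "ap_percent", "is_positive", "k_clusters", "dab_percent")

#' @export
as.data.frame.sample_result <- function(x, ...) {
  as.data.frame(unclass(x)[report_columns], stringsAsFactors = FALSE)
}

#' Write / read the batch CSV report
#'
#' One header row plus one row per sample; columns are exactly
#' `image_id, marker, rotation_deg, tissue_px, ap_percent, is_positive,
#' k_clusters, dab_percent` (UTF-8, comma separator, '.' decimal).
#'
#' @param results List of [sample_result()] records (possibly empty), or a
#'   data frame with the report columns.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.data.frame(results)) {
    df <- results[, report_columns]
  } else if (length(results) == 0L) {
    df <- as.data.frame(stats::setNames(
      lapply(report_columns, function(x) character(0)), report_columns))
  } else {
    df <- do.call(rbind, lapply(results, as.data.frame))
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write report: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(image_id = "character", marker = "character"))
}
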