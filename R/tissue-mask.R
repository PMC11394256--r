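#' Tissue masking from the hematoxylin channel
#'
#' Stained tissue absorbs light while the slide background stays near-white,
#' so tissue pixels are the dark class of an Otsu split on the hematoxylin
#' grayscale rendering. Morphological opening/closing with a disk structuring
#' element, hole filling, and largest-component selection then clean the
#' binary mask.
#'
#' @name tissue-masking
NULL

#' Morphology parameters for tissue masking
#'
#' @param se_radius Disk structuring-element radius in pixels (default 15).
#' @param fill_holes Fill interior holes (default `TRUE`).
#' @param min_tissue_fraction Minimum tissue fraction of the frame below which
#'   a "no tissue detected" error is raised (default 0.005).
#' @return A `morphology_params` list.
#' @export
morphology_params <- function(se_radius = 15L, fill_holes = TRUE,
                              min_tissue_fraction = 0.005) {
  if (se_radius < 1L) stop("se_radius must be >= 1", call. = FALSE)
  structure(list(se_shape = "disk", se_radius = as.integer(se_radius),
                 fill_holes = isTRUE(fill_holes),
                 min_tissue_fraction = min_tissue_fraction),
            class = "morphology_params")
}

#' Otsu threshold over the 256-bin intensity histogram
#'
#' Maximizes the between-class variance `w0 * w1 * (mu0 - mu1)^2` over all
#' splits of the 0..255 histogram (intensities are binned by rounding). Ties
#' are broken by averaging all maximizing split points, so a two-level
#' histogram thresholds midway between the levels. The dark class
#' (intensities `<= threshold`) is the foreground (tissue).
#'
#' @param gray H x W matrix of intensities in \[0,255\].
#' @return Threshold intensity (numeric scalar, possibly half-integer).
#' @export
otsu_threshold <- function(gray) {
  v <- round(as.numeric(gray))
  if (length(v) == 0L) stop("empty image", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct values",
         call. = FALSE)
  n <- length(v)
  levels <- 0:255
  w0 <- cumsum(counts)[1:255] / n
  w1 <- 1 - w0
  m0 <- cumsum(counts * levels)[1:255] / pmax(cumsum(counts)[1:255], 1L)
  total <- sum(counts * levels)
  m1 <- (total - cumsum(counts * levels)[1:255]) / pmax(n - cumsum(counts)[1:255], 1L)
  sigma_b <- w0 * w1 * (m0 - m1)^2
  best <- which(sigma_b == max(sigma_b)) - 1L  # split t: class0 = {<= t}
  mean(best)
}

# ---- connected components and hole filling (C++ flood fill) ----

#' Label connected components of a binary mask
#'
#' @param mask Logical H x W matrix.
#' @param connectivity 8 (default, foreground convention) or 4.
#' @return Integer H x W matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  validate_mask(mask)
  cpp_label(mask, as.integer(connectivity))
}

#' @describeIn label_components Keep only the largest component (pixel count;
#'   ties broken by scan order).
#' @export
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' @describeIn label_components Fill holes: background regions (4-connected)
#'   not connected to the frame border become foreground.
#' @export
fill_holes <- function(mask) {
  validate_mask(mask)
  bg <- cpp_label(!mask, 4L)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border <- border[border > 0L]
  hole <- bg > 0L & !matrix(bg %in% border, nrow(mask), ncol(mask))
  mask | hole
}

# disc structuring element of the given radius as an EBImage brush
disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# remove light specks inside the tissue (closing), then dark specks in the
# background (opening); the smoothing pass used twice by make_tissue_mask
close_open <- function(mask, brush) {
  eb <- EBImage::Image(t(mask) * 1)
  eb <- EBImage::opening(EBImage::closing(eb, brush), brush)
  t(EBImage::imageData(eb)) > 0.5
}

#' Build the tissue mask from the hematoxylin grayscale channel
#'
#' Sequence: (1) Otsu binarization (dark = tissue); (2) removal of light
#' specks/pinholes inside the tissue (morphological closing of the tissue
#' foreground, the "opening" of the background-polarity mask) with a disk SE;
#' (3) removal of dark specks in the background (opening of the foreground)
#' with the same SE; (4) hole filling; (5) selection of the largest
#' 8-connected component; (6) a second closing/opening/hole-filling pass to
#' smooth the final outline.
#'
#' @param hema_gray H x W hematoxylin grayscale plane in \[0,255\].
#' @param params A [morphology_params()] list.
#' @return Logical H x W tissue mask.
#' @export
make_tissue_mask <- function(hema_gray, params = morphology_params()) {
  thr <- otsu_threshold(hema_gray)
  mask <- hema_gray <= thr
  if (!any(mask)) stop("no tissue detected", call. = FALSE)
  brush <- disk_brush(params$se_radius)
  mask <- close_open(mask, brush)
  if (params$fill_holes) mask <- fill_holes(mask)
  if (!any(mask)) stop("no tissue detected", call. = FALSE)
  mask <- largest_component(mask, 8L)
  mask <- close_open(mask, brush)
  if (params$fill_holes) mask <- fill_holes(mask)
  if (sum(mask) < params$min_tissue_fraction * length(mask))
    stop("no tissue detected", call. = FALSE)
  mask
}
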