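#' Automatic rotation of the tissue strip to horizontal
#'
#' The reconstructed epidermis forms a thin elongated strip. Its orientation
#' is found by rotating the tissue mask over a dense angle grid and, at each
#' angle, computing the boundary intensity distribution: the vector of
#' foreground counts per image row. The peak of this profile is largest
#' exactly when the strip's long axis lies horizontal, so the chosen rotation
#' maximizes the profile maximum (ties go to the smallest angle). This is the
#' mask's Radon projection evaluated by direct rotate-and-sum.
#'
#' @name orientation
NULL

#' Rotation search parameters
#'
#' @param angle_min,angle_max,angle_step Search grid in degrees (defaults
#'   1 to 180 by 0.1, i.e. 1791 angles).
#' @param coarse_to_fine Two-stage search (1 degree pass, then +/- 1 degree
#'   refined at `angle_step`); default `FALSE` — the full grid is the
#'   definition, the coarse path a speed option.
#' @param margin_px Crop margin around the mask bounding box (default 5).
#' @return A `rotation_search_params` list.
#' @export
rotation_search_params <- function(angle_min = 1, angle_max = 180,
                                   angle_step = 0.1, coarse_to_fine = FALSE,
                                   margin_px = 5L) {
  if (angle_min > angle_max) stop("angle_min must be <= angle_max", call. = FALSE)
  if (angle_step <= 0) stop("angle_step must be > 0", call. = FALSE)
  structure(list(angle_min = angle_min, angle_max = angle_max,
                 angle_step = angle_step,
                 coarse_to_fine = isTRUE(coarse_to_fine),
                 margin_px = as.integer(margin_px)),
            class = "rotation_search_params")
}

#' Boundary intensity profile of a rotated mask
#'
#' Rotates the mask by `angle` degrees about its center (nearest-neighbour
#' resampling on a canvas expanded so no pixel is lost; positive angles follow
#' the same direction convention as `EBImage::rotate`) and returns the
#' foreground count in each row. Counts are integers; their sum equals the
#' foreground pixel count of the rotated mask.
#'
#' @param mask Logical H x W matrix, nonempty.
#' @param angle Rotation in degrees.
#' @return Integer vector of per-row foreground counts.
#' @export
boundary_profile <- function(mask, angle) {
  validate_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  cpp_rotation_profile(mask, angle)
}

#' Find the rotation that brings the strip horizontal
#'
#' Evaluates [boundary_profile()] at every grid angle and returns the angle
#' whose profile maximum is largest; ties are broken by the smallest angle.
#'
#' @param mask Logical H x W tissue mask, nonempty.
#' @param params A [rotation_search_params()] list.
#' @return A `rotation_result`: `best_angle` (degrees), `profile_max`,
#'   `profile` (row sums at the best angle), plus the evaluated `angles` and
#'   their `maxima`.
#' @export
find_horizontal_rotation <- function(mask, params = rotation_search_params()) {
  validate_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  grid <- seq(params$angle_min, params$angle_max, by = params$angle_step)
  if (params$coarse_to_fine && params$angle_step < 1) {
    coarse <- seq(ceiling(params$angle_min), floor(params$angle_max), by = 1)
    cm <- cpp_rotation_search(mask, coarse)
    center <- coarse[which.max(cm)]
    fine <- seq(max(params$angle_min, center - 1),
                min(params$angle_max, center + 1), by = params$angle_step)
    angles <- sort(unique(c(coarse, fine)))
  } else {
    angles <- grid
  }
  maxima <- cpp_rotation_search(mask, angles)
  best <- angles[which.max(maxima)]  # which.max: first index, smallest angle
  prof <- cpp_rotation_profile(mask, best)
  structure(list(best_angle = best, profile_max = max(prof), profile = prof,
                 angles = angles, maxima = maxima),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat("rotation search: best angle ", x$best_angle, " deg (profile max ",
      x$profile_max, " px over ", length(x$angles), " angles)\n", sep = "")
  invisible(x)
}

#' Rotate image and mask, then crop to the tissue bounding box
#'
#' The image is rotated with bilinear resampling (white background), the mask
#' with nearest-neighbour; both use the same expanded canvas so they stay
#' aligned. The frame is cropped to the mask's bounding box expanded by
#' `margin` pixels (clamped to the canvas). Any extra planes (e.g. the DAB
#' grayscale/RGB renderings) are rotated and cropped identically.
#'
#' @param image H x W x 3 array in \[0,255\].
#' @param mask Logical H x W matrix aligned to `image`.
#' @param angle Rotation in degrees (from [find_horizontal_rotation()]).
#' @param margin Crop margin in pixels (default 5).
#' @param extras Named list of H x W matrices or H x W x 3 arrays to carry
#'   along (rotated bilinear with white background).
#' @return List with `image`, `mask`, `extras`, `angle`, and the crop
#'   `bbox` (row/col ranges in the rotated canvas).
#' @export
rotate_and_crop <- function(image, mask, angle, margin = 5L, extras = list()) {
  validate_rgb_image(image)
  validate_mask(mask, image)
  if (angle %% 360 != 0) {
    rot_rgb <- function(a) {
      eb <- EBImage::rotate(as_ebimage(a), angle, filter = "bilinear",
                            bg.col = "white")
      clamp(from_ebimage(eb), 0, 255)
    }
    rot_plane <- function(p) {
      eb <- EBImage::rotate(EBImage::Image(t(p) / 255), angle,
                            filter = "bilinear", bg.col = "white")
      clamp(t(EBImage::imageData(eb)) * 255, 0, 255)
    }
    image <- rot_rgb(image)
    ebm <- EBImage::rotate(EBImage::Image(t(mask) * 1), angle,
                           filter = "none", bg.col = 0)
    mask <- t(EBImage::imageData(ebm)) > 0.5
    extras <- lapply(extras, function(x) {
      if (length(dim(x)) == 3L) rot_rgb(x) else rot_plane(x)
    })
  }
  if (!any(mask)) stop("empty mask after rotation", call. = FALSE)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  r0 <- max(1L, rr[1] - margin); r1 <- min(nrow(mask), rr[2] + margin)
  c0 <- max(1L, cc[1] - margin); c1 <- min(ncol(mask), cc[2] + margin)
  crop <- function(x) {
    if (length(dim(x)) == 3L) x[r0:r1, c0:c1, , drop = FALSE]
    else x[r0:r1, c0:c1, drop = FALSE]
  }
  list(image = crop(image), mask = crop(mask), extras = lapply(extras, crop),
       angle = angle, bbox = c(row_min = r0, row_max = r1,
                               col_min = c0, col_max = c1))
}
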