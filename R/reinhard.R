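#' Reinhard color normalization in the l-alpha-beta opponent space
#'
#' Color transfer matches the per-channel mean and standard deviation of a
#' source image to a reference in the decorrelated l-alpha-beta space reached
#' through RGB -> LMS -> log10 -> l-alpha-beta. After the inverse transform a
#' per-channel min-max stretch (MATLAB's `mat2gray`) maps each RGB channel to
#' the full \[0,1\] range before 8-bit re-quantization.
#'
#' @name reinhard
NULL

# Reinhard et al. colour-transfer matrices (RGB in [0,1])
.RGB2LMS <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444),
                   nrow = 3, byrow = TRUE)
.LMS2RGB <- solve(.RGB2LMS)

# log-LMS -> l-alpha-beta
.LMS2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1,
           1, 1, -2,
           1, -1, 0),
         nrow = 3, byrow = TRUE)
.LAB2LMS <- solve(.LMS2LAB)

# epsilon added in LMS space before log10 so that zero RGB stays finite
.LOG_EPS <- 1 / 255

#' @describeIn reinhard Forward transform to l-alpha-beta planes.
#' @param image H x W x 3 array in \[0,255\].
#' @return `rgb_to_lab_opponent`: H x W x 3 array of l, alpha, beta planes.
#' @export
rgb_to_lab_opponent <- function(image) {
  validate_rgb_image(image)
  d <- dim(image)
  v <- matrix(image, ncol = 3L) / 255
  lms <- v %*% t(.RGB2LMS)
  lab <- log10(lms + .LOG_EPS) %*% t(.LMS2LAB)
  array(lab, dim = d)
}

#' @describeIn reinhard Inverse transform back to RGB (\[0,255\], unquantized).
#' @param lab H x W x 3 array of l-alpha-beta planes.
#' @export
lab_opponent_to_rgb <- function(lab) {
  d <- dim(lab)
  lms <- 10^(matrix(lab, ncol = 3L) %*% t(.LAB2LMS)) - .LOG_EPS
  v <- lms %*% t(.LMS2RGB)
  array(clamp(v, 0, 1) * 255, dim = d)
}

#' @describeIn reinhard Per-channel mean and population standard deviation.
#' @return `compute_channel_stats`: a `channel_stats` list with `mean`, `sd`
#'   (population, i.e. divisor n) and a `degenerate` flag per channel.
#' @export
compute_channel_stats <- function(lab) {
  if (length(lab) == 0L) stop("empty image", call. = FALSE)
  m <- matrix(lab, ncol = 3L)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  structure(list(mean = as.numeric(mu), sd = as.numeric(sdev),
                 degenerate = sdev == 0),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat("l-alpha-beta channel statistics\n")
  cat("  mean:", format(x$mean, digits = 5), "\n")
  cat("  sd:  ", format(x$sd, digits = 5),
      if (any(x$degenerate)) " (degenerate channel present)" else "", "\n")
  invisible(x)
}

resolve_reference_stats <- function(ref) {
  if (inherits(ref, "channel_stats")) return(ref)
  if (is.character(ref) && length(ref) == 1L)
    return(compute_channel_stats(rgb_to_lab_opponent(load_rgb_image(ref))))
  if (is.array(ref) && length(dim(ref)) == 3L)
    return(compute_channel_stats(rgb_to_lab_opponent(ref)))
  if (is.list(ref) && all(c("mean", "sd") %in% names(ref)))
    return(structure(list(mean = as.numeric(ref$mean), sd = as.numeric(ref$sd),
                          degenerate = as.numeric(ref$sd) == 0),
                     class = "channel_stats"))
  stop("reference must be channel_stats, an RGB image/array, an image path, ",
       "or a list with mean and sd", call. = FALSE)
}

#' @describeIn reinhard Normalize a source image to reference statistics.
#' @param source H x W x 3 array in \[0,255\].
#' @param ref Reference: a `channel_stats` object, an RGB image array, a path
#'   to an image, or a list with `mean` and `sd`. Defaults to statistics of
#'   the bundled synthetic well-stained reference fixture.
#' @param stretch Apply the per-channel min-max stretch (default `TRUE`).
#' @param quantize Round to 8-bit \[0,255\] integers (default `TRUE`). With
#'   `stretch = FALSE, quantize = FALSE` the raw color-transferred image is
#'   returned for diagnostics.
#' @return `reinhard_normalize`: H x W x 3 array in \[0,255\].
#' @export
reinhard_normalize <- function(source, ref = default_reference_stats(),
                               stretch = TRUE, quantize = TRUE) {
  validate_rgb_image(source, "source")
  ref <- resolve_reference_stats(ref)
  if (any(ref$sd <= 0))
    stop("reference standard deviations must be > 0", call. = FALSE)
  lab <- rgb_to_lab_opponent(source)
  st <- compute_channel_stats(lab)
  d <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  for (ch in 1:3) {
    if (st$degenerate[ch]) {
      warning("degenerate channel ", ch, ": zero variance, shifting only",
              call. = FALSE)
      scale <- 1
    } else {
      scale <- ref$sd[ch] / st$sd[ch]
    }
    m[, ch] <- (m[, ch] - st$mean[ch]) * scale + ref$mean[ch]
  }
  out <- lab_opponent_to_rgb(array(m, dim = d))
  if (stretch) {
    for (ch in 1:3) {
      plane <- out[, , ch]
      rng <- range(plane)
      if (rng[2] > rng[1]) {
        out[, , ch] <- (plane - rng[1]) / (rng[2] - rng[1]) * 255
      } # constant channel: left unchanged (stretch undefined)
    }
  }
  out <- clamp(out, 0, 255)
  if (quantize) out <- round(out)
  out
}

#' Default synthetic reference statistics
#'
#' Channel statistics of a bundled, seeded synthetic well-stained H-DAB strip
#' fixture (generated in code; no external data). Used as the default
#' Reinhard reference so results are reproducible without the original
#' acquisition's reference slide.
#'
#' @return A `channel_stats` object.
#' @export
default_reference_stats <- function() {
  if (is.null(.dq_cache$ref_stats)) {
    fx <- generate_strip_image(fixture_params(
      height = 320L, width = 420L, strip_angle = 0, strip_thickness = 60L,
      dab_fraction = 0.25, seed = 760L))
    .dq_cache$ref_stats <- compute_channel_stats(rgb_to_lab_opponent(fx$image))
  }
  .dq_cache$ref_stats
}
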