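#' Seeded synthetic H-DAB strip fixtures with ground truth
#'
#' Emulates a stained cross-section of reconstructed human epidermis: a thin
#' elongated tissue strip at an arbitrary angle on a near-white slide
#' background, with hematoxylin-blue nuclei and brown DAB patches of known
#' area fraction. Images are composed in optical-density space with the same
#' Beer-Lambert model and H-DAB stain vectors the deconvolution module uses,
#' so every pipeline stage can be tested against exact planted truth.
#'
#' @name synthetic-fixtures
NULL

#' Fixture generator parameters
#'
#' @param height,width Frame size in pixels (default 480 x 640).
#' @param strip_angle Planted strip angle in degrees (same rotation
#'   convention as the orientation module).
#' @param strip_thickness Strip thickness in pixels (default 60).
#' @param strip_length Strip length; `NULL` (default) = longest that fits in
#'   the frame at the given angle, with a small border margin.
#' @param dab_fraction Target DAB fraction of tissue area in \[0,1\].
#' @param nuclei_density Nuclei per 1000 tissue pixels (default 0.8).
#' @param noise_sd Gaussian optical-density noise s.d. (default 0.02).
#' @param artifact_count Dark specks planted outside the strip (default 0).
#' @param seed RNG seed.
#' @param background_mean,background_sd Near-white slide background intensity
#'   (default 250 +/- 3).
#' @param c_h_tissue,c_h_nucleus,c_d Planted hematoxylin concentrations of
#'   cytoplasm/nuclei and DAB concentration of stained patches.
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(height = 480L, width = 640L, strip_angle = 30,
                           strip_thickness = 60L, strip_length = NULL,
                           dab_fraction = 0.2, nuclei_density = 0.8,
                           noise_sd = 0.02, artifact_count = 0L, seed = 1L,
                           background_mean = 250, background_sd = 3,
                           c_h_tissue = 0.35, c_h_nucleus = 0.8, c_d = 0.7) {
  if (dab_fraction < 0 || dab_fraction > 1)
    stop("dab_fraction must be in [0, 1]", call. = FALSE)
  if (strip_thickness < 2L) stop("strip_thickness must be >= 2", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 strip_angle = strip_angle,
                 strip_thickness = as.integer(strip_thickness),
                 strip_length = strip_length, dab_fraction = dab_fraction,
                 nuclei_density = nuclei_density, noise_sd = noise_sd,
                 artifact_count = as.integer(artifact_count),
                 seed = as.integer(seed), background_mean = background_mean,
                 background_sd = background_sd, c_h_tissue = c_h_tissue,
                 c_h_nucleus = c_h_nucleus, c_d = c_d),
            class = "fixture_params")
}

# analytic strip mask: pixel centers within a rotated stadium (rectangle with
# semicircular end caps, as tissue sections taper) about the frame centre
# (no resampling, exact planted truth at any angle)
strip_mask <- function(H, W, angle, thickness, len) {
  theta <- angle * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  cc <- matrix(rep(0:(W - 1), each = H), H, W) - cx   # x
  rr <- matrix(rep(0:(H - 1), W), H, W) - cy          # y
  u <- cos(theta) * cc + sin(theta) * rr              # along strip axis
  v <- -sin(theta) * cc + cos(theta) * rr             # across strip
  r <- thickness / 2
  half_body <- pmax(len / 2 - r, 0)
  du <- pmax(abs(u) - half_body, 0)                   # distance past body end
  du^2 + v^2 <= r^2
}

# longest strip length fitting the frame at this angle (small border margin)
fit_strip_length <- function(H, W, angle, thickness) {
  theta <- angle * pi / 180
  c_ <- abs(cos(theta)); s_ <- abs(sin(theta))
  margin <- 6
  # rotated rectangle half-extent: (L/2)*c + (T/2)*s horizontally, etc.
  lx <- if (c_ > 1e-9) ((W - 1) / 2 - margin - thickness / 2 * s_) / c_ else Inf
  ly <- if (s_ > 1e-9) ((H - 1) / 2 - margin - thickness / 2 * c_) / s_ else Inf
  len <- 2 * min(lx, ly)
  if (len < 4 * thickness)
    stop("infeasible strip geometry for this frame/angle", call. = FALSE)
  len
}

disk_at <- function(H, W, r0, c0, radius) {
  rr <- pmax(1L, floor(r0 - radius)):pmin(H, ceiling(r0 + radius))
  cc <- pmax(1L, floor(c0 - radius)):pmin(W, ceiling(c0 + radius))
  out <- matrix(FALSE, H, W)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  out[rr, cc] <- d2 <= radius^2
  out
}

# plant contiguous DAB blobs covering ~`target_frac` of the tissue area
plant_dab_blobs <- function(tissue, target_frac) {
  H <- nrow(tissue); W <- ncol(tissue)
  dab <- matrix(FALSE, H, W)
  if (target_frac <= 0) return(dab)
  tissue_px <- sum(tissue)
  target <- target_frac * tissue_px
  cand <- which(tissue)
  r_base <- max(4, round(sqrt(0.01 * tissue_px / pi)))
  for (it in seq_len(5000L)) {
    area <- sum(dab)
    if (area >= target) break
    needed <- target - area
    radius <- min(r_base, max(2, ceiling(sqrt(needed / pi))))
    ctr <- cand[sample.int(length(cand), 1L)]
    r0 <- (ctr - 1L) %% H + 1L
    c0 <- (ctr - 1L) %/% H + 1L
    dab <- dab | (disk_at(H, W, r0, c0, radius) & tissue)
  }
  dab
}

#' Generate one synthetic H-DAB strip image with ground truth
#'
#' @param params A [fixture_params()] list.
#' @return List with `image` (H x W x 3, \[0,255\] integers) and `truth`, a
#'   `fixture_truth` list: `tissue_mask`, `dab_mask`, `angle`,
#'   `realized_dab_fraction`, and the planted concentration planes
#'   `c_h`, `c_d`.
#' @export
generate_strip_image <- function(params = fixture_params()) {
  p <- params
  H <- p$height; W <- p$width
  with_seed(p$seed, {
    len <- if (is.null(p$strip_length)) {
      fit_strip_length(H, W, p$strip_angle, p$strip_thickness)
    } else p$strip_length
    tissue <- strip_mask(H, W, p$strip_angle, p$strip_thickness, len)
    if (!any(tissue)) stop("infeasible strip geometry", call. = FALSE)
    tissue_idx <- which(tissue)

    # hematoxylin: cytoplasm base + elliptical nuclei
    c_h <- matrix(0, H, W)
    c_h[tissue_idx] <- p$c_h_tissue
    n_nuc <- round(p$nuclei_density * length(tissue_idx) / 1000)
    if (n_nuc > 0) {
      ctrs <- sample(tissue_idx, n_nuc, replace = TRUE)
      for (ctr in ctrs) {
        r0 <- (ctr - 1L) %% H + 1L
        c0 <- (ctr - 1L) %/% H + 1L
        a <- runif(1, 2.5, 5); b <- runif(1, 1.5, 3.5)
        phi <- runif(1, 0, pi)
        rr <- pmax(1L, floor(r0 - 6)):pmin(H, ceiling(r0 + 6))
        cc <- pmax(1L, floor(c0 - 6)):pmin(W, ceiling(c0 + 6))
        for (ci in cc) {
          dx <- ci - c0; dy <- rr - r0
          u <- cos(phi) * dx + sin(phi) * dy
          v <- -sin(phi) * dx + cos(phi) * dy
          hit <- rr[(u / a)^2 + (v / b)^2 <= 1]
          c_h[hit, ci] <- pmax(c_h[hit, ci],
                               p$c_h_nucleus * runif(1, 0.85, 1.1))
        }
      }
    }
    c_h[!tissue] <- 0

    # DAB patches of the requested area fraction, with mild amplitude jitter
    dab <- plant_dab_blobs(tissue, p$dab_fraction)
    c_d <- matrix(0, H, W)
    if (any(dab)) c_d[dab] <- p$c_d * runif(sum(dab), 0.85, 1.15)

    # compose in OD space; background = near-white neutral slide
    od <- compose_hdab_od(c_h, c_d)
    bg_int <- clamp(rnorm(H * W, p$background_mean, p$background_sd), 200, 255)
    od_bg <- -log10((matrix(bg_int, H, W) + 1) / 256)
    for (ch in 1:3) {
      plane <- od[, , ch]
      plane[!tissue] <- od_bg[!tissue]
      od[, , ch] <- plane
    }

    # dark artifacts outside the strip
    if (p$artifact_count > 0) {
      outside <- which(!tissue)
      for (i in seq_len(p$artifact_count)) {
        ctr <- outside[sample.int(length(outside), 1L)]
        r0 <- (ctr - 1L) %% H + 1L
        c0 <- (ctr - 1L) %/% H + 1L
        spot <- disk_at(H, W, r0, c0, runif(1, 4, 9)) & !tissue
        for (ch in 1:3) {
          plane <- od[, , ch]
          plane[spot] <- 0.8
          od[, , ch] <- plane
        }
      }
    }

    if (p$noise_sd > 0)
      od <- od + array(rnorm(length(od), 0, p$noise_sd), dim = dim(od))

    image <- od_to_rgb(pmax(od, 0))
    truth <- structure(list(
      tissue_mask = tissue, dab_mask = dab, angle = p$strip_angle,
      realized_dab_fraction = sum(dab) / sum(tissue),
      c_h = c_h, c_d = c_d, params = p), class = "fixture_truth")
    list(image = image, truth = truth)
  })
}

#' Generate a labeled positive/negative control set
#'
#' Positives draw their DAB fraction uniformly from \[0.05, 0.5\]; negatives
#' have none. Per-image seeds and strip angles are derived from the master
#' seed, so the set is reproducible.
#'
#' @param n_pos,n_neg Numbers of positive and negative fixtures.
#' @param seed Master seed.
#' @param base_params Template [fixture_params()] for frame size etc.
#' @return List of elements `list(image, truth, label)` with label
#'   "positive"/"negative".
#' @export
generate_labeled_set <- function(n_pos, n_neg, seed = 1L,
                                 base_params = fixture_params()) {
  n <- n_pos + n_neg
  if (n < 1L) stop("need at least one fixture", call. = FALSE)
  meta <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    fractions = c(runif(n_pos, 0.05, 0.5), rep(0, n_neg)),
    angles = runif(n, 5, 175)))
  lapply(seq_len(n), function(i) {
    p <- base_params
    p$seed <- meta$seeds[i]
    p$dab_fraction <- meta$fractions[i]
    p$strip_angle <- meta$angles[i]
    fx <- generate_strip_image(p)
    list(image = fx$image, truth = fx$truth,
         label = if (i <= n_pos) "positive" else "negative")
  })
}

#' Write a fixture set to disk (PNG images plus truth JSON)
#'
#' @param dir Output directory (created if needed).
#' @param n_pos,n_neg,seed See [generate_labeled_set()].
#' @param base_params Template parameters.
#' @return Data frame with file names and labels, invisibly.
#' @export
write_fixture_set <- function(dir, n_pos, n_neg, seed = 1L,
                              base_params = fixture_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set <- generate_labeled_set(n_pos, n_neg, seed, base_params)
  rows <- lapply(seq_along(set), function(i) {
    fx <- set[[i]]
    id <- sprintf("fixture_%03d_%s", i, fx$label)
    write_image_png(fx$image, file.path(dir, paste0(id, ".png")))
    jsonlite::write_json(
      list(label = fx$label, angle = fx$truth$angle,
           dab_fraction = fx$truth$realized_dab_fraction,
           tissue_px = sum(fx$truth$tissue_mask), seed = fx$truth$params$seed),
      file.path(dir, paste0(id, ".json")), auto_unbox = TRUE, digits = NA)
    data.frame(file = paste0(id, ".png"), label = fx$label,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}
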