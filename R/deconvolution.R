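#' Ruifrok-Johnston color deconvolution for H-DAB staining
#'
#' Stains absorb light multiplicatively, so mixing is linear in optical
#' density (OD = -log10 transmittance). Each stain has a unit absorbance
#' direction in (R, G, B) OD space; inverting the 3 x 3 stain matrix unmixes
#' a pixel's OD vector into per-stain concentrations (Beer-Lambert model).
#'
#' @name deconvolution
NULL

#' Default H-DAB stain vectors
#'
#' The published H-DAB absorbance constants of the ImageJ "Colour
#' Deconvolution 2" plugin: hematoxylin (0.650, 0.704, 0.286) and DAB
#' (0.268, 0.570, 0.776). Overridable through the `stains.*` config keys.
#'
#' @return List with unit-normalized `h` and `dab` 3-vectors.
#' @export
hdab_stain_vectors <- function() {
  list(h = c(0.650, 0.704, 0.286), dab = c(0.268, 0.570, 0.776))
}

#' Convert intensities to optical density and back
#'
#' `OD_c = -log10((I_c + 1) / (background + 1))`; the +1 offset avoids
#' log(0) at fully absorbed pixels and makes the mapping exactly invertible.
#'
#' @param image H x W x 3 array in \[0,255\].
#' @param background Background (white) intensity, default 255.
#' @return `rgb_to_od`: H x W x 3 array of optical densities (>= 0 for
#'   intensities at or below `background`).
#' @export
rgb_to_od <- function(image, background = 255) {
  if (background <= 0) stop("background must be > 0", call. = FALSE)
  -log10((image + 1) / (background + 1))
}

#' @rdname rgb_to_od
#' @param od H x W x 3 array of optical densities.
#' @param round Round to integer intensities (default `TRUE`).
#' @export
od_to_rgb <- function(od, background = 255, round = TRUE) {
  v <- (background + 1) * 10^(-od) - 1
  v <- clamp(v, 0, 255)
  if (round) v <- base::round(v)
  v
}

#' Build a 3 x 3 stain matrix from hematoxylin and DAB vectors
#'
#' Rows 1-2 are the unit-normalized inputs; row 3 (the residual channel) is
#' their normalized cross product, completing an invertible basis.
#'
#' @param h_vec,dab_vec Nonzero, non-collinear absorbance 3-vectors.
#' @return A `stain_matrix`: 3 x 3 numeric matrix with rows
#'   `h`, `dab`, `residual`, each of unit Euclidean norm.
#' @export
build_stain_matrix <- function(h_vec = hdab_stain_vectors()$h,
                               dab_vec = hdab_stain_vectors()$dab) {
  if (length(h_vec) != 3L || length(dab_vec) != 3L)
    stop("stain vectors must have length 3", call. = FALSE)
  nh <- sqrt(sum(h_vec^2)); nd <- sqrt(sum(dab_vec^2))
  if (nh == 0 || nd == 0) stop("stain vectors must be nonzero", call. = FALSE)
  h <- h_vec / nh; d <- dab_vec / nd
  cr <- c(h[2] * d[3] - h[3] * d[2],
          h[3] * d[1] - h[1] * d[3],
          h[1] * d[2] - h[2] * d[1])
  ncr <- sqrt(sum(cr^2))
  if (ncr < 1e-8)
    stop("stain vectors are collinear; cannot build a stain matrix",
         call. = FALSE)
  M <- rbind(h = h, dab = d, residual = cr / ncr)
  colnames(M) <- c("R", "G", "B")
  class(M) <- c("stain_matrix", class(M))
  M
}

#' Unmix optical densities into per-stain concentration maps
#'
#' Uses the row-vector convention `od = c %*% M`, so concentrations are
#' `c = od %*% solve(M)`. Raw (possibly slightly negative) concentrations are
#' preserved for diagnostics; single-stain renderings clip at zero.
#'
#' @param od H x W x 3 optical-density array.
#' @param M A [build_stain_matrix()] result.
#' @param background Background intensity for the renderings (default 255).
#' @return A `stain_maps` list: raw concentration planes `h`, `dab`,
#'   `residual`; grayscale renderings `hema_gray`, `dab_gray`
#'   (`(bg+1) * 10^-c - 1`, darker = more stain, in \[0,255\]); and
#'   single-stain RGB renderings `hema_rgb`, `dab_rgb`
#'   (`I_c = (bg+1) * 10^(-c_s * M[s, c]) - 1`).
#' @export
deconvolve <- function(od, M = build_stain_matrix(), background = 255) {
  d <- dim(od)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stop("od must be an H x W x 3 array", call. = FALSE)
  conc <- matrix(od, ncol = 3L) %*% solve(unclass(M))
  plane <- function(v) matrix(v, nrow = d[1L], ncol = d[2L])
  render_gray <- function(cs) {
    clamp((background + 1) * 10^(-pmax(cs, 0)) - 1, 0, 255)
  }
  render_rgb <- function(cs, row) {
    v <- vapply(1:3, function(ch) {
      clamp((background + 1) * 10^(-pmax(cs, 0) * M[row, ch]) - 1, 0, 255)
    }, numeric(length(cs)))
    array(v, dim = d)
  }
  structure(list(
    h = plane(conc[, 1L]),
    dab = plane(conc[, 2L]),
    residual = plane(conc[, 3L]),
    hema_gray = plane(render_gray(conc[, 1L])),
    dab_gray = plane(render_gray(conc[, 2L])),
    hema_rgb = render_rgb(conc[, 1L], 1L),
    dab_rgb = render_rgb(conc[, 2L], 2L),
    stain_matrix = M,
    background = background
  ), class = "stain_maps")
}

#' @export
print.stain_maps <- function(x, ...) {
  cat("H-DAB stain concentration maps (", nrow(x$h), " x ", ncol(x$h), ")\n",
      sep = "")
  cat("  hematoxylin range: ", paste(format(range(x$h), digits = 4),
                                     collapse = " .. "), "\n", sep = "")
  cat("  DAB range:         ", paste(format(range(x$dab), digits = 4),
                                     collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' Compose an OD image from concentration planes (Beer-Lambert forward model)
#'
#' The forward counterpart of [deconvolve()]: `od = c_h * M[h,] + c_d *
#' M[dab,]`. Used by the synthetic generator and by round-trip checks.
#'
#' @param c_h,c_d H x W concentration planes.
#' @param M Stain matrix.
#' @return H x W x 3 optical-density array.
#' @export
compose_hdab_od <- function(c_h, c_d, M = build_stain_matrix()) {
  stopifnot(identical(dim(c_h), dim(c_d)))
  od <- array(0, dim = c(dim(c_h), 3L))
  for (ch in 1:3) od[, , ch] <- c_h * M[1L, ch] + c_d * M[2L, ch]
  od
}
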