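#' Rejection of unstained (negative-control) samples
#'
#' Negative controls contain no DAB, but scattered brown-ish pixels still
#' occur. The average proportion (AP) statistic is the percentage of pixels
#' of the DAB grayscale rendering darker than a pixel-intensity threshold,
#' taken over the whole (cropped) frame. Images with AP below a calibrated
#' cutoff are classified negative and skip segmentation.
#'
#' @name dab-gating
NULL

#' Gate parameters
#'
#' @param pixel_threshold Intensity threshold inside the AP statistic, on the
#'   0..255 DAB grayscale (default 30: genuine DAB precipitate is nearly
#'   opaque in the DAB channel, approx. 1 OD or darker, while unmixing
#'   crosstalk from dark hematoxylin nuclei after color normalization stays
#'   lighter; fixed by ROC calibration on the synthetic control set).
#' @param ap_cutoff AP cutoff in percent (default 0.6, the Youden-optimal
#'   value reported for the hardest marker).
#' @return A `gate_params` list.
#' @export
gate_params <- function(pixel_threshold = 30, ap_cutoff = 0.6) {
  if (pixel_threshold <= 0 || pixel_threshold >= 255)
    stop("pixel_threshold must be in (0, 255)", call. = FALSE)
  if (ap_cutoff <= 0 || ap_cutoff > 100)
    stop("ap_cutoff must be in (0, 100]", call. = FALSE)
  structure(list(pixel_threshold = pixel_threshold, ap_cutoff = ap_cutoff),
            class = "gate_params")
}

#' Average proportion of dark DAB pixels
#'
#' `AP = 100 * #\{pixels < pixel_threshold\} / #\{pixels\}`, evaluated over
#' the full (cropped) frame.
#'
#' @param dab_gray H x W DAB grayscale plane in \[0,255\].
#' @param pixel_threshold Intensity threshold (default 30).
#' @return AP in percent.
#' @export
average_proportion <- function(dab_gray, pixel_threshold = 30) {
  if (length(dab_gray) == 0L) stop("empty evaluation region", call. = FALSE)
  100 * mean(dab_gray < pixel_threshold)
}

#' @describeIn average_proportion Gate decision: positive iff
#'   `ap >= ap_cutoff` (boundary inclusive).
#' @param ap AP value in percent.
#' @param ap_cutoff Cutoff in percent (default 0.6).
#' @export
classify_sample <- function(ap, ap_cutoff = 0.6) {
  ap >= ap_cutoff
}

#' Calibrate the AP cutoff by ROC / Youden analysis
#'
#' For every cutoff on the grid, samples with `AP >= cutoff` are predicted
#' positive; the chosen cutoff maximizes the Youden index `J = TPR - FPR`
#' (ties broken by the smallest cutoff). AUC is the trapezoid area under the
#' grid's ROC points, anchored at (0,0) and (1,1).
#'
#' @param ap Numeric vector of AP values in percent.
#' @param labels Logical vector (or "positive"/"negative" strings) of the
#'   same length; both classes must be present.
#' @param grid_min,grid_max,grid_step Cutoff grid in percent (defaults 0.1 to
#'   1.0 by 0.01).
#' @return An `ap_calibration`: `best_cutoff`, `youden_j`, `auc`, and the
#'   `roc` data frame (cutoff, fpr, tpr).
#' @export
calibrate_ap_cutoff <- function(ap, labels, grid_min = 0.1, grid_max = 1.0,
                                grid_step = 0.01) {
  if (is.character(labels)) labels <- labels %in% c("positive", "pos", "1", "TRUE")
  labels <- as.logical(labels)
  if (length(ap) != length(labels))
    stop("ap and labels must have the same length", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("cannot calibrate: both positive and negative labels are required",
         call. = FALSE)
  grid <- seq(grid_min, grid_max, by = grid_step)
  npos <- sum(labels); nneg <- sum(!labels)
  tpr <- vapply(grid, function(ct) sum(ap >= ct & labels) / npos, 0)
  fpr <- vapply(grid, function(ct) sum(ap >= ct & !labels) / nneg, 0)
  j <- tpr - fpr
  best <- which.max(j)  # first max = smallest cutoff under ties
  roc <- data.frame(cutoff = grid, fpr = fpr, tpr = tpr)
  ord <- order(roc$fpr, roc$tpr)
  xs <- c(0, roc$fpr[ord], 1)
  ys <- c(0, roc$tpr[ord], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(best_cutoff = grid[best], youden_j = j[best], auc = auc,
                 roc = roc),
            class = "ap_calibration")
}

#' @export
print.ap_calibration <- function(x, ...) {
  cat("AP cutoff calibration\n")
  cat("  best cutoff:", x$best_cutoff, "% (Youden J =",
      format(x$youden_j, digits = 4), ")\n")
  cat("  AUC:", format(x$auc, digits = 4), "\n")
  invisible(x)
}
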