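#' DAB region segmentation by k-means with Davies-Bouldin model selection
#'
#' Tissue pixels of the DAB single-stain RGB rendering are z-scored per
#' channel and clustered with k-means; the number of clusters (1-3) is chosen
#' by the Davies-Bouldin index (k = 1 only when splitting explains almost no
#' variance). Clusters are ordered by their mean DAB-grayscale intensity and
#' the darkest cluster forms the DAB-positive mask; the result is reported as
#' percent of the tissue area.
#'
#' @name dab-segmentation
NULL

#' Clustering parameters
#'
#' @param k_min,k_max Cluster-count search range (defaults 1 and 3).
#' @param n_init Number of k-means restarts (default 5).
#' @param seed RNG seed for the restarts (default 0).
#' @param max_iter Maximum k-means iterations (default 300).
#' @param inertia_tol Relative within-variance improvement of k = 2 over
#'   k = 1 below which k = 1 is adopted (default 0.01).
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(k_min = 1L, k_max = 3L, n_init = 5L, seed = 0L,
                              max_iter = 300L, inertia_tol = 0.01) {
  if (k_min < 1L || k_max > 3L || k_min > k_max)
    stop("require 1 <= k_min <= k_max <= 3", call. = FALSE)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_init = as.integer(n_init), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), inertia_tol = inertia_tol),
            class = "clustering_params")
}

#' Build the z-scored feature matrix of tissue pixels
#'
#' Rows are the tissue pixels' values in the DAB single-stain RGB rendering;
#' each channel is centered and scaled by its population standard deviation
#' over tissue pixels. A zero-variance channel is set to 0 with a warning.
#'
#' @param dab_rgb H x W x 3 DAB single-stain rendering in \[0,255\].
#' @param tissue Logical H x W tissue mask, nonempty.
#' @return List with `features` (N x 3 matrix, columns R/G/B) and `idx`
#'   (linear indices of tissue pixels, for writing labels back into the
#'   image frame).
#' @export
build_feature_matrix <- function(dab_rgb, tissue) {
  validate_mask(tissue, dab_rgb, "tissue")
  idx <- which(tissue)
  if (length(idx) == 0L) stop("empty tissue mask", call. = FALSE)
  np <- prod(dim(tissue))
  X <- cbind(R = dab_rgb[idx], G = dab_rgb[idx + np], B = dab_rgb[idx + 2L * np])
  for (ch in 1:3) {
    mu <- mean(X[, ch])
    sdev <- sqrt(mean((X[, ch] - mu)^2))
    if (sdev == 0) {
      warning("zero-variance channel ", colnames(X)[ch],
              " in feature matrix; set to 0", call. = FALSE)
      X[, ch] <- 0
    } else {
      X[, ch] <- (X[, ch] - mu) / sdev
    }
  }
  list(features = X, idx = idx)
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) * sum_i max_{j != i} (s_i + s_j) / d_ij`, with `s_i` the mean
#' Euclidean distance of cluster members to their centroid and `d_ij` the
#' distance between centroids. Lower is better; undefined for k < 2.
#'
#' @param features N x d numeric matrix.
#' @param labels Integer cluster assignment of length N; every cluster in
#'   `1..k` must be nonempty.
#' @return Nonnegative scalar (Inf when centroids coincide).
#' @export
davies_bouldin_index <- function(features, labels) {
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) stop("DB undefined for fewer than 2 clusters", call. = FALSE)
  if (!identical(ks, seq_len(max(ks))) || any(tabulate(labels) == 0L))
    stop("empty cluster in labels", call. = FALSE)
  cent <- t(vapply(ks, function(i) colMeans(features[labels == i, , drop = FALSE]),
                   numeric(ncol(features))))
  s <- vapply(ks, function(i) {
    d <- sweep(features[labels == i, , drop = FALSE], 2L, cent[i, ])
    mean(sqrt(rowSums(d^2)))
  }, 0)
  ratio <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    if (i == j) next
    dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    ratio[i, j] <- if (dij == 0) Inf else (s[i] + s[j]) / dij
  }
  mean(apply(ratio, 1L, max))
}

#' Seeded k-means clustering
#'
#' Standard k-means (best of `n_init` restarts by total within-cluster sum of
#' squares), deterministic for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param features N x d matrix, N >= k.
#' @param k Number of clusters.
#' @param seed,n_init,max_iter See [clustering_params()].
#' @return Integer label vector with attributes `centers` and `inertia`.
#' @export
kmeans_cluster <- function(features, k, seed = 0L, n_init = 5L,
                           max_iter = 300L) {
  n <- nrow(features)
  if (n < k) stop("fewer points than clusters", call. = FALSE)
  if (k == 1L) {
    labels <- rep(1L, n)
    attr(labels, "centers") <- matrix(colMeans(features), nrow = 1L)
    attr(labels, "inertia") <- sum(sweep(features, 2L, colMeans(features))^2)
    return(labels)
  }
  km <- with_seed(seed, suppressWarnings(
    kmeans(features, centers = k, nstart = n_init, iter.max = max_iter)))
  labels <- as.integer(km$cluster)
  attr(labels, "centers") <- km$centers
  attr(labels, "inertia") <- km$tot.withinss
  labels
}

#' Choose the number of clusters (1-3)
#'
#' k-means is run for k = 2 and (if allowed) k = 3; the Davies-Bouldin index
#' picks between them. k = 1 is adopted only when the k = 2 solution reduces
#' total within-cluster variance by less than `inertia_tol` (the index itself
#' is undefined at k = 1).
#'
#' @param features N x d matrix.
#' @param params A [clustering_params()] list.
#' @return Integer k.
#' @export
select_k <- function(features, params = clustering_params()) {
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 points to select k", call. = FALSE)
  if (params$k_max == 1L) return(1L)
  inertia1 <- sum(sweep(features, 2L, colMeans(features))^2)
  # degenerate feature cloud (all points coincide): a single cluster,
  # regardless of k_min — k-means cannot place more centers than points
  if (inertia1 == 0) return(1L)
  lab2 <- kmeans_cluster(features, 2L, params$seed, params$n_init,
                         params$max_iter)
  if (params$k_min == 1L &&
      (inertia1 - attr(lab2, "inertia")) / inertia1 < params$inertia_tol)
    return(1L)
  cand <- seq(max(2L, params$k_min), params$k_max)
  cand <- cand[cand <= n & cand <= nrow(unique(features))]
  if (length(cand) == 0L) return(1L)
  db <- vapply(cand, function(k) {
    lab <- if (k == 2L) lab2 else
      kmeans_cluster(features, k, params$seed, params$n_init, params$max_iter)
    davies_bouldin_index(features, lab)
  }, 0)
  cand[which.min(db)]
}

#' Extract the DAB mask from a clustering
#'
#' Computes the mean DAB-grayscale intensity of each cluster; the darkest
#' cluster forms the DAB-positive mask. When the darkest and next cluster
#' means differ by fewer than 10 intensity levels the result is flagged
#' low-contrast (a sample that should normally have been gated out).
#'
#' @param labels Integer labels of tissue pixels (aligned with `idx`).
#' @param idx Linear indices of tissue pixels in the frame.
#' @param dab_gray H x W DAB grayscale plane.
#' @param tissue Logical H x W tissue mask.
#' @return List: `dab_mask`, `dab_percent` (= 100 * |dab| / |tissue|),
#'   `cluster_order` (darkest first), `cluster_means`, `low_contrast`.
#' @export
extract_dab_mask <- function(labels, idx, dab_gray, tissue) {
  stopifnot(length(labels) == length(idx))
  vals <- dab_gray[idx]
  means <- vapply(seq_len(max(labels)), function(i) mean(vals[labels == i]), 0)
  ord <- order(means)  # darkest first
  darkest <- ord[1L]
  dab_mask <- tissue & FALSE
  dab_mask[idx[labels == darkest]] <- TRUE
  low_contrast <- length(means) >= 2L && (means[ord[2L]] - means[darkest]) < 10
  list(dab_mask = dab_mask,
       dab_percent = 100 * sum(dab_mask) / sum(tissue),
       cluster_order = ord, cluster_means = means,
       low_contrast = low_contrast)
}

#' Full segmentation of DAB-positive regions within the tissue
#'
#' Runs the feature construction, model selection, clustering and darkest-
#' cluster extraction in sequence.
#'
#' @param dab_rgb H x W x 3 DAB single-stain rendering.
#' @param dab_gray H x W DAB grayscale plane.
#' @param tissue Logical H x W tissue mask.
#' @param params A [clustering_params()] list.
#' @return A `dab_segmentation`: `k`, `labels` (H x W integer plane, 0 =
#'   non-tissue), `cluster_order`, `cluster_means`, `dab_mask`,
#'   `dab_percent`, `low_contrast`.
#' @export
segment_dab <- function(dab_rgb, dab_gray, tissue,
                        params = clustering_params()) {
  fm <- build_feature_matrix(dab_rgb, tissue)
  k <- select_k(fm$features, params)
  labels <- kmeans_cluster(fm$features, k, params$seed, params$n_init,
                           params$max_iter)
  ext <- extract_dab_mask(labels, fm$idx, dab_gray, tissue)
  plane <- matrix(0L, nrow(tissue), ncol(tissue))
  plane[fm$idx] <- as.integer(labels)
  structure(list(k = as.integer(k), labels = plane,
                 cluster_order = ext$cluster_order,
                 cluster_means = ext$cluster_means,
                 dab_mask = ext$dab_mask, dab_percent = ext$dab_percent,
                 low_contrast = ext$low_contrast),
            class = "dab_segmentation")
}

#' @export
print.dab_segmentation <- function(x, ...) {
  cat("DAB segmentation: k = ", x$k, ", DAB occupancy ",
      format(x$dab_percent, digits = 4), "% of tissue",
      if (x$low_contrast) " (low contrast)" else "", "\n", sep = "")
  invisible(x)
}

# 4-neighbour erosion treating out-of-frame as background
erode4 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
}

#' Draw red contours of the DAB mask on the original image
#'
#' The 1-pixel boundary of each mask component (mask pixels with a
#' 4-neighbour outside the mask, frame border included) is painted pure red
#' (255, 0, 0); the interior is untouched.
#'
#' @param original H x W x 3 array in \[0,255\].
#' @param dab_mask Logical H x W matrix aligned to `original`.
#' @return H x W x 3 array with the contour drawn.
#' @export
draw_overlay <- function(original, dab_mask) {
  validate_rgb_image(original, "original")
  validate_mask(dab_mask, original, "dab_mask")
  boundary <- dab_mask & !erode4(dab_mask)
  out <- original
  np <- prod(dim(dab_mask))
  bidx <- which(boundary)
  out[bidx] <- 255
  out[bidx + np] <- 0
  out[bidx + 2L * np] <- 0
  out
}
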