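make_blobs <- function(centers, n_each, sd = 0.05, seed = 1) {
  with_seed <- dabquant:::with_seed
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_each * 3, mean = rep(centers[i, ], each = n_each),
                   sd = sd), n_each, 3)
    }))
  })
}

test_that("feature matrix z-scores tissue pixels per channel", {
  # two-color tissue with equal counts: features are exactly +/- 1
  img <- array(0, dim = c(4, 4, 3))
  img[, 1:2, ] <- 50; img[, 3:4, ] <- 150
  tissue <- matrix(TRUE, 4, 4)
  fm <- build_feature_matrix(img, tissue)
  expect_true(all(abs(abs(fm$features) - 1) < 1e-12))

  # constant tissue: degenerate branch, all zeros with a warning
  cimg <- array(80, dim = c(3, 3, 3))
  expect_warning(fm0 <- build_feature_matrix(cimg, matrix(TRUE, 3, 3)),
                 "zero-variance")
  expect_true(all(fm0$features == 0))

  # random fixture: column moments are exactly standardized
  set.seed(71)
  rimg <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), dim = c(20, 20, 3))
  tis <- matrix(runif(400) > 0.3, 20, 20)
  fm2 <- build_feature_matrix(rimg, tis)
  expect_equal(colMeans(fm2$features), c(R = 0, G = 0, B = 0),
               tolerance = 1e-9)
  expect_equal(apply(fm2$features, 2, function(x) sqrt(mean(x^2))),
               c(R = 1, G = 1, B = 1), tolerance = 1e-9)
  # index map points back at tissue pixels
  expect_identical(fm2$idx, which(tis))
})

test_that("Davies-Bouldin index matches hand-computed values and degenerates correctly", {
  # pencil-and-paper 6-point, 2-cluster instance in the plane z = 0:
  # cluster 1: (0,0), (1,0), (0.5,1); centroid (0.5, 1/3)
  # cluster 2: (5,0), (6,0), (5.5,1); centroid (5.5, 1/3)
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0),
               c(5, 0, 0), c(6, 0, 0), c(5.5, 1, 0))
  lab <- c(1L, 1L, 1L, 2L, 2L, 2L)
  s1 <- (2 * sqrt(0.5^2 + (1 / 3)^2) + sqrt(0 + (2 / 3)^2)) / 3
  expected <- (s1 + s1) / 5  # d12 = 5, symmetric clusters
  expect_equal(davies_bouldin_index(pts, lab), expected, tolerance = 1e-12)

  # well-separated tight blobs: DB < 0.2
  tight <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 50, sd = 0.05, seed = 72)
  expect_lt(davies_bouldin_index(tight, rep(1:2, each = 50)), 0.2)

  # one blob duplicated and split into two identical halves: centroids
  # coincide exactly, so DB diverges
  half <- make_blobs(rbind(c(0, 0, 0)), 50, sd = 0.05, seed = 73)
  co <- rbind(half, half)
  expect_gte(davies_bouldin_index(co, rep(1:2, each = 50)), 1e3)

  expect_error(davies_bouldin_index(tight, rep(1L, 100)), "fewer than 2")
  expect_error(davies_bouldin_index(tight, c(rep(1L, 99), 3L)), "empty cluster")
})

test_that("k-means is seeded, deterministic, and recovers planted partitions", {
  X <- make_blobs(rbind(c(0, 0, 0), c(8, 8, 0)), 60, sd = 0.3, seed = 74)
  l1 <- kmeans_cluster(X, 2, seed = 0)
  l2 <- kmeans_cluster(X, 2, seed = 0)
  expect_identical(as.integer(l1), as.integer(l2))

  # planted partition recovered exactly (up to label permutation)
  truth <- rep(1:2, each = 60)
  tab <- table(as.integer(l1), truth)
  expect_equal(sum(apply(tab, 1, max)), 120)

  # k = 1: single cluster at the mean
  l0 <- kmeans_cluster(X, 1)
  expect_true(all(l0 == 1L))
  expect_equal(as.numeric(attr(l0, "centers")), colMeans(X))

  # RNG state of the caller is untouched
  set.seed(42); before <- .Random.seed
  invisible(kmeans_cluster(X, 2, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("cluster-count selection follows Davies-Bouldin with the k=1 variance rule", {
  two <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 80, sd = 0.3, seed = 75)
  expect_equal(select_k(two), 2L)

  three <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0), c(5, 9, 0)), 80,
                      sd = 0.3, seed = 76)
  expect_equal(select_k(three), 3L)

  # structureless features (a quantized constant color collapses to one
  # point after z-scoring): a single cluster
  one <- matrix(0, 150, 3)
  expect_equal(select_k(one), 1L)
})

test_that("DAB mask extraction picks the darkest cluster and quantifies area", {
  fx <- generate_strip_image(small_params(dab_fraction = 0.2, strip_angle = 0,
                                          seed = 78))
  maps <- deconvolve(rgb_to_od(fx$image))
  tissue <- fx$truth$tissue_mask
  seg <- segment_dab(maps$dab_rgb, maps$dab_gray, tissue)
  expect_gte(seg$dab_percent, 18); expect_lte(seg$dab_percent, 22)

  # label conservation: every tissue pixel labeled, sizes sum to |tissue|
  expect_equal(sum(seg$labels > 0), sum(tissue))
  expect_true(all((seg$labels > 0) == tissue))
  # darkest cluster has the minimum mean DAB intensity
  expect_equal(seg$cluster_order[1], which.min(seg$cluster_means))
  expect_true(all(seg$cluster_means[seg$cluster_order[1]] <=
                    seg$cluster_means))
  expect_true(all(seg$dab_mask[seg$dab_mask] & tissue[seg$dab_mask]))

  # uniformly dark tissue at k = 1 covers everything
  dark <- array(20, dim = c(6, 6, 3))
  dg <- matrix(20, 6, 6)
  tis <- matrix(TRUE, 6, 6)
  seg1 <- suppressWarnings(segment_dab(dark, dg, tis))
  expect_equal(seg1$k, 1L)
  expect_equal(seg1$dab_percent, 100)

  # zero-DAB tissue forced through clustering still returns the darkest
  # cluster (and its occupancy is meaningless but well-defined)
  fx0 <- generate_strip_image(small_params(dab_fraction = 0, strip_angle = 0,
                                           seed = 79))
  m0 <- deconvolve(rgb_to_od(fx0$image))
  seg0 <- segment_dab(m0$dab_rgb, m0$dab_gray, fx0$truth$tissue_mask,
                      clustering_params(k_min = 2L))
  expect_gte(seg0$k, 2L)
  expect_equal(seg0$cluster_order[1], which.min(seg0$cluster_means))

  # low-contrast flag contract: mean separation < 10 levels flags, >= 10 not
  tis2 <- matrix(TRUE, 2, 4)
  close_gray <- matrix(c(100, 100, 100, 100, 105, 105, 105, 105), 2, 4)
  lab2 <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  expect_true(extract_dab_mask(lab2, 1:8, close_gray, tis2)$low_contrast)
  far_gray <- matrix(c(100, 100, 100, 100, 180, 180, 180, 180), 2, 4)
  ext <- extract_dab_mask(lab2, 1:8, far_gray, tis2)
  expect_false(ext$low_contrast)
  expect_equal(ext$dab_percent, 50)
  expect_true(all(which(ext$dab_mask) == 1:4))
})

test_that("overlay draws exactly the 1-px component boundaries in red", {
  img <- array(120, dim = c(20, 20, 3))
  # empty mask: unchanged
  expect_identical(draw_overlay(img, matrix(FALSE, 20, 20)), img + 0)

  # 10x10 square: exactly its 36 boundary pixels turn red
  sq <- rect_mask(20, 20, 6, 15, 6, 15)
  ov <- draw_overlay(img, sq)
  red <- ov[, , 1] == 255 & ov[, , 2] == 0 & ov[, , 3] == 0
  expect_equal(sum(red), 36)
  expect_true(all(red[6, 6:15]) && all(red[15, 6:15]))
  expect_false(red[8, 8])  # interior untouched
  expect_equal(ov[8, 8, ], c(120, 120, 120))

  # full-frame mask: only the frame border is drawn
  ovf <- draw_overlay(img, matrix(TRUE, 20, 20))
  redf <- ovf[, , 1] == 255 & ovf[, , 2] == 0 & ovf[, , 3] == 0
  expect_equal(sum(redf), 2 * 20 + 2 * 18)
  expect_false(redf[10, 10])
})
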