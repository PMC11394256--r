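# shared helpers: small fixtures and independent oracles

# reduced-size generator parameters for fast unit tests
small_params <- function(...) {
  fixture_params(height = 240L, width = 320L, strip_thickness = 40L, ...)
}

# analytic axis-aligned solid rectangle mask
rect_mask <- function(H, W, r0, r1, c0, c1) {
  m <- matrix(FALSE, H, W)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# analytic rotated solid rectangle (pixel centers inside), about frame centre
rotated_rect_mask <- function(H, W, angle, half_len, half_thick) {
  th <- angle * pi / 180
  cc <- matrix(rep(0:(W - 1), each = H), H, W) - (W - 1) / 2
  rr <- matrix(rep(0:(H - 1), W), H, W) - (H - 1) / 2
  u <- cos(th) * cc + sin(th) * rr
  v <- -sin(th) * cc + cos(th) * rr
  abs(u) <= half_len & abs(v) <= half_thick
}

# independent rotation-profile oracle: EBImage nearest-neighbour rotation,
# then row sums (different code path and resampling conventions)
ebimage_profile <- function(mask, angle) {
  eb <- EBImage::rotate(EBImage::Image(t(mask) * 1), angle,
                        filter = "none", bg.col = 0)
  as.integer(rowSums(t(as.matrix(eb)) > 0.5))
}

# pure-R rotate-and-sum with the same mapping conventions as the C++ kernel
# (inverse NN about the centre, expanded canvas, round-half-up)
r_reference_profile <- function(mask, angle) {
  th <- angle * pi / 180
  H <- nrow(mask); W <- ncol(mask)
  ct <- cos(th); st <- sin(th)
  Wr <- ceiling(W * abs(ct) + H * abs(st) - 1e-9)
  Hr <- ceiling(W * abs(st) + H * abs(ct) - 1e-9)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  cxr <- (Wr - 1) / 2; cyr <- (Hr - 1) / 2
  prof <- integer(Hr)
  xr <- 0:(Wr - 1)
  for (yr in 0:(Hr - 1)) {
    dx <- xr - cxr; dy <- yr - cyr
    ix <- floor(ct * dx + st * dy + cx + 0.5)
    iy <- floor(-st * dx + ct * dy + cy + 0.5)
    ok <- ix >= 0 & ix < W & iy >= 0 & iy < H
    prof[yr + 1] <- sum(mask[cbind(iy[ok] + 1, ix[ok] + 1)])
  }
  prof
}

# exhaustive Otsu oracle: naive between-class-variance maximization over all
# 255 split points, mean of tying argmaxima
brute_otsu <- function(gray) {
  v <- round(as.numeric(gray))
  sigma <- vapply(0:254, function(t) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    w0 * w1 * (mean(g0) - mean(g1))^2
  }, 0)
  mean(which(sigma == max(sigma)) - 1)
}

# naive double-loop Youden sweep oracle
brute_youden <- function(ap, labels, grid) {
  best_j <- -Inf; best_cut <- NA
  for (ct in grid) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(ap)) {
      pred <- ap[i] >= ct
      if (pred && labels[i]) tp <- tp + 1
      if (pred && !labels[i]) fp <- fp + 1
      if (!pred && labels[i]) fn <- fn + 1
      if (!pred && !labels[i]) tn <- tn + 1
    }
    j <- tp / (tp + fn) - fp / (fp + tn)
    if (j > best_j + 1e-12) { best_j <- j; best_cut <- ct }
  }
  list(cutoff = best_cut, j = best_j)
}

# intersection-over-union of two masks
iou <- function(a, b) sum(a & b) / sum(a | b)

# residual tilt (degrees) after applying `found` to a strip planted at `planted`
residual_tilt <- function(planted, found) {
  r <- (planted + found) %% 180
  min(r, 180 - r)
}
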