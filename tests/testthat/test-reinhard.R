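test_that("forward l-alpha-beta transform matches a hand-evaluated matrix chain", {
  # independent oracle: direct evaluation of the published Reinhard matrices
  # for a single pixel (200, 100, 50), written out step by step
  rgb <- c(200, 100, 50) / 255
  lms <- c(0.3811 * rgb[1] + 0.5783 * rgb[2] + 0.0402 * rgb[3],
           0.1967 * rgb[1] + 0.7244 * rgb[2] + 0.0782 * rgb[3],
           0.0241 * rgb[1] + 0.1288 * rgb[2] + 0.8444 * rgb[3])
  loglms <- log10(lms + 1 / 255)
  expected <- c((loglms[1] + loglms[2] + loglms[3]) / sqrt(3),
                (loglms[1] + loglms[2] - 2 * loglms[3]) / sqrt(6),
                (loglms[1] - loglms[2]) / sqrt(2))
  px <- array(c(200, 100, 50), dim = c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_lab_opponent(px)), expected, tolerance = 1e-12)
})

test_that("achromatic input has constant opponent planes and transform round-trips", {
  gray <- array(128, dim = c(4, 6, 3))
  lab <- rgb_to_lab_opponent(gray)
  expect_equal(max(lab[, , 2]) - min(lab[, , 2]), 0)
  expect_equal(max(lab[, , 3]) - min(lab[, , 3]), 0)

  set.seed(11)
  img <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  back <- lab_opponent_to_rgb(rgb_to_lab_opponent(img))
  expect_lt(max(abs(back - img)), 1)
})

test_that("channel statistics match a brute-force two-pass oracle", {
  # closed form two-pixel case
  two <- array(0, dim = c(2, 1, 3)); two[2, 1, ] <- 2
  st <- compute_channel_stats(two)
  expect_equal(st$mean, c(1, 1, 1))
  expect_equal(st$sd, c(1, 1, 1))  # population sd

  # constant image flags all channels degenerate
  stc <- compute_channel_stats(array(5, dim = c(3, 3, 3)))
  expect_identical(stc$degenerate, c(TRUE, TRUE, TRUE))
  expect_equal(stc$sd, c(0, 0, 0))

  set.seed(21)
  lab <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  st <- compute_channel_stats(lab)
  for (ch in 1:3) {
    v <- as.numeric(lab[, , ch])
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / length(v))
    expect_equal(st$mean[ch], m, tolerance = 1e-12)
    expect_equal(st$sd[ch], s, tolerance = 1e-12)
  }
})

test_that("normalization to the source's own statistics reduces to the min-max stretch", {
  set.seed(31)
  img <- array(sample(10:240, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  self <- reinhard_normalize(img, compute_channel_stats(rgb_to_lab_opponent(img)))
  manual <- img
  for (ch in 1:3) {
    p <- img[, , ch]; r <- range(p)
    manual[, , ch] <- round((p - r[1]) / (r[2] - r[1]) * 255)
  }
  # identity before the stretch, so output = stretched source up to the
  # 1-level rounding ambiguity of the forward-inverse float chain
  expect_lte(max(abs(self - manual)), 1)
  expect_lt(mean(abs(self - manual)), 0.05)
})

test_that("the affine transfer maps statistics exactly and preserves channel order", {
  set.seed(41)
  src <- array(sample(30:220, 12 * 12 * 3, replace = TRUE), dim = c(12, 12, 3))
  ref <- default_reference_stats()
  out <- reinhard_normalize(src, ref, stretch = FALSE, quantize = FALSE)
  # statistics transfer: post-normalization stats equal the reference's
  raw_lab <- rgb_to_lab_opponent(src)
  src_st <- compute_channel_stats(raw_lab)
  mapped <- raw_lab
  for (ch in 1:3) {
    mapped[, , ch] <- (raw_lab[, , ch] - src_st$mean[ch]) *
      (ref$sd[ch] / src_st$sd[ch]) + ref$mean[ch]
  }
  mst <- compute_channel_stats(mapped)
  expect_equal(mst$mean, ref$mean, tolerance = 1e-6)
  expect_equal(mst$sd, ref$sd, tolerance = 1e-6)
  # hand-applied affine map equals the package's pre-stretch output
  expect_equal(out, lab_opponent_to_rgb(mapped), tolerance = 1e-9)
  # monotone per channel: ranking preserved pre-quantization
  for (ch in 1:3) {
    o <- order(raw_lab[, , ch])
    expect_true(all(diff(mapped[, , ch][o]) >= 0))
  }
})

test_that("degenerate sources shift to the reference mean color", {
  const <- array(77, dim = c(4, 4, 3))
  ref <- default_reference_stats()
  out <- suppressWarnings(reinhard_normalize(const, ref))
  # constant in, constant out (stretch leaves constant channels unchanged)
  for (ch in 1:3) expect_equal(max(out[, , ch]), min(out[, , ch]))
  expect_warning(reinhard_normalize(const, ref), "degenerate")
  # and the constant equals the reference mean color
  expected <- lab_opponent_to_rgb(array(ref$mean, dim = c(1, 1, 3)))
  expect_equal(as.numeric(out[1, 1, ]), round(as.numeric(expected)))
})
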