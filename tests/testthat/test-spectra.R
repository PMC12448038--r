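test_that("DPSS tapers match a dense eigensolver oracle at small n", {
  n <- 64; nw <- 4; K <- 7
  tap <- dpss_tapers(n, nw, K)
  # independent oracle: dense eigendecomposition of the same tridiagonal
  W <- nw / n
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  M <- diag(d)
  for (i in 1:(n - 1)) M[i, i + 1] <- M[i + 1, i] <- e[i]
  ev <- eigen(M, symmetric = TRUE)
  for (k in 1:K) {
    v <- ev$vectors[, k]
    expect_equal(abs(sum(v * tap[, k])), 1, tolerance = 1e-8)
  }
})

test_that("DPSS tapers are orthonormal and cached", {
  tap <- dpss_tapers(500, 4, 7)
  gram <- crossprod(tap)
  expect_equal(gram, diag(7), tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(tap, dpss_tapers(500, 4, 7))   # cache hit
})

test_that("epoching respects blocks, discards tails and hits the default count", {
  rec <- small_recording(seed = 1, fs = 50, block_s = 120, n_cycles = 5)
  ep <- epoch_recording(rec, 30)
  expect_equal(dim(ep$eyes_closed$epochs)[1], 20)
  expect_equal(dim(ep$eyes_open$epochs)[1], 20)
  # 100-s blocks give 3 epochs each, 10-s tails discarded
  rec2 <- small_recording(seed = 1, fs = 50, block_s = 100, n_cycles = 2)
  ep2 <- epoch_recording(rec2, 30)
  expect_equal(dim(ep2$eyes_closed$epochs)[1], 6)
  expect_error(epoch_recording(rec2, 150), "exceeds")
  # epochs tile each block without crossing boundaries: first epoch of the
  # first eyes-open block starts right at the block boundary
  blk <- which(rec2$conditions == "eyes_open")[1]
  expect_equal(ep2$eyes_open$epochs[1, 3, ],
               unname(rec2$samples[3, blk:(blk + 30 * 50 - 1)]))
})

test_that("multitaper PSD integrates a pure sine to A^2/2", {
  fs <- 250; A <- 20
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- A * sin(2 * pi * 10 * t)
  arr <- array(0, dim = c(2, 1, length(t)))
  arr[1, 1, ] <- x; arr[2, 1, ] <- x
  ep <- structure(list(condition = "eyes_closed", epochs = arr * 1e-6,
                       fs = fs, epoch_s = 10, channels = "O1"),
                  class = "epoch_set")
  sp <- psd_multitaper(ep, smoothing_hz = 1)
  expect_s3_class(sp, "spectrum_set")
  expect_true(all(sp$power >= 0))
  expect_true(all(diff(sp$freqs) > 0))
  expect_lte(max(sp$freqs), fs / 2)
  # integrated power near the line (within the smoothing bandwidth)
  df <- sp$freqs[2] - sp$freqs[1]
  near <- abs(sp$freqs - 10) <= 2
  expect_equal(sum(sp$power[1, 1, near]) * df, A^2 / 2, tolerance = 0.05)
  # all-zero epochs give an all-zero spectrum
  arr0 <- array(0, dim = c(2, 1, length(t)))
  ep0 <- structure(list(condition = "x", epochs = arr0, fs = fs,
                        epoch_s = 10, channels = "O1"),
                   class = "epoch_set")
  expect_equal(max(psd_multitaper(ep0)$power), 0)
  expect_error(psd_multitaper(ep, smoothing_hz = 0.05), "smoothing")
})

test_that("multitaper spectrum of white noise is flat", {
  fs <- 100
  set.seed(21)
  nep <- 30
  arr <- array(rnorm(nep * 1 * fs * 4, sd = 1e-6),
               dim = c(nep, 1, fs * 4))
  ep <- structure(list(condition = "x", epochs = arr, fs = fs, epoch_s = 4,
                       channels = "CZ"),
                  class = "epoch_set")
  sp <- psd_multitaper(ep, smoothing_hz = 1)
  sel <- sp$freqs > 5 & sp$freqs < 45          # away from edge bias
  m <- colMeans(matrix(sp$power[, 1, sel], nrow = nep))
  grand <- mean(m)
  se <- sd(m) / sqrt(length(m))    # conservative: bins are W-correlated
  expect_true(all(abs(m - grand) < 3 * sd(m) + 1e-12))
  expect_equal(grand, 2 / fs, tolerance = 0.1)  # 2 sigma^2/fs, one-sided
})

test_that("band powers integrate the density and partition 1-30 Hz", {
  rec <- small_recording(seed = 13, fs = 100, block_s = 30, n_cycles = 1)
  sp <- psd_multitaper(epoch_recording(rec, 10)$eyes_closed)
  bands <- eeg_bands()
  expect_equal(bands$lo, c(1, 4, 8, 12))
  expect_equal(bands$hi, c(4, 8, 12, 30))
  total <- band_power(sp, c(1, 30))
  parts <- Reduce(`+`, lapply(seq_len(nrow(bands)),
                              function(i) band_power(sp, bands[i, ])))
  expect_equal(parts, total, tolerance = 1e-12)
  # a 10 Hz line lands in alpha, not beta
  fs <- 250
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  arr <- array(rep(10e-6 * sin(2 * pi * 10 * t), each = 2),
               dim = c(2, 1, length(t)))
  ep <- structure(list(condition = "x", epochs = arr, fs = fs, epoch_s = 10,
                       channels = "O1"),
                  class = "epoch_set")
  sps <- psd_multitaper(ep)
  expect_gt(band_power(sps, c(8, 12))[1, 1],
            100 * band_power(sps, c(12, 30))[1, 1])
  expect_error(band_power(sps, c(30, 8)), "lo < hi")
})
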