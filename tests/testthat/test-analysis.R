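test_that("noisy-channel screening drops loud, dead and flat channels only", {
  rec <- small_recording(seed = 17, fs = 100)
  clean <- exclude_noisy_channels(rec)
  expect_length(clean$excluded, 0)
  expect_equal(dim(clean$rec$samples), dim(rec$samples))
  # one channel replaced by 10x-amplitude noise
  loud <- rec
  set.seed(1)
  loud$samples["C3", ] <- rnorm(ncol(rec$samples),
                                sd = 10 * sd(rec$samples["C3", ]))
  scr <- exclude_noisy_channels(loud)
  expect_identical(scr$excluded, "C3")
  expect_equal(nrow(scr$rec$samples), 23)
  expect_identical(scr$rec$montage$label, setdiff(rec$montage$label, "C3"))
  # a flat channel is dropped
  flat <- rec
  flat$samples["T8", ] <- 0
  expect_true("T8" %in% exclude_noisy_channels(flat)$excluded)
  # all-flat input errors
  allflat <- rec
  allflat$samples[] <- 0
  expect_error(exclude_noisy_channels(allflat), "all channels")
})

test_that("the t-map equals the textbook pooled-variance t", {
  set.seed(5)
  # hand-sized: 3 vs 3 epochs, 1 channel, 1 bin
  a <- c(1.1, 2.3, 0.7); b <- c(3.0, 2.8, 4.1)
  mk <- function(v, cond)
    fake_spectrum_set(array(10^v, dim = c(length(v), 1, 1)),
                      freqs = 10, channels = "O1", condition = cond)
  tm <- t_map(mk(a, "eyes_closed"), mk(b, "eyes_open"))
  sp <- sqrt(((3 - 1) * var(a) + (3 - 1) * var(b)) / (3 + 3 - 2))
  t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(unname(tm[1, 1]), t_ref, tolerance = 1e-10)
  # identical groups give t = 0; swapping the groups negates t
  expect_equal(unname(t_map(mk(a, "x"), mk(a, "y"))[1, 1]), 0)
  expect_equal(unname(t_map(mk(b, "y"), mk(a, "x"))[1, 1]),
               unname(-tm[1, 1]), tolerance = 1e-10)
  expect_error(t_map(mk(a[1:2], "x"), mk(b, "y")), NA)
  expect_error(t_map(mk(a[1], "x"), mk(b, "y")), "2 epochs")
})

test_that("channel adjacency is symmetric, irreflexive and anatomically sane", {
  adj <- channel_adjacency(montage_1020_24())
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  expect_true(adj["O1", "OZ"])
  expect_false(adj["FP1", "O2"])
  expect_true(all(rowSums(adj) >= 1))
})

test_that("Monte Carlo cluster p-values approach the exhaustive permutation law", {
  # tiny instance: 4 + 4 epochs, 2 channels, 3 bins -> C(8,4) = 70 splits
  set.seed(33)
  na <- 4; nb <- 4; nch <- 2; nf <- 3
  x <- array(10^rnorm((na + nb) * nch * nf), dim = c(na + nb, nch, nf))
  x[1:na, 1, ] <- x[1:na, 1, ] * 50          # planted effect on channel 1
  freqs <- c(9, 10, 11)
  sp_a <- fake_spectrum_set(x[1:na, , , drop = FALSE], freqs, c("A", "B"))
  sp_b <- fake_spectrum_set(x[na + 1:nb, , , drop = FALSE], freqs,
                            c("A", "B"), "eyes_open")
  adj <- matrix(TRUE, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  diag(adj) <- FALSE

  cfg <- cluster_test_config(cluster_alpha = 0.05, n_permutations = 2000,
                             seed = 7)
  res <- cluster_permutation(sp_a, sp_b, adj, cfg)
  expect_gt(length(res$clusters), 0)

  # exhaustive oracle over all 70 group assignments
  lx <- log10(matrix(x, na + nb, nch * nf))
  thresh <- qt(1 - cfg$cluster_alpha / 2, df = na + nb - 2)
  adj_list <- list(2L, 1L)
  max_stat <- function(idx_a) {
    ta <- eegstream:::pooled_t(lx[idx_a, , drop = FALSE],
                               lx[-idx_a, , drop = FALSE])
    eegstream:::.cluster_max_stat(matrix(ta, nch, nf), thresh, adj_list)
  }
  all_splits <- utils::combn(na + nb, na)
  dist_exact <- apply(all_splits, 2, max_stat)
  obs <- abs(res$clusters[[1]]$stat)
  p_exact <- mean(dist_exact >= obs - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / cfg$n_permutations)
  expect_lt(abs(res$clusters[[1]]$p - p_exact), 3 * se + 2 / cfg$n_permutations)
})

test_that("the cluster test is deterministic under a fixed seed", {
  rec <- small_recording(seed = 19, fs = 100, block_s = 20, n_cycles = 2)
  ep <- epoch_recording(rec, 10)
  sp_c <- psd_multitaper(ep$eyes_closed)
  sp_o <- psd_multitaper(ep$eyes_open)
  adj <- channel_adjacency(montage_1020_24())
  cfg <- cluster_test_config(n_permutations = 100, seed = 42)
  r1 <- cluster_permutation(sp_c, sp_o, adj, cfg)
  r2 <- cluster_permutation(sp_c, sp_o, adj, cfg)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p"),
                   vapply(r2$clusters, `[[`, numeric(1), "p"))
  expect_identical(r1$perm_max, r2$perm_max)
  # p-values live in (0, 1] and members are within the tested range
  ps <- vapply(r1$clusters, `[[`, numeric(1), "p")
  expect_true(all(ps > 0 & ps <= 1))
  for (cl in r1$clusters)
    expect_true(all(cl$members$freq_hz >= 1 & cl$members$freq_hz <= 30))
})

test_that("effective channels are the union over significant clusters, montage-ordered", {
  mk <- function(p1, p2) {
    structure(list(
      clusters = list(
        list(members = data.frame(channel = c("O2", "O1"),
                                  freq_hz = c(10, 10)),
             stat = 50, sign = 1, p = p1),
        list(members = data.frame(channel = "FP1", freq_hz = 2),
             stat = -30, sign = -1, p = p2)),
      channels = montage_1020_24()$label,
      config = cluster_test_config()),
      class = "cluster_result")
  }
  expect_identical(effective_channels(mk(0.01, 0.2)), c("O1", "O2"))
  expect_identical(effective_channels(mk(0.01, 0.01)), c("FP1", "O1", "O2"))
  expect_length(effective_channels(mk(0.5, 0.5)), 0)
  empty <- structure(list(clusters = list(), channels = letters,
                          config = cluster_test_config()),
                     class = "cluster_result")
  expect_length(effective_channels(empty), 0)
})

test_that("pipeline comparison is 1 for identical input and degrades with coarse codecs", {
  # artifact-sized blinks force saturation at b=10/max_shift=0 but not b=16
  rec <- small_recording(seed = 23, fs = 250, block_s = 30, n_cycles = 2,
                         blink_amp_uv = 1500, blink_rate_hz = 0.5)
  self <- compare_pipelines(rec, rec, epoch_s = 10)
  expect_equal(self$r, 1, tolerance = 1e-12)
  adc <- adc_config(gain = 8)
  roundtrip <- function(bits, max_shift = 8) {
    cfg <- codec_config(payload_bits = bits, max_shift = max_shift, fs = 250)
    dec <- decode_stream(encode_stream(volts_to_code(adc, rec$samples), cfg),
                         cfg)
    out <- rec
    out$samples <- code_to_volts(adc, dec$codes)
    compare_pipelines(rec, out, epoch_s = 10)$r
  }
  r16 <- roundtrip(16)
  r10 <- roundtrip(10, max_shift = 0)
  expect_gt(r16, 0.95)
  expect_lte(r10, r16)
})
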