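test_that("bits_needed matches the brute-force minimal-bit oracle", {
  # oracle: smallest k with 2^k - 1 >= limit
  oracle <- function(limit) {
    k <- 0
    while (2^k - 1 < limit) k <- k + 1
    k
  }
  limits <- c(0:66, 127, 128, 255, 256, 1023, 2048, 2^20, 2^23 - 1)
  expect_equal(bits_needed(limits), vapply(limits, oracle, numeric(1)))
  expect_error(bits_needed(-1), "non-negative")
})

test_that("safety factor 8 buys exactly four extra high-order bits over the baseline", {
  sigma <- 256
  baseline <- bits_needed(sigma - 1)      # covers differences strictly below sigma
  with_safety <- bits_needed(round(8 * sigma))
  expect_identical(with_safety - baseline, 4)
})

test_that("select_shift clamps, matches worked examples and is monotone", {
  expect_identical(select_shift(0, codec_config()), 0L)
  expect_identical(select_shift(256, codec_config(payload_bits = 16)), 0L)
  expect_identical(select_shift(256, codec_config(payload_bits = 10)), 3L)
  expect_identical(select_shift(1e6, codec_config(max_shift = 0)), 0L)
  # monotone in sigma, in safety factor; never decreasing when b shrinks
  sigmas <- c(0, 1, 7, 64, 255, 256, 300, 2048, 1e5)
  for (f in c(1, 2, 8, 16)) {
    for (b in c(10, 14, 16)) {
      cfg <- codec_config(payload_bits = b, safety_factor = f, max_shift = 9)
      s <- select_shift(sigmas, cfg)
      expect_true(all(diff(s) >= 0))
    }
    s16 <- select_shift(sigmas, codec_config(payload_bits = 16,
                                             safety_factor = f, max_shift = 9))
    s10 <- select_shift(sigmas, codec_config(payload_bits = 10,
                                             safety_factor = f, max_shift = 9))
    expect_true(all(s10 >= s16))
  }
  for (sg in c(10, 500, 5000)) {
    cfg1 <- codec_config(safety_factor = 2, max_shift = 9)
    cfg2 <- codec_config(safety_factor = 8, max_shift = 9)
    expect_true(select_shift(sg, cfg2) >= select_shift(sg, cfg1))
  }
})

test_that("update_stats tracks mean and first-difference population SD", {
  cfg <- codec_config()
  st <- channel_state()
  # constant signal: sigma 0, shift 0
  st1 <- update_stats(st, rep(7L, 250), cfg)
  expect_equal(st1$sigma, 0)
  expect_identical(st1$shift, 0L)
  expect_equal(st1$running_mean, 7)
  # differences alternating +a/-a have population SD a
  a <- 40
  x <- cumsum(c(0, rep(c(a, -a), 50)))
  st2 <- update_stats(st, x, cfg)
  expect_equal(st2$sigma, a)
  # degenerate windows
  expect_equal(update_stats(st, 5L, cfg)$sigma, 0)
  expect_identical(update_stats(st, integer(0), cfg), st)
})

test_that("encode_sample/decode_sample are closed-loop mirrors with saturation", {
  cfg <- codec_config(payload_bits = 16)
  st <- channel_state(shift = 0)
  r <- encode_sample(st, 5, cfg)
  expect_equal(r$symbol, 5)
  expect_equal(r$state$prev_recon, 5)
  st3 <- channel_state(shift = 3)
  r <- encode_sample(st3, 100, cfg)
  expect_equal(r$symbol, 13)          # round(100/8)
  expect_equal(r$state$prev_recon, 104)
  d <- decode_sample(channel_state(), 13, 3, cfg)
  expect_equal(d$code24, 104)
  # b = 10 saturates at 2^9 - 1
  r <- encode_sample(channel_state(), 1000, codec_config(payload_bits = 10))
  expect_equal(r$symbol, 511)
  expect_equal(r$state$prev_recon, 511)
  expect_error(decode_sample(channel_state(), 600, 0,
                             codec_config(payload_bits = 10)), "corruption")
})

test_that("stream framing: keyframe opens each second, delta packets chunked", {
  cfg <- codec_config()                       # 250 Hz, spp 25
  expect_length(encode_stream(matrix(integer(), 24, 0), cfg), 0)
  pk <- encode_stream(walk_codes(250), cfg)
  expect_length(pk, 11)                       # 1 keyframe + 10 delta
  expect_true(pk[[1]]$keyframe)
  expect_false(any(vapply(pk[-1], function(p) p$keyframe, logical(1))))
  # last delta packet of the window is short (24 samples)
  expect_equal(ncol(pk[[11]]$payload), 24)
  expect_equal(sum(vapply(pk, eegstream:::length_payload, integer(1))), 250)
  # every symbol fits the payload width
  qmax <- 2^(cfg$payload_bits - 1) - 1
  for (p in pk[-1]) expect_true(all(abs(p$payload) <= qmax))
  expect_error(encode_stream(matrix(0L, 23, 100), cfg), "channel count")
})

test_that("encoder and decoder reconstructions are bit-identical without loss", {
  cfg <- codec_config()
  codes <- walk_codes(1000, sd = 300, seed = 5)
  pk <- encode_stream(codes, cfg)
  dec <- decode_stream(pk, cfg)
  expect_identical(dec$codes, unname(attr(pk, "encoder_recon")))
  expect_false(any(dec$lost))
  expect_equal(dec$stats$loss_fraction, 0)
})

test_that("per-sample error is bounded by 2^(s-1) when nothing saturates", {
  cfg <- codec_config(payload_bits = 16)
  codes <- walk_codes(1500, sd = 500, seed = 8)
  pk <- encode_stream(codes, cfg)
  expect_identical(attr(pk, "n_saturated"), 0L)
  dec <- decode_stream(pk, cfg)
  err <- abs(dec$codes - codes)
  # reconstruct the per-sample shift bound from the per-window shifts
  w <- round(cfg$stats_window_s * cfg$fs)
  for (win in seq_len(ceiling(ncol(codes) / w))) {
    idx <- ((win - 1) * w + 1):min(ncol(codes), win * w)
    kf <- pk[[which(vapply(pk, function(p) p$keyframe, logical(1)))[win]]]
    bound <- ifelse(kf$shifts > 0, 2^(kf$shifts - 1), 0)
    expect_true(all(err[, idx] <= bound))
  }
})

test_that("streams with small differences and shift 0 are lossless", {
  cfg <- codec_config(payload_bits = 16, max_shift = 0)
  codes <- walk_codes(600, sd = 100, seed = 2)
  dec <- decode_stream(encode_stream(codes, cfg), cfg)
  expect_identical(dec$codes, unname(codes))
})

test_that("reconstruction recovers exactly at the first post-loss keyframe", {
  cfg <- codec_config()
  codes <- walk_codes(1250, sd = 400, seed = 13)
  pk <- encode_stream(codes, cfg)
  set.seed(99)
  for (rep in 1:5) {
    # keep the opening keyframe and the final packet (so the stream length
    # stays inferable; trailing loss is indistinguishable from stream end)
    drop <- sample(setdiff(seq_along(pk), c(1L, length(pk))), sample(1:6, 1))
    dec <- decode_stream(pk[-drop], cfg)
    expect_equal(dim(dec$codes), dim(codes))
    # after the last affected window's next keyframe, output is exact
    w <- round(cfg$stats_window_s * cfg$fs)
    ppw <- 1 + ceiling((w - 1) / cfg$samples_per_packet)
    last_lost_win <- max((drop - 1) %/% ppw)
    resync <- (last_lost_win + 1) * w + 1
    if (resync <= ncol(codes)) {
      expect_identical(dec$codes[, resync:ncol(codes)],
                       unname(attr(pk, "encoder_recon"))[, resync:ncol(codes)])
    }
    # flagged samples are exactly those covered by dropped delta packets
    expect_equal(sum(dec$lost),
                 sum(vapply(pk[drop], eegstream:::length_payload, integer(1))))
  }
})

test_that("stream-level codec matches the per-sample operations", {
  cfg <- codec_config(payload_bits = 14, max_shift = 6)
  codes <- walk_codes(500, sd = 2000, seed = 21)
  pk <- encode_stream(codes, cfg)
  recon <- attr(pk, "encoder_recon")
  w <- round(cfg$stats_window_s * cfg$fs)
  keyframes <- pk[vapply(pk, function(p) p$keyframe, logical(1))]
  for (ch in c(1, 12, 24)) {
    st <- channel_state()
    trace <- numeric(ncol(codes))
    for (t in seq_len(ncol(codes))) {
      win <- (t - 1) %/% w + 1
      if ((t - 1) %% w == 0) {        # keyframe sample: absolute
        st$prev_recon <- as.numeric(codes[ch, t])
      } else {
        st$shift <- keyframes[[win]]$shifts[ch]
        st <- encode_sample(st, codes[ch, t], cfg)$state
      }
      trace[t] <- st$prev_recon
    }
    expect_equal(trace, as.numeric(recon[ch, ]))
  }
})

test_that("sequence numbers wrap at 2^16 without confusing the decoder", {
  cfg <- codec_config()
  codes <- walk_codes(750, seed = 31)
  pk <- encode_stream(codes, cfg, first_seq = 65530L)
  expect_equal(pk[[8]]$seq, (65530 + 7) %% 65536)
  dec <- decode_stream(pk, cfg)
  expect_identical(dec$codes, unname(attr(pk, "encoder_recon")))
  expect_equal(dec$stats$packets_expected, length(pk))
})

test_that("loss accounting and the monitor's strict threshold behave", {
  s <- stream_stats(1000L, 970L)
  expect_equal(s$loss_fraction, 0.03)
  expect_true(loss_monitor(s, 0.01)$recommendation)
  expect_match(loss_monitor(s, 0.01)$message, "bits|sampling rate")
  expect_false(loss_monitor(stream_stats(100L, 100L))$recommendation)
  # exactly at threshold: strict inequality, no recommendation
  expect_false(loss_monitor(stream_stats(100L, 97L), 0.03)$recommendation)
})

test_that("malformed streams are rejected", {
  cfg <- codec_config()
  pk <- encode_stream(walk_codes(300), cfg)
  expect_error(decode_stream(pk[-1], cfg), "keyframe")
  bad <- pk
  bad[[2]]$payload[1, 1] <- 2^15
  expect_error(decode_stream(bad, cfg), "corruption")
  expect_error(codec_config(payload_bits = 12), "payload_bits")
  expect_error(codec_config(payload_bits = 16, max_shift = 10), "max_shift")
  expect_error(codec_config(safety_factor = 0.5), "safety_factor")
})

test_that("compression accounting: transmitted bits stay below the raw 24-bit stream", {
  cfg <- codec_config(payload_bits = 16)
  codes <- walk_codes(2500, seed = 17)     # 10 s at 250 Hz
  pk <- encode_stream(codes, cfg)
  # bits actually needed per second per channel: payload symbols + keyframe
  n_delta <- sum(vapply(pk, function(p) !p$keyframe, logical(1)) *
                   vapply(pk, eegstream:::length_payload, integer(1)))
  n_key <- sum(vapply(pk, function(p) p$keyframe, logical(1)))
  bits <- n_delta * cfg$payload_bits / 24 * 24 + n_key * (24 * 24 + 8 * 24)
  secs <- ncol(codes) / cfg$fs
  per_channel_per_s <- bits / 24 / secs
  expect_lt(per_channel_per_s, cfg$fs * 24)
})
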