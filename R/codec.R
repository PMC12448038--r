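#' Telemetry codec configuration
#'
#' Parameters of the adaptive delta-encoding codec. Each transmitted symbol
#' is a quantised first difference `round(d / 2^s)` in `payload_bits` signed
#' bits; the per-channel shift `s` adapts once per statistics window so that
#' single-sample changes up to `safety_factor` times the recent
#' first-difference standard deviation fit without truncation.
#'
#' @param payload_bits Bits per transmitted difference symbol, one of
#'   10, 14, 16. Default 16.
#' @param safety_factor Multiplier `f >= 1` on the windowed standard
#'   deviation defining the largest change that must remain representable.
#'   Default 8 (which buys four extra high-order bits over the baseline).
#' @param max_shift Upper clamp on the shift (`0 <= max_shift <=
#'   24 - payload_bits + 1`). Limiting the shift sacrifices artifact-sized
#'   jumps to preserve resolution. Default 8.
#' @param stats_window_s Statistics window in seconds (default 1): shift and
#'   sigma are refreshed once per window and announced in that window's
#'   keyframe.
#' @param samples_per_packet Delta-packet frame size (default 25, i.e. ten
#'   delta packets per second at 250 Hz so one lost packet costs <= 100 ms).
#' @param fs Stream rate in Hz (default 250).
#' @return An object of class `codec_config`.
#' @export
codec_config <- function(payload_bits = 16, safety_factor = 8, max_shift = 8,
                         stats_window_s = 1, samples_per_packet = 25,
                         fs = 250) {
  if (!payload_bits %in% c(10, 14, 16))
    stop("`payload_bits` must be one of 10, 14, 16", call. = FALSE)
  if (safety_factor < 1) stop("`safety_factor` must be >= 1", call. = FALSE)
  if (max_shift < 0 || max_shift > 24 - payload_bits + 1)
    stop(sprintf("`max_shift` must lie in [0, %d]", 24 - payload_bits + 1),
         call. = FALSE)
  if (stats_window_s <= 0 || fs <= 0)
    stop("`stats_window_s` and `fs` must be positive", call. = FALSE)
  if (samples_per_packet < 1 || samples_per_packet > 255)
    stop("`samples_per_packet` must be in [1, 255]", call. = FALSE)
  structure(list(payload_bits = as.integer(payload_bits),
                 safety_factor = safety_factor,
                 max_shift = as.integer(max_shift),
                 stats_window_s = stats_window_s,
                 samples_per_packet = as.integer(samples_per_packet),
                 fs = fs),
            class = "codec_config")
}

#' @export
print.codec_config <- function(x, ...) {
  cat(sprintf(paste0("<codec_config> b=%d bits, safety f=%g, max shift %d, ",
                     "%g s window, %d samples/packet @ %g Hz\n"),
              x$payload_bits, x$safety_factor, x$max_shift, x$stats_window_s,
              x$samples_per_packet, x$fs))
  invisible(x)
}

#' Per-channel codec state
#'
#' Tracks the closed-loop reconstruction, the floating signal average, the
#' windowed first-difference standard deviation and the active bit shift of
#' one channel.
#'
#' @param prev_recon Previous reconstructed 24-bit code (default 0).
#' @param running_mean Floating average of the signal, in codes.
#' @param sigma Standard deviation of the difference signal over the last
#'   statistics window, in codes (>= 0).
#' @param shift Current bit shift (integer >= 0).
#' @return An object of class `channel_state`.
#' @export
channel_state <- function(prev_recon = 0, running_mean = 0, sigma = 0,
                          shift = 0) {
  stopifnot(sigma >= 0, shift >= 0)
  structure(list(prev_recon = prev_recon, running_mean = running_mean,
                 sigma = sigma, shift = shift),
            class = "channel_state")
}

#' Refresh channel statistics from the last window
#'
#' Recomputes the floating average, the population standard deviation of the
#' first differences within the window, and the shift for the next window.
#'
#' @param state A [channel_state()].
#' @param window_codes Integer vector: the last statistics window of 24-bit
#'   codes (possibly shorter at stream start). Empty windows leave the state
#'   unchanged.
#' @param cfg A [codec_config()].
#' @return The updated `channel_state`.
#' @export
update_stats <- function(state, window_codes, cfg) {
  if (length(window_codes) == 0) return(state)
  state$running_mean <- mean(window_codes)
  if (length(window_codes) < 2) {
    state$sigma <- 0
  } else {
    d <- diff(window_codes)
    state$sigma <- sqrt(mean((d - mean(d))^2))  # population SD
  }
  state$shift <- select_shift(state$sigma, cfg)
  state
}

#' Minimal magnitude bits covering 0..limit
#'
#' The smallest `k` such that every value `v` with `0 <= v <= limit` fits in
#' `k` magnitude bits (`2^k - 1 >= limit`); 0 for `limit = 0`.
#'
#' @param limit Non-negative integer (vectorised).
#' @return Integer bit counts.
#' @export
bits_needed <- function(limit) {
  if (any(limit < 0)) stop("`limit` must be non-negative", call. = FALSE)
  ifelse(limit >= 1, floor(log2(limit)) + 1, 0L)
}

#' Select the per-channel bit shift
#'
#' The shift is the number of low-order bits dropped from each 24-bit
#' difference so that changes up to `safety_factor * sigma` stay
#' representable in `payload_bits - 1` magnitude bits:
#' `s = clamp(bits_needed(round(f * sigma)) - (payload_bits - 1), 0,
#' max_shift)`. Monotone non-decreasing in both `sigma` and `f`.
#'
#' @param sigma Windowed first-difference standard deviation in codes (>= 0).
#' @param cfg A [codec_config()].
#' @return Integer shift.
#' @export
select_shift <- function(sigma, cfg) {
  if (any(sigma < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  s <- bits_needed(round_half_away(cfg$safety_factor * sigma)) -
    (cfg$payload_bits - 1L)
  as.integer(pmin(pmax(s, 0L), cfg$max_shift))
}

#' Encode one sample against the closed-loop state
#'
#' Quantises the difference to the encoder's own previous reconstruction
#' (never the true previous sample, so quantisation error cannot
#' accumulate): `q = round((code - prev_recon) / 2^s)` saturated to
#' `+/-(2^(b-1) - 1)`; the state advances by `q * 2^s`.
#'
#' @param state A [channel_state()] (its `shift` is used).
#' @param code24 Signed 24-bit code to encode.
#' @param cfg A [codec_config()].
#' @return `list(symbol, state)` with the updated state.
#' @export
encode_sample <- function(state, code24, cfg) {
  s <- state$shift
  qmax <- 2^(cfg$payload_bits - 1) - 1
  d <- code24 - state$prev_recon
  q <- round_half_away(d / 2^s)
  q <- min(max(q, -qmax), qmax)
  state$prev_recon <- state$prev_recon + q * 2^s
  list(symbol = q, state = state)
}

#' Decode one difference symbol
#'
#' Mirrors [encode_sample()]: `code = prev_recon + symbol * 2^shift`. Over a
#' loss-free stream the decoder state is bit-identical to the encoder's.
#'
#' @param state A [channel_state()].
#' @param symbol Quantised difference symbol (within `payload_bits` signed
#'   range).
#' @param shift Bit shift in force for this symbol.
#' @param cfg A [codec_config()].
#' @return `list(code24, state)` with the updated state.
#' @export
decode_sample <- function(state, symbol, shift, cfg) {
  qmax <- 2^(cfg$payload_bits - 1) - 1
  if (abs(symbol) > qmax)
    stop("stream corruption: symbol exceeds payload width", call. = FALSE)
  code <- state$prev_recon + symbol * 2^shift
  state$prev_recon <- code
  list(code24 = code, state = state)
}

packets_per_window <- function(cfg) {
  w <- round(cfg$stats_window_s * cfg$fs)
  1L + as.integer(ceiling(max(w - 1L, 0L) / cfg$samples_per_packet))
}

#' Encode a code stream into framed packets
#'
#' Each statistics window (1 s by default) opens with a keyframe packet
#' carrying the absolute 24-bit codes of its first sample and the freshly
#' selected per-channel shifts; the remaining samples follow as delta
#' packets of quantised difference symbols (`samples_per_packet` each, the
#' last one in a window possibly shorter). Sequence numbers are consecutive
#' with 16-bit wraparound. The first window, having no prior statistics,
#' uses `max_shift` on all channels.
#'
#' @param codes Integer matrix, channels x time, signed 24-bit codes
#'   (24 rows for the device montage).
#' @param cfg A [codec_config()].
#' @param first_seq Sequence number of the first packet (default 0).
#' @return A list of packets (class `eeg_packet_stream`); attribute
#'   `n_saturated` counts clipped difference symbols.
#' @export
encode_stream <- function(codes, cfg, first_seq = 0L) {
  if (!is.matrix(codes)) stop("`codes` must be a channels x time matrix",
                              call. = FALSE)
  if (nrow(codes) != 24)
    stop(sprintf("channel count mismatch: expected 24 channels, got %d",
                 nrow(codes)), call. = FALSE)
  n <- ncol(codes)
  out <- list()
  if (n == 0) return(structure(out, class = "eeg_packet_stream",
                               n_saturated = 0L))
  storage.mode(codes) <- "integer"
  w <- round(cfg$stats_window_s * cfg$fs)
  core <- .codec_encode_core(codes, cfg$payload_bits, cfg$safety_factor,
                             cfg$max_shift, w, cfg$max_shift)
  spp <- cfg$samples_per_packet
  seq_no <- as.integer(first_seq)
  nwin <- ncol(core$shifts)
  for (win in seq_len(nwin)) {
    t0 <- (win - 1L) * w + 1L
    t1 <- min(n, t0 + w - 1L)
    shifts <- core$shifts[, win]
    out[[length(out) + 1L]] <- structure(
      list(seq = seq_no, keyframe = TRUE, shifts = unname(shifts),
           payload = unname(codes[, t0])),
      class = "eeg_packet")
    seq_no <- (seq_no + 1L) %% 65536L
    t <- t0 + 1L
    while (t <= t1) {
      te <- min(t1, t + spp - 1L)
      out[[length(out) + 1L]] <- structure(
        list(seq = seq_no, keyframe = FALSE, shifts = unname(shifts),
             payload = core$symbols[, t:te, drop = FALSE]),
        class = "eeg_packet")
      seq_no <- (seq_no + 1L) %% 65536L
      t <- te + 1L
    }
  }
  structure(out, class = "eeg_packet_stream",
            n_saturated = core$n_saturated,
            encoder_recon = core$recon)
}

#' Decode a (possibly gapped) packet stream
#'
#' Packets must arrive in order; gaps are detected from the sequence
#' numbers. Samples covered by a lost delta packet hold the last
#' reconstructed value and are flagged; reconstruction resynchronises
#' exactly at the next received keyframe. The stream must open with a
#' keyframe.
#'
#' @param packets A list of packets as produced by [encode_stream()] (gaps
#'   allowed).
#' @param cfg The [codec_config()] the stream was encoded with (frame
#'   layout: window length and samples per packet).
#' @return `list(codes, lost, stats)`: the reconstructed channels x time
#'   integer matrix, a logical per-sample loss flag, and a `stream_stats`
#'   list (`packets_expected`, `packets_received`, `loss_fraction`,
#'   `recommendation`).
#' @export
decode_stream <- function(packets, cfg) {
  if (length(packets) == 0)
    return(list(codes = matrix(integer(), 24, 0), lost = logical(),
                stats = stream_stats(0L, 0L)))
  if (!isTRUE(packets[[1]]$keyframe))
    stop("stream error: first packet is not a keyframe", call. = FALSE)
  w <- round(cfg$stats_window_s * cfg$fs)
  spp <- cfg$samples_per_packet
  ppw <- packets_per_window(cfg)
  s0 <- packets[[1]]$seq
  # global packet index (sequence arithmetic with 16-bit wraparound)
  pidx <- integer(length(packets))
  prev_seq <- s0
  acc <- 0L
  for (i in seq_along(packets)) {
    dseq <- (packets[[i]]$seq - prev_seq) %% 65536L
    if (i > 1L && dseq == 0L)
      stop("stream error: duplicate or non-monotone sequence number",
           call. = FALSE)
    acc <- acc + dseq
    pidx[i] <- acc
    prev_seq <- packets[[i]]$seq
  }
  # packet index -> first sample index (1-based) it covers
  pkt_start <- function(p) {
    win <- p %/% ppw
    r <- p %% ppw
    if (r == 0L) win * w + 1L else win * w + 1L + 1L + (r - 1L) * spp
  }
  last <- length(packets)
  n <- pkt_start(pidx[last]) + length_payload(packets[[last]]) - 1L
  codes <- matrix(0L, 24, n)
  lost <- rep(TRUE, n)
  prev <- rep(0, 24)
  have_key <- FALSE
  for (i in seq_along(packets)) {
    pk <- packets[[i]]
    t0 <- pkt_start(pidx[i])
    if (isTRUE(pk$keyframe)) {
      prev <- as.numeric(pk$payload)
      codes[, t0] <- as.integer(prev)
      lost[t0] <- FALSE
      have_key <- TRUE
    } else {
      qmax <- 2^(cfg$payload_bits - 1) - 1
      if (any(abs(pk$payload) > qmax))
        stop("stream corruption: symbol exceeds payload width", call. = FALSE)
      step <- 2^pk$shifts
      nspl <- ncol(pk$payload)
      inc <- pk$payload * step               # recycled per column
      rec <- matrixStats_rowCumsum(inc) + prev
      codes[, t0:(t0 + nspl - 1L)] <- as.integer(rec)
      lost[t0:(t0 + nspl - 1L)] <- FALSE
      prev <- rec[, nspl]
    }
  }
  # fill lost samples by holding the last reconstructed value
  if (any(lost)) {
    for (t in seq_len(n)) {
      if (lost[t] && t > 1L) codes[, t] <- codes[, t - 1L]
    }
  }
  expected <- pidx[last] + 1L
  stats <- stream_stats(expected, length(packets))
  list(codes = codes, lost = lost, stats = stats)
}

length_payload <- function(pk) {
  if (isTRUE(pk$keyframe)) 1L else ncol(pk$payload)
}

# row-wise cumulative sum (channels x samples)
matrixStats_rowCumsum <- function(x) {
  if (ncol(x) == 1L) return(x)
  t(apply(x, 1L, cumsum))
}

#' Stream loss statistics
#'
#' Loss accounting from sequence arithmetic: `loss_fraction = 1 -
#' received / expected`.
#'
#' @param packets_expected Expected packet count from the sequence span.
#' @param packets_received Packets actually received.
#' @return A `stream_stats` list.
#' @export
stream_stats <- function(packets_expected, packets_received) {
  lf <- if (packets_expected > 0)
    (packets_expected - packets_received) / packets_expected else 0
  structure(list(packets_expected = as.integer(packets_expected),
                 packets_received = as.integer(packets_received),
                 loss_fraction = lf),
            class = "stream_stats")
}

#' @export
print.stream_stats <- function(x, ...) {
  cat(sprintf("<stream_stats> %d/%d packets received, loss %.2f%%\n",
              x$packets_received, x$packets_expected, 100 * x$loss_fraction))
  invisible(x)
}

#' Packet-loss monitor
#'
#' Raises a settings recommendation when the observed loss fraction exceeds
#' the threshold (strictly): lowering the payload width or the sampling rate
#' reduces the radio load.
#'
#' @param stats A [stream_stats()] (or the `stats` element of
#'   [decode_stream()] output).
#' @param threshold Loss fraction above which to recommend a settings
#'   change. Default 0.01.
#' @return `list(recommendation, loss_fraction, message)`.
#' @export
loss_monitor <- function(stats, threshold = 0.01) {
  rec <- stats$loss_fraction > threshold
  msg <- if (rec) {
    sprintf(paste0("%.1f%% of packets lost: consider lowering the bits per ",
                   "channel (payload_bits) or the sampling rate to reduce ",
                   "the transmission load"),
            100 * stats$loss_fraction)
  } else {
    sprintf("packet loss %.1f%% within tolerance", 100 * stats$loss_fraction)
  }
  list(recommendation = rec, loss_fraction = stats$loss_fraction,
       message = msg)
}
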