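#' Eyes-open/eyes-closed block protocol
#'
#' The validation protocol: alternating blocks of eyes-closed and eyes-open
#' rest. The defaults reproduce the study conditions — five cycles of
#' 2-minute eyes-closed / 2-minute eyes-open (20 minutes total), starting
#' eyes-closed.
#'
#' @param block_s Block duration in seconds (default 120).
#' @param n_cycles Number of closed+open repetitions (default 5).
#' @param first Starting condition (default `"eyes_closed"`).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(block_s = 120, n_cycles = 5,
                          first = c("eyes_closed", "eyes_open")) {
  first <- match.arg(first)
  if (block_s <= 0 || n_cycles <= 0)
    stop("`block_s` and `n_cycles` must be positive", call. = FALSE)
  structure(list(block_s = block_s, n_cycles = as.integer(n_cycles),
                 first = first),
            class = "protocol_spec")
}

#' Per-sample condition timeline
#'
#' @param spec A [protocol_spec()].
#' @param fs Sampling rate in Hz.
#' @return Character vector of `"eyes_closed"` / `"eyes_open"` labels of
#'   length `2 * block_s * n_cycles * fs`.
#' @export
make_protocol <- function(spec, fs = 250) {
  other <- setdiff(c("eyes_closed", "eyes_open"), spec$first)
  block <- round(spec$block_s * fs)
  rep(rep(c(spec$first, other), times = spec$n_cycles), each = block)
}

#' Synthetic signal parameters
#'
#' Amplitudes and rates of the synthetic EEG content. The defaults are
#' physiologically plausible resting-EEG magnitudes: a 10 uV RMS 1/f (pink)
#' background on every channel, 20 uV peak ~10 Hz alpha on the
#' occipital/parietal group during eyes-closed (parietal channels at half
#' amplitude, giving the spatially spread posterior topography), 15 uV RMS
#' frontal delta plus 100 uV blink transients during eyes-open, and an
#' optional common 50 Hz mains component.
#'
#' @param alpha_hz Alpha centre frequency (8-12 Hz; default 10).
#' @param alpha_amp_uv Occipital alpha peak amplitude in uV (default 20).
#' @param alpha_channels Channels carrying alpha (default POZ, O1, OZ, O2
#'   at full amplitude and P3, PZ, P4 at half).
#' @param delta_amp_uv Frontal delta RMS amplitude during eyes-open
#'   (default 15).
#' @param blink_rate_hz Mean blink rate during eyes-open (default 0.25/s).
#' @param blink_amp_uv Blink peak amplitude on the frontopolar channels
#'   (default 100).
#' @param pink_amp_uv 1/f background RMS per channel (default 10).
#' @param line_hz Mains frequency (default 50).
#' @param line_amp_uv Mains amplitude on all channels (default 5; 0
#'   disables).
#' @param seed Random seed for the generator (default 1).
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(alpha_hz = 10, alpha_amp_uv = 20,
                          alpha_channels = c("POZ", "O1", "OZ", "O2",
                                             "P3", "PZ", "P4"),
                          delta_amp_uv = 15, blink_rate_hz = 0.25,
                          blink_amp_uv = 100, pink_amp_uv = 10,
                          line_hz = 50, line_amp_uv = 5, seed = 1) {
  if (alpha_hz < 8 || alpha_hz > 12)
    stop("`alpha_hz` must lie within 8-12 Hz", call. = FALSE)
  amps <- c(alpha_amp_uv, delta_amp_uv, blink_amp_uv, pink_amp_uv,
            line_amp_uv, blink_rate_hz)
  if (any(amps < 0)) stop("amplitudes and rates must be >= 0", call. = FALSE)
  structure(list(alpha_hz = alpha_hz, alpha_amp_uv = alpha_amp_uv,
                 alpha_channels = alpha_channels,
                 delta_amp_uv = delta_amp_uv, blink_rate_hz = blink_rate_hz,
                 blink_amp_uv = blink_amp_uv, pink_amp_uv = pink_amp_uv,
                 line_hz = line_hz, line_amp_uv = line_amp_uv, seed = seed),
            class = "signal_params")
}

# 1/f-amplitude ("pink") noise via spectral shaping, exact target RMS
pink_noise <- function(n, rms) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)                 # two-sided bin distance from DC
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# band-limited gaussian noise (for the frontal delta walk), target RMS
bandlimited_noise <- function(n, fs, lo, hi, rms) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# contiguous runs of a condition label -> two-column matrix (start, end)
condition_spans <- function(conditions, label) {
  r <- rle(conditions == label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Generate a synthetic eyes-open/eyes-closed recording
#'
#' Builds a 24-channel recording emulating the validation experiment: pink
#' background everywhere; alpha (with slow amplitude/frequency jitter) on
#' the posterior channels while eyes are closed; frontal delta drift and
#' Poisson-placed blink transients while eyes are open; an optional common
#' mains sinusoid. Identical parameters (including `seed`) give bit-identical
#' output; the generator uses R's default Mersenne-Twister stream seeded
#' once at entry.
#'
#' @param protocol A [protocol_spec()].
#' @param montage Montage data.frame (default [montage_1020_24()]).
#' @param params A [signal_params()].
#' @param fs Sampling rate in Hz (default 250).
#' @return A [raw_recording()] in volts with per-sample condition labels.
#' @export
generate_recording <- function(protocol = protocol_spec(),
                               montage = montage_1020_24(),
                               params = signal_params(), fs = 250) {
  unknown <- setdiff(params$alpha_channels, montage$label)
  if (length(unknown))
    stop("unknown channel labels in params: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  conditions <- make_protocol(protocol, fs)
  n <- length(conditions)
  nch <- nrow(montage)
  set.seed(params$seed)
  uv <- matrix(0, nch, n, dimnames = list(montage$label, NULL))
  for (ch in seq_len(nch)) uv[ch, ] <- pink_noise(n, params$pink_amp_uv)

  # posterior alpha during eyes-closed (smooth gain + frequency jitter)
  closed <- conditions == "eyes_closed"
  if (params$alpha_amp_uv > 0 && any(closed)) {
    occipital <- c("POZ", "O1", "OZ", "O2")
    for (lab in params$alpha_channels) {
      w <- if (lab %in% occipital) 1 else 0.5
      fjit <- bandlimited_noise(n, fs, 0.01, 0.2, rms = 0.15)
      ajit <- pmax(1 + bandlimited_noise(n, fs, 0.01, 0.3, rms = 0.25), 0)
      phase <- 2 * pi * cumsum(params$alpha_hz + fjit) / fs +
        stats::runif(1, 0, 2 * pi)
      uv[lab, closed] <- uv[lab, closed] +
        (w * params$alpha_amp_uv * ajit * sin(phase))[closed]
    }
  }

  # frontal delta drift during eyes-open
  open <- conditions == "eyes_open"
  if (params$delta_amp_uv > 0 && any(open)) {
    for (lab in intersect(c("FP1", "FPZ", "FP2"), montage$label)) {
      d <- bandlimited_noise(n, fs, 0.5, 4, rms = params$delta_amp_uv)
      uv[lab, open] <- uv[lab, open] + d[open]
    }
  }

  rec <- raw_recording(uv * 1e-6, fs, montage, conditions)
  rec <- add_blinks(rec, params$blink_rate_hz, params$blink_amp_uv)
  if (params$line_amp_uv > 0)
    rec <- add_line_noise(rec, params$line_hz, params$line_amp_uv)
  rec
}

#' Add a common mains sinusoid
#'
#' Adds a single common-phase sinusoid (`line_hz`) to every channel,
#' emulating power-line pickup.
#'
#' @param rec A [raw_recording()].
#' @param line_hz Mains frequency (must be below `fs/2`).
#' @param amp_uv Amplitude in uV (0 returns `rec` unchanged).
#' @return The recording with the line component added.
#' @export
add_line_noise <- function(rec, line_hz = 50, amp_uv = 5) {
  if (amp_uv == 0) return(rec)
  if (line_hz >= rec$fs / 2)
    stop("`line_hz` must be below the Nyquist rate", call. = FALSE)
  t <- (seq_len(ncol(rec$samples)) - 1) / rec$fs
  rec$samples <- rec$samples +
    rep(amp_uv * 1e-6 * sin(2 * pi * line_hz * t),
        each = nrow(rec$samples))
  rec
}

#' Add blink transients during eyes-open spans
#'
#' Places Poisson-distributed smooth biphasic transients (~300 ms) on the
#' frontopolar channels, restricted to eyes-open spans (a blink is only
#' started where its full waveform fits inside the span). Blink onsets are
#' recorded in the `blink_onsets` attribute.
#'
#' @param rec A [raw_recording()] with condition labels.
#' @param rate_hz Mean blink rate per second of eyes-open time (>= 0).
#' @param amp_uv Peak amplitude in uV on the target channels.
#' @param channels Target channels (default FP1, FPZ, FP2).
#' @return The recording with blinks added.
#' @export
add_blinks <- function(rec, rate_hz = 0.25, amp_uv = 100,
                       channels = c("FP1", "FPZ", "FP2")) {
  if (rate_hz < 0) stop("`rate_hz` must be >= 0", call. = FALSE)
  if (rate_hz == 0 || amp_uv == 0 || is.null(rec$conditions)) {
    attr(rec, "blink_onsets") <- integer(0)
    return(rec)
  }
  fs <- rec$fs
  spans <- condition_spans(rec$conditions, "eyes_open")
  if (nrow(spans) == 0) {
    attr(rec, "blink_onsets") <- integer(0)
    return(rec)
  }
  blink_len <- round(0.3 * fs)
  tt <- seq_len(blink_len) / blink_len
  wave <- sin(2 * pi * tt) * sin(pi * tt)^2    # smooth, biphasic, zero ends
  wave <- wave / max(abs(wave))
  open_s <- sum(spans[, "end"] - spans[, "start"] + 1) / fs
  n_blinks <- stats::rpois(1, rate_hz * open_s)
  # candidate onsets: eyes-open samples where the full wave fits in-span
  ok <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    if (spans[i, "end"] - spans[i, "start"] + 1 < blink_len) return(integer(0))
    spans[i, "start"]:(spans[i, "end"] - blink_len + 1L)
  }))
  n_blinks <- min(n_blinks, length(ok))
  onsets <- sort(sample(ok, n_blinks))
  chans <- intersect(channels, rownames(rec$samples))
  for (on in onsets) {
    idx <- on:(on + blink_len - 1L)
    for (lab in chans)
      rec$samples[lab, idx] <- rec$samples[lab, idx] + amp_uv * 1e-6 * wave
  }
  attr(rec, "blink_onsets") <- onsets
  rec
}
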