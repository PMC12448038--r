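#' Filter specification from the device menu
#'
#' The firmware offers a fixed menu of IIR (Butterworth) designs at the
#' 500 Hz acquisition rate: high-pass 0.8 Hz order 2, 1.0 Hz order 4,
#' 1.7 Hz order 4 or 2; low-pass 45 Hz order 4 or 60 Hz order 6; band-stop
#' 46-54 Hz or 48-52 Hz at (total) order 6 or 4; each stage may also be
#' `"off"`. For a band-stop stage `order` is the total polynomial order
#' (an order-6 band-stop is a 3rd-order low-pass prototype mirrored around
#' the stop band).
#'
#' @param kind One of `"high_pass"`, `"low_pass"`, `"band_stop"`, `"off"`.
#' @param cutoff_hz One edge (HP/LP) or two edges (band-stop), in Hz.
#' @param order Filter order (total order for band-stop).
#' @param unvalidated Allow a specification outside the device menu.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind, cutoff_hz = NULL, order = NULL,
                        unvalidated = FALSE) {
  kind <- match.arg(kind, c("high_pass", "low_pass", "band_stop", "off"))
  if (kind == "off")
    return(structure(list(kind = "off", cutoff_hz = NULL, order = NULL),
                     class = "filter_spec"))
  spec <- structure(list(kind = kind, cutoff_hz = cutoff_hz,
                         order = as.integer(order)),
                    class = "filter_spec")
  if (!unvalidated && !spec_in_menu(spec))
    stop(sprintf("filter %s is not in the device menu (use unvalidated = TRUE to override)",
                 format(spec)), call. = FALSE)
  if (kind == "band_stop") {
    if (length(cutoff_hz) != 2 || diff(cutoff_hz) <= 0)
      stop("band-stop needs two increasing edges", call. = FALSE)
    if (spec$order %% 2 != 0)
      stop("band-stop total order must be even", call. = FALSE)
  } else if (length(cutoff_hz) != 1) {
    stop("high/low-pass needs a single cutoff", call. = FALSE)
  }
  spec
}

#' @export
format.filter_spec <- function(x, ...) {
  if (x$kind == "off") return("off")
  sprintf("%s %s Hz order %d", x$kind, paste(x$cutoff_hz, collapse = "-"),
          x$order)
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec>", format(x), "\n")
  invisible(x)
}

#' The device filter menu
#'
#' @return A list with elements `high_pass`, `low_pass`, `band_stop`, each a
#'   list of `filter_spec`s.
#' @export
filter_menu <- function() {
  hp <- list(c(0.8, 2), c(1.0, 4), c(1.7, 4), c(1.7, 2))
  lp <- list(c(45, 4), c(60, 6))
  bs <- list(list(c(46, 54), 6), list(c(46, 54), 4),
             list(c(48, 52), 6), list(c(48, 52), 4))
  list(
    high_pass = lapply(hp, function(p) filter_spec("high_pass", p[1], p[2])),
    low_pass = lapply(lp, function(p) filter_spec("low_pass", p[1], p[2])),
    band_stop = lapply(bs, function(p) filter_spec("band_stop", p[[1]], p[[2]]))
  )
}

spec_in_menu <- function(spec) {
  menu <- switch(spec$kind,
    high_pass = list(c(0.8, 2), c(1.0, 4), c(1.7, 4), c(1.7, 2)),
    low_pass = list(c(45, 4), c(60, 6)),
    band_stop = list(list(c(46, 54), 6), list(c(46, 54), 4),
                     list(c(48, 52), 6), list(c(48, 52), 4)),
    return(TRUE))
  for (m in menu) {
    co <- if (is.list(m)) m[[1]] else m[1]
    or <- if (is.list(m)) m[[2]] else m[2]
    if (isTRUE(all.equal(unname(spec$cutoff_hz), co)) && spec$order == or)
      return(TRUE)
  }
  FALSE
}

#' Design a menu filter as Butterworth coefficients
#'
#' Butterworth of the stated order (`-3 dB` at each cutoff, the Butterworth
#' definition); band-stop order counts the total polynomial order. All
#' designs are checked for stability (every pole strictly inside the unit
#' circle) at construction.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate the filter runs at, in Hz (cutoffs must be below
#'   `fs/2`).
#' @return A list with `b`, `a` polynomial coefficients, the `spec` and
#'   `fs`; `NULL` for an `"off"` spec.
#' @export
design_filter <- function(spec, fs) {
  if (spec$kind == "off") return(NULL)
  if (any(spec$cutoff_hz >= fs / 2))
    stop("cutoff at or above Nyquist", call. = FALSE)
  wn <- spec$cutoff_hz / (fs / 2)
  ba <- switch(spec$kind,
    high_pass = signal::butter(spec$order, wn, type = "high"),
    low_pass = signal::butter(spec$order, wn, type = "low"),
    band_stop = signal::butter(spec$order / 2L, wn, type = "stop"))
  poles <- polyroot(rev(ba$a))
  if (any(Mod(poles) >= 1 - 1e-9))
    stop(sprintf("unstable design: %s at fs=%g", format(spec), fs),
         call. = FALSE)
  list(b = ba$b, a = ba$a, spec = spec, fs = fs)
}

#' The default filter chain
#'
#' High-pass 1 Hz order 4, low-pass 45 Hz order 4, band-stop 46-54 Hz order
#' 6, designed at the acquisition rate (500 Hz by default) and applied in
#' that order before decimation.
#'
#' @param fs_in Design rate in Hz (default 500).
#' @return A `filter_chain`.
#' @export
default_chain <- function(fs_in = 500) {
  filter_chain(hp = filter_spec("high_pass", 1.0, 4),
               lp = filter_spec("low_pass", 45, 4),
               bs = filter_spec("band_stop", c(46, 54), 6),
               fs_in = fs_in)
}

#' Assemble a filter chain
#'
#' @param hp,lp,bs [filter_spec()]s (use `filter_spec("off")` to disable a
#'   stage).
#' @param fs_in Design rate in Hz.
#' @return An object of class `filter_chain` holding the designed
#'   coefficient sets; stability of every stage is verified.
#' @export
filter_chain <- function(hp = filter_spec("off"), lp = filter_spec("off"),
                         bs = filter_spec("off"), fs_in = 500) {
  structure(list(hp = design_filter(hp, fs_in),
                 lp = design_filter(lp, fs_in),
                 bs = design_filter(bs, fs_in),
                 fs_in = fs_in),
            class = "filter_chain")
}

#' @export
print.filter_chain <- function(x, ...) {
  fmt <- function(f) if (is.null(f)) "off" else format(f$spec)
  cat(sprintf("<filter_chain> @ %g Hz: HP %s | LP %s | BS %s\n", x$fs_in,
              fmt(x$hp), fmt(x$lp), fmt(x$bs)))
  invisible(x)
}

#' Complex frequency response of a chain
#'
#' @param chain A [filter_chain()].
#' @param f Frequencies in Hz.
#' @return Complex response of the cascade at `f`.
#' @export
chain_response <- function(chain, f) {
  z <- exp(-2i * pi * f / chain$fs_in)
  h <- rep(1 + 0i, length(f))
  for (stage in list(chain$hp, chain$lp, chain$bs)) {
    if (is.null(stage)) next
    num <- vapply(seq_along(f), function(i)
      sum(stage$b * z[i]^(seq_along(stage$b) - 1)), complex(1))
    den <- vapply(seq_along(f), function(i)
      sum(stage$a * z[i]^(seq_along(stage$a) - 1)), complex(1))
    h <- h * num / den
  }
  h
}

#' Apply a filter chain causally
#'
#' Forward-only (causal) filtering per channel in the order HP -> LP -> BS,
#' matching the streaming firmware; `zero_phase = TRUE` switches to offline
#' forward-backward filtering.
#'
#' @param chain A [filter_chain()].
#' @param x Numeric vector, channels x time matrix, or [raw_recording()]
#'   sampled at `chain$fs_in`.
#' @param fs Sampling rate of `x` (taken from the recording if omitted);
#'   must equal the chain design rate.
#' @param zero_phase Use `signal::filtfilt` instead of causal filtering.
#' @return Filtered data of the same shape (a `raw_recording` in, a
#'   `raw_recording` out), with attribute `filtered = TRUE`.
#' @export
apply_chain <- function(chain, x, fs = NULL, zero_phase = FALSE) {
  if (inherits(x, "raw_recording")) {
    out <- x
    out$samples <- apply_chain(chain, x$samples, fs = x$fs,
                               zero_phase = zero_phase)
    attr(out, "filtered") <- TRUE
    return(out)
  }
  if (is.null(fs))
    stop("supply `fs` when filtering a bare matrix/vector", call. = FALSE)
  if (!isTRUE(all.equal(fs, chain$fs_in)))
    stop(sprintf("rate mismatch: data at %g Hz, chain designed at %g Hz",
                 fs, chain$fs_in), call. = FALSE)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  run <- function(stage, sig) {
    if (is.null(stage)) return(sig)
    if (zero_phase)
      signal::filtfilt(signal::Arma(b = stage$b, a = stage$a), sig)
    else
      as.numeric(signal::filter(signal::Arma(b = stage$b, a = stage$a), sig))
  }
  for (stage in list(chain$hp, chain$lp, chain$bs)) {
    if (is.null(stage)) next
    for (ch in seq_len(nrow(x))) x[ch, ] <- run(stage, x[ch, ])
  }
  if (vec) x <- drop(x)
  attr(x, "filtered") <- TRUE
  x
}

#' Decimate a 500 Hz stream to 250 or 167 Hz
#'
#' Keeps sample 1 and every 2nd (250 Hz) or 3rd (167 Hz) sample thereafter.
#' No extra anti-alias stage is added: the chain's low-pass (<= 60 Hz) is
#' assumed to have been applied; decimating data without the `filtered`
#' attribute logs a warning.
#'
#' @param x Channels x time matrix (or vector) at 500 Hz, or a
#'   [raw_recording()].
#' @param target Target rate: 250 or 167.
#' @return Downsampled data (`floor(n/2)` resp. `floor(n/3)` samples,
#'   keeping the first).
#' @export
decimate_stream <- function(x, target = 250) {
  if (!target %in% c(250, 167))
    stop("`target` must be 250 or 167", call. = FALSE)
  k <- if (target == 250) 2L else 3L
  if (inherits(x, "raw_recording")) {
    out <- x
    keep <- seq(1L, ncol(x$samples), by = k)
    if (is.null(attr(x, "filtered")))
      warning("decimating a recording without prior low-pass filtering")
    out$samples <- x$samples[, keep, drop = FALSE]
    if (!is.null(x$conditions)) out$conditions <- x$conditions[keep]
    out$fs <- x$fs / k
    return(out)
  }
  if (is.null(attr(x, "filtered")))
    warning("decimating data without prior low-pass filtering")
  if (is.matrix(x)) x[, seq(1L, ncol(x), by = k), drop = FALSE]
  else x[seq(1L, length(x), by = k)]
}

#' Sweep-test harness: filtered vs unfiltered power ratio
#'
#' Injects a linear frequency sweep, runs it through a chain (and a
#' reference chain, by default all-off) and returns the per-frequency-bin
#' power ratio, estimated by Welch averaging. With the default chain the
#' ratio at 50 Hz is the notch attenuation; with all stages off the ratio
#' is ~1 everywhere in band.
#'
#' @param chain_on The chain under test.
#' @param chain_off Reference chain (default: all stages off at the same
#'   rate).
#' @param f_lo,f_hi Sweep range in Hz (default 1-70).
#' @param fs Sampling rate (default 500).
#' @param dur_s Sweep duration in seconds (default 120; longer sweeps give
#'   cleaner per-bin estimates).
#' @return A data.frame with `freq_hz` and `power_ratio`
#'   (filtered/unfiltered), restricted to the sweep range.
#' @export
sweep_attenuation <- function(chain_on, chain_off = NULL, f_lo = 1,
                              f_hi = 70, fs = 500, dur_s = 120) {
  if (is.null(chain_off)) chain_off <- filter_chain(fs_in = fs)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  # linear chirp f_lo -> f_hi
  phase <- 2 * pi * (f_lo * t + (f_hi - f_lo) * t^2 / (2 * dur_s))
  x <- sin(phase)
  y_on <- apply_chain(chain_on, x, fs = fs)
  y_off <- apply_chain(chain_off, x, fs = fs)
  p_on <- welch_psd(y_on, fs, seg_s = 2)
  p_off <- welch_psd(y_off, fs, seg_s = 2)
  keep <- p_on$freq_hz >= f_lo & p_on$freq_hz <= f_hi
  data.frame(freq_hz = p_on$freq_hz[keep],
             power_ratio = p_on$power[keep] / pmax(p_off$power[keep],
                                                   .Machine$double.xmin))
}

# Hann-windowed, 50%-overlap segment-averaged periodogram
welch_psd <- function(x, fs, seg_s = 2) {
  nseg <- round(seg_s * fs)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  win <- win / sqrt(mean(win^2))
  starts <- seq(1, length(x) - nseg + 1, by = nseg %/% 2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * win
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc[seq_len(nseg %/% 2 + 1)] / (length(starts) * nseg * fs)
  data.frame(freq_hz = (seq_len(nseg %/% 2 + 1) - 1) * fs / nseg, power = p)
}
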