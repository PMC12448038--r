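#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the `K` leading DPSS tapers of length `n` at time-bandwidth
#' product `nw`, via the classical symmetric tridiagonal eigenproblem
#' (Sturm-sequence bisection for the leading eigenvalues, inverse
#' iteration for the eigenvectors). Tapers are unit-energy and mutually
#' orthogonal; results are cached per `(n, nw, K)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (`T * W` in cycles).
#' @param K Number of tapers (`K <= 2 * nw` for well-concentrated tapers).
#' @return An `n x K` matrix, leading taper first.
#' @export
dpss_tapers <- function(n, nw, K) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, K)
  hit <- .eegstream_cache[[key]]
  if (!is.null(hit)) return(hit)
  tap <- .dpss_core(as.integer(n), nw, as.integer(K))
  .eegstream_cache[[key]] <- tap
  tap
}

#' Segment a recording into fixed-length epochs per condition
#'
#' Cuts consecutive, non-overlapping epochs inside each condition block;
#' partial tail segments of a block are discarded and no epoch spans a
#' condition boundary. With the default 20-minute protocol and 30-s epochs
#' this yields 40 epochs (20 per condition).
#'
#' @param rec A [raw_recording()] with condition labels.
#' @param epoch_s Epoch length in seconds (default 30).
#' @return A named list of `epoch_set` objects (one per condition present),
#'   each with `epochs` (epoch x channel x time array), `fs`, `epoch_s`,
#'   `condition` and `channels`.
#' @export
epoch_recording <- function(rec, epoch_s = 30) {
  if (is.null(rec$conditions))
    stop("recording has no condition labels", call. = FALSE)
  ne <- round(epoch_s * rec$fs)
  out <- list()
  for (cond in c("eyes_closed", "eyes_open")) {
    spans <- condition_spans(rec$conditions, cond)
    if (nrow(spans) == 0) next
    if (all(spans[, "end"] - spans[, "start"] + 1 < ne))
      stop(sprintf("epoch length %g s exceeds every %s block", epoch_s, cond),
           call. = FALSE)
    pieces <- list()
    for (i in seq_len(nrow(spans))) {
      len <- spans[i, "end"] - spans[i, "start"] + 1L
      for (k in seq_len(len %/% ne)) {
        t0 <- spans[i, "start"] + (k - 1L) * ne
        pieces[[length(pieces) + 1L]] <-
          rec$samples[, t0:(t0 + ne - 1L), drop = FALSE]
      }
    }
    arr <- array(0, dim = c(length(pieces), nrow(rec$samples), ne))
    for (i in seq_along(pieces)) arr[i, , ] <- pieces[[i]]
    out[[cond]] <- structure(
      list(condition = cond, epochs = arr, fs = rec$fs, epoch_s = epoch_s,
           channels = rownames(rec$samples)),
      class = "epoch_set")
  }
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs x %d channels x %g s @ %g Hz\n",
              x$condition, dim(x$epochs)[1], dim(x$epochs)[2], x$epoch_s,
              x$fs))
  invisible(x)
}

#' Multitaper power spectral density per epoch and channel
#'
#' Thomson multitaper estimate: DPSS tapers at half-bandwidth
#' `smoothing_hz` (time-bandwidth product `T * smoothing_hz`), using
#' `K = floor(2 * T * W) - 1` tapers, eigenspectra averaged with equal
#' weights. Spectra are one-sided densities in uV^2/Hz on the grid of a
#' power-of-two zero-padded FFT, from 0 to `fs/2`.
#'
#' @param epochs An `epoch_set` from [epoch_recording()] (voltages in
#'   volts).
#' @param smoothing_hz Spectral half-bandwidth W in Hz (default 1).
#' @return A `spectrum_set`: `power` (epoch x channel x frequency,
#'   uV^2/Hz), `freqs` (Hz), `channels`, and taper metadata.
#' @export
psd_multitaper <- function(epochs, smoothing_hz = 1) {
  dims <- dim(epochs$epochs)
  nep <- dims[1]; nch <- dims[2]; n <- dims[3]
  T_s <- n / epochs$fs
  K <- floor(2 * T_s * smoothing_hz) - 1
  if (K < 1)
    stop(sprintf(paste0("smoothing half-bandwidth %g Hz is too small for ",
                        "%g-s epochs (needs at least 1/T Hz)"),
                 smoothing_hz, T_s), call. = FALSE)
  tap <- dpss_tapers(n, T_s * smoothing_hz, K)
  nfft <- 2^ceiling(log2(n))
  # columns = epoch-major, channel-minor series, in uV
  x <- matrix(aperm(epochs$epochs, c(3, 1, 2)), nrow = n) * 1e6
  acc <- .mtm_accum(x, tap, as.integer(nfft))
  nf <- nfft / 2 + 1
  psd <- acc / epochs$fs
  psd[2:(nf - 1), ] <- 2 * psd[2:(nf - 1), ]      # one-sided doubling
  power <- aperm(array(psd, dim = c(nf, nep, nch)), c(2, 3, 1))
  structure(list(power = power,
                 freqs = (seq_len(nf) - 1) * epochs$fs / nfft,
                 channels = epochs$channels, condition = epochs$condition,
                 fs = epochs$fs, n_tapers = K, nw = T_s * smoothing_hz,
                 nfft = nfft),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(paste0("<spectrum_set> %s: %d epochs x %d channels x %d bins ",
                     "(0-%g Hz, %d tapers, NW=%g)\n"),
              x$condition %||% "?", dim(x$power)[1], dim(x$power)[2],
              dim(x$power)[3], max(x$freqs), x$n_tapers, x$nw))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The classical EEG frequency bands
#'
#' Delta 1-4, Theta 4-8, Alpha 8-12, Beta 12-30 Hz (half-open intervals
#' `[lo, hi)`, so the four bands partition 1-30 Hz).
#'
#' @return A data.frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("Delta", "Theta", "Alpha", "Beta"),
             lo = c(1, 4, 8, 12), hi = c(4, 8, 12, 30))
}

#' Integrated band power
#'
#' Integrates the spectral density over `lo <= f < hi` (sum of bin power
#' times bin width).
#'
#' @param spec A `spectrum_set`.
#' @param band Either a row of [eeg_bands()] (or any list/data.frame with
#'   `lo` and `hi` in Hz) or a numeric `c(lo, hi)`.
#' @return An epoch x channel matrix of band power in uV^2.
#' @export
band_power <- function(spec, band) {
  if (is.numeric(band) && length(band) == 2) band <- list(lo = band[1], hi = band[2])
  if (band$lo >= band$hi) stop("band must have lo < hi", call. = FALSE)
  if (band$lo < min(spec$freqs) || band$hi > max(spec$freqs) + 1e-9)
    stop("band outside the spectral range", call. = FALSE)
  df <- spec$freqs[2] - spec$freqs[1]
  sel <- spec$freqs >= band$lo & spec$freqs < band$hi
  apply(spec$power[, , sel, drop = FALSE], c(1, 2), sum) * df
}
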