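#' Multichannel EEG recording
#'
#' A channels x time matrix of voltages (volts) tied to a montage, a
#' sampling rate and an optional per-sample condition label. The container
#' carries physical units at its boundary; integer ADC codes appear only
#' inside the codec.
#'
#' @param samples Numeric matrix, channels x time, in volts. Row names (if
#'   present) must match the montage labels.
#' @param fs Sampling rate in Hz. Device-faithful rates are 500, 250 and
#'   167 Hz, but any positive rate is accepted for synthetic work.
#' @param montage Montage data.frame (default [montage_1020_24()]). Row
#'   count of `samples` must equal the montage size.
#' @param conditions Optional character vector, one of `"eyes_closed"`,
#'   `"eyes_open"`, `"none"` per sample.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, montage = montage_1020_24(),
                          conditions = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric channels x time matrix", call. = FALSE)
  if (nrow(samples) != nrow(montage))
    stop(sprintf("channel count (%d) must equal montage size (%d)",
                 nrow(samples), nrow(montage)), call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!is.null(rownames(samples)) && !identical(rownames(samples), montage$label))
    stop("row names of `samples` do not match the montage labels", call. = FALSE)
  rownames(samples) <- montage$label
  if (!is.null(conditions)) {
    conditions <- as.character(conditions)
    if (length(conditions) != ncol(samples))
      stop("`conditions` must have one label per sample", call. = FALSE)
    bad <- setdiff(unique(conditions), c("eyes_closed", "eyes_open", "none"))
    if (length(bad))
      stop("unknown condition label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, montage = montage,
                 conditions = conditions),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  if (!is.null(x$conditions)) {
    tb <- table(x$conditions)
    cat("  conditions:",
        paste(sprintf("%s %.0f s", names(tb), tb / x$fs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.raw_recording <- function(x) dim(x$samples)
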