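#' ADC front-end configuration
#'
#' Describes the delta-sigma converter front end: reference voltage,
#' programmable-gain-amplifier (PGA) setting and output resolution. The
#' converter digitises a bipolar input of +/- vref/gain into signed
#' two's-complement codes centred on 0 V.
#'
#' @param vref Reference voltage in volts (> 0). Default 2.5 V.
#' @param gain PGA gain, one of 1, 2, 4, 8. Higher gain trades input range
#'   for resolution.
#' @param bits Converter resolution in bits, one of 10, 14, 16, 24.
#' @return An object of class `adc_config`.
#' @examples
#' cfg <- adc_config()
#' lsb_volts(cfg) * 1e6   # ~0.298 uV per LSB
#' @export
adc_config <- function(vref = 2.5, gain = 1, bits = 24) {
  if (!is.numeric(vref) || length(vref) != 1 || !is.finite(vref) || vref <= 0)
    stop("`vref` must be a single positive number", call. = FALSE)
  if (!gain %in% c(1, 2, 4, 8))
    stop("`gain` must be one of 1, 2, 4, 8", call. = FALSE)
  if (!bits %in% c(10, 14, 16, 24))
    stop("`bits` must be one of 10, 14, 16, 24", call. = FALSE)
  structure(list(vref = vref, gain = as.integer(gain), bits = as.integer(bits)),
            class = "adc_config")
}

#' @export
print.adc_config <- function(x, ...) {
  cat(sprintf("<adc_config> vref %g V, gain %d, %d-bit (LSB %.4g uV, range +/- %g V)\n",
              x$vref, x$gain, x$bits, lsb_volts(x) * 1e6, x$vref / x$gain))
  invisible(x)
}

stopifnot_adc <- function(cfg) {
  if (!inherits(cfg, "adc_config")) stop("expected an `adc_config`", call. = FALSE)
  cfg
}

#' Voltage quantum (LSB) of the converter
#'
#' The full bipolar span `2 * vref / gain` divided by the `2^bits` codes:
#' the smallest voltage step the converter resolves.
#'
#' @param cfg An [adc_config()].
#' @return Volts per least-significant bit.
#' @export
lsb_volts <- function(cfg) {
  stopifnot_adc(cfg)
  (2 * cfg$vref / cfg$gain) / 2^cfg$bits
}

#' Bipolar input range of the converter
#'
#' @param cfg An [adc_config()].
#' @return Numeric `c(lo, hi)` = `c(-vref/gain, +vref/gain)` in volts.
#' @export
input_range_volts <- function(cfg) {
  stopifnot_adc(cfg)
  c(-cfg$vref / cfg$gain, cfg$vref / cfg$gain)
}

# round half away from zero (sign-symmetric, unlike base round())
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Convert voltages to signed ADC codes
#'
#' Quantises by rounding half away from zero and saturates to the signed
#' code range (real converters clip rather than error on over-range input).
#'
#' @param cfg An [adc_config()].
#' @param v Numeric vector/matrix of voltages (finite).
#' @return Signed integer codes, same shape as `v`.
#' @export
volts_to_code <- function(cfg, v) {
  stopifnot_adc(cfg)
  if (any(!is.finite(v))) stop("voltages must be finite", call. = FALSE)
  lo <- -2^(cfg$bits - 1)
  hi <- 2^(cfg$bits - 1) - 1
  code <- round_half_away(v / lsb_volts(cfg))
  code[code < lo] <- lo
  code[code > hi] <- hi
  code
}

#' Convert signed ADC codes back to volts
#'
#' @param cfg An [adc_config()].
#' @param code Signed integer codes within the range of `cfg$bits`.
#' @return Voltages (`code * lsb_volts(cfg)`).
#' @export
code_to_volts <- function(cfg, code) {
  stopifnot_adc(cfg)
  lo <- -2^(cfg$bits - 1)
  hi <- 2^(cfg$bits - 1) - 1
  if (any(code < lo | code > hi, na.rm = TRUE))
    stop(sprintf("code out of signed %d-bit range [%d, %d]", cfg$bits, lo, hi),
         call. = FALSE)
  code * lsb_volts(cfg)
}

#' Requantize 24-bit codes to a lower bit depth
#'
#' Pure truncation: an arithmetic right shift by `24 - target_bits` drops the
#' low-order bits (no dithering). `upscale = TRUE` reverses the scale by a
#' left shift, leaving the dropped bits zero.
#'
#' @param code24 Signed 24-bit codes.
#' @param target_bits Target depth: 10, 14, 16 (or 24 = identity).
#' @param upscale If `TRUE`, map codes at `target_bits` back to the 24-bit
#'   scale instead.
#' @return Signed codes at the target depth (or back at 24-bit scale).
#' @export
requantize <- function(code24, target_bits, upscale = FALSE) {
  if (!target_bits %in% c(10, 14, 16, 24))
    stop("`target_bits` must be one of 10, 14, 16, 24", call. = FALSE)
  shift <- 24 - target_bits
  if (upscale) return(code24 * 2^shift)
  # arithmetic right shift == floor division for signed integers
  floor(code24 / 2^shift)
}
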