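#' Write packets in the DMP1 binary format
#'
#' Little-endian stream: magic `"DMP1"` (4 bytes); then per packet:
#' `seq` uint16, `flags` uint8 (bit 0 = keyframe), `n_samples` uint8,
#' 24 x `shift` uint8; keyframe payload 24 x int32 (sign-extended 24-bit
#' codes); delta payload `n_samples` x 24 x int16, sample-major. Symbols
#' wider than int16 cannot be represented (`payload_bits <= 16` is
#' enforced by the codec).
#'
#' @param packets Packet list from [encode_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_packets <- function(packets, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("DMP1"), con)
  for (pk in packets) {
    writeBin(as.integer(pk$seq), con, size = 2, endian = "little")
    writeBin(as.integer(ifelse(isTRUE(pk$keyframe), 1L, 0L)), con, size = 1)
    writeBin(as.integer(length_payload(pk)), con, size = 1)
    writeBin(as.integer(pk$shifts), con, size = 1)
    if (isTRUE(pk$keyframe)) {
      writeBin(as.integer(pk$payload), con, size = 4, endian = "little")
    } else {
      if (any(abs(pk$payload) > 32767))
        stop("delta symbol exceeds int16", call. = FALSE)
      # sample-major: all 24 channel symbols of sample 1, then sample 2, ...
      writeBin(as.integer(pk$payload), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a DMP1 packet stream
#'
#' Tolerates nothing: a wrong magic is a format error and a truncated final
#' packet raises an error naming the byte offset where the stream ended.
#'
#' @param path Input file path.
#' @return A packet list (class `eeg_packet_stream`).
#' @export
read_packets <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 4 || !identical(raw[1:4], charToRaw("DMP1")))
    stop(sprintf("%s is not a DMP1 stream (bad magic)", path), call. = FALSE)
  pos <- 5L
  packets <- list()
  need <- function(k, what) {
    if (pos + k - 1L > length(raw))
      stop(sprintf("truncated DMP1 stream: %s cut off at byte offset %d",
                   what, pos - 1L), call. = FALSE)
  }
  u8 <- function() {
    v <- as.integer(raw[pos]); pos <<- pos + 1L; v
  }
  u16 <- function() {
    v <- as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
    pos <<- pos + 2L
    v
  }
  while (pos <= length(raw)) {
    need(4L + 24L, "packet header")
    seq_no <- u16()
    flags <- u8()
    nspl <- u8()
    shifts <- as.integer(raw[pos:(pos + 23L)]); pos <- pos + 24L
    keyframe <- bitwAnd(flags, 1L) == 1L
    if (keyframe) {
      need(24L * 4L, "keyframe payload")
      payload <- readBin(raw[pos:(pos + 96L - 1L)], "integer", n = 24,
                         size = 4, endian = "little")
      pos <- pos + 96L
    } else {
      nb <- as.integer(nspl) * 24L * 2L
      need(nb, "delta payload")
      vals <- readBin(raw[pos:(pos + nb - 1L)], "integer", n = nspl * 24L,
                      size = 2, signed = TRUE, endian = "little")
      payload <- matrix(vals, nrow = 24L)
      pos <- pos + nb
    }
    packets[[length(packets) + 1L]] <- structure(
      list(seq = seq_no, keyframe = keyframe, shifts = shifts,
           payload = payload),
      class = "eeg_packet")
  }
  structure(packets, class = "eeg_packet_stream")
}
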