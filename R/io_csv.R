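#' Write a recording as CSV
#'
#' The repository's normative CSV dialect: comma-separated, UTF-8, header
#' `time_s` followed by the 24 montage labels (in montage order), values in
#' microvolts with full precision, plus an optional trailing `condition`
#' column when the recording carries labels.
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @param condition_column Include the condition column if labels are
#'   present (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, condition_column = TRUE) {
  n <- ncol(rec$samples)
  dt <- data.table::data.table(time_s = (seq_len(n) - 1) / rec$fs)
  uv <- t(rec$samples) * 1e6
  for (i in seq_len(nrow(rec$samples)))
    data.table::set(dt, j = rownames(rec$samples)[i], value = uv[, i])
  if (condition_column && !is.null(rec$conditions))
    data.table::set(dt, j = "condition", value = rec$conditions)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the dialect written by [write_recording_csv()]; the header must
#' be `time_s` followed by the montage labels, exactly and in order. The
#' sampling rate is recovered from the time column.
#'
#' @param path Input file path.
#' @param montage Expected montage (default [montage_1020_24()]).
#' @return A [raw_recording()].
#' @export
read_recording_csv <- function(path, montage = montage_1020_24()) {
  dt <- withCallingHandlers(
    tryCatch(
      data.table::fread(path, header = TRUE, sep = ","),
      error = function(e) stop(sprintf("parse error in %s: %s", path,
                                       conditionMessage(e)), call. = FALSE)),
    warning = function(w) {
      # fread housekeeping notices are benign; content warnings are not
      if (grepl("cleaned up", conditionMessage(w), ignore.case = TRUE)) {
        invokeRestart("muffleWarning")
      } else {
        stop(sprintf("parse error in %s: %s", path, conditionMessage(w)),
             call. = FALSE)
      }
    })
  want <- c("time_s", montage$label)
  got <- names(dt)
  has_cond <- length(got) == length(want) + 1 &&
    got[length(got)] == "condition"
  if (!identical(got[seq_along(want)], want) ||
      (!has_cond && length(got) != length(want)))
    stop(sprintf("malformed header in %s (line 1): expected 'time_s,%s[,condition]'",
                 path, paste(montage$label, collapse = ",")), call. = FALSE)
  if (nrow(dt) == 0)
    return(raw_recording(matrix(0, nrow(montage), 0,
                                dimnames = list(montage$label, NULL)),
                         fs = 250, montage = montage))
  fs <- if (nrow(dt) > 1) 1 / stats::median(diff(dt$time_s)) else 250
  fs <- round(fs, 6)
  samples <- t(as.matrix(dt[, montage$label, with = FALSE])) * 1e-6
  rownames(samples) <- montage$label
  conditions <- if (has_cond) dt$condition else NULL
  raw_recording(samples, fs = fs, montage = montage,
                conditions = conditions)
}
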