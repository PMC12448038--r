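#' Plot mean power spectra
#'
#' Channel-averaged multitaper spectrum (log10 power density) for one or
#' more conditions on a shared frequency axis.
#'
#' @param ... One or more `spectrum_set`s.
#' @param f_max Upper frequency limit of the plot (default 40 Hz).
#' @param channels Optional channel subset (labels).
#' @return Invisibly, the plotted matrix of mean spectra.
#' @export
plot_spectra <- function(..., f_max = 40, channels = NULL) {
  specs <- list(...)
  cols <- grDevices::hcl.colors(max(2, length(specs)), "Dark 2")
  first <- TRUE
  out <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sel <- if (is.null(channels)) seq_along(sp$channels)
    else match(channels, sp$channels)
    keep <- sp$freqs <= f_max & sp$freqs > 0
    m <- apply(sp$power[, sel, keep, drop = FALSE], 3, mean)
    if (first) {
      plot(sp$freqs[keep], log10(m), type = "l", col = cols[i], lwd = 2,
           xlab = "frequency (Hz)", ylab = "log10 power (uV^2/Hz)",
           main = "multitaper power spectra")
      first <- FALSE
    } else {
      graphics::lines(sp$freqs[keep], log10(m), col = cols[i], lwd = 2)
    }
    out[[sp$condition %||% as.character(i)]] <- m
  }
  graphics::legend("topright", legend = names(out), col = cols[seq_along(out)],
                   lwd = 2, bty = "n")
  invisible(out)
}

#' Schematic topography of per-channel values
#'
#' Draws the montage as a head-plane scatter coloured by `values` (e.g. a
#' band-power contrast or a t statistic), with channel labels.
#'
#' @param values Named numeric vector (names = channel labels).
#' @param montage Montage data.frame (default [montage_1020_24()]).
#' @param main Plot title.
#' @return Invisibly, `values`.
#' @export
plot_topography <- function(values, montage = montage_1020_24(),
                            main = "topography") {
  idx <- match(montage$label, names(values))
  v <- values[idx]
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  rng <- max(abs(v), na.rm = TRUE)
  col <- pal[pmin(64, pmax(1, round((v / rng + 1) / 2 * 63) + 1))]
  plot(montage$x, montage$y, asp = 1, pch = 21, bg = col, cex = 3,
       xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), axes = FALSE,
       xlab = "", ylab = "", main = main)
  graphics::symbols(0, 0, circles = 1.05, inches = FALSE, add = TRUE)
  graphics::text(montage$x, montage$y - 0.12, montage$label, cex = 0.6)
  invisible(values)
}
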