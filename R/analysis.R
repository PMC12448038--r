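#' Exclude noisy or flat channels
#'
#' Automates the visual bad-channel screen: a channel is dropped when its
#' log10 variance is an outlier against the median across channels — robust
#' z-score (median / 1.4826*MAD) above `z_threshold` *and* variance at
#' least `min_ratio` times the median (the ratio guard keeps tightly
#' clustered clean channels from being flagged when the MAD is tiny) — or
#' when it is flat (zero variance). Symmetrically, dead channels (robust z
#' below `-z_threshold` and variance below `median/min_ratio`) are dropped.
#'
#' @param rec A [raw_recording()] with at least 4 channels.
#' @param z_threshold Robust z-score threshold (default 5).
#' @param min_ratio Minimal variance ratio to the median for exclusion
#'   (default 10).
#' @return `list(rec, excluded)`: the recording restricted to the kept
#'   channels (montage subset accordingly) and the excluded labels.
#' @export
exclude_noisy_channels <- function(rec, z_threshold = 5, min_ratio = 10) {
  if (nrow(rec$samples) < 4)
    stop("need at least 4 channels", call. = FALSE)
  v <- apply(rec$samples, 1, stats::var)
  flat <- v <= 0
  lv <- log10(v[!flat])
  bad <- flat
  if (sum(!flat) >= 4) {
    med <- stats::median(lv)
    scale <- stats::mad(lv, center = med)
    # degenerate MAD (many identical variances): the ratio guard decides
    z <- if (scale > 0) (lv - med) / scale else
      ifelse(lv == med, 0, sign(lv - med) * Inf)
    ratio <- v[!flat] / stats::median(v[!flat])
    noisy <- z > z_threshold & ratio >= min_ratio
    dead <- z < -z_threshold & ratio <= 1 / min_ratio
    bad[!flat] <- noisy | dead
  }
  if (all(bad)) stop("all channels excluded", call. = FALSE)
  keep <- !bad
  out <- rec
  out$samples <- rec$samples[keep, , drop = FALSE]
  out$montage <- rec$montage[keep, , drop = FALSE]
  list(rec = out, excluded = rownames(rec$samples)[bad])
}

#' Channel x frequency t-map
#'
#' Two-sample pooled-variance t statistic per (channel, frequency) cell,
#' computed on log10 power (EEG band power is strongly right-skewed, so the
#' test runs on the log scale).
#'
#' @param spec_a,spec_b `spectrum_set`s on identical channel/frequency
#'   grids, with >= 2 epochs each.
#' @param log10_transform Test log10 power (default `TRUE`).
#' @return A channels x frequencies matrix of t values
#'   (`spec_a` minus `spec_b`).
#' @export
t_map <- function(spec_a, spec_b, log10_transform = TRUE) {
  stopifnot(identical(spec_a$channels, spec_b$channels),
            isTRUE(all.equal(spec_a$freqs, spec_b$freqs)))
  na <- dim(spec_a$power)[1]; nb <- dim(spec_b$power)[1]
  if (na < 2 || nb < 2) stop("need >= 2 epochs per group", call. = FALSE)
  nch <- dim(spec_a$power)[2]; nf <- dim(spec_a$power)[3]
  xa <- matrix(spec_a$power, na, nch * nf)
  xb <- matrix(spec_b$power, nb, nch * nf)
  if (log10_transform) {
    xa <- log10(pmax(xa, .Machine$double.xmin))
    xb <- log10(pmax(xb, .Machine$double.xmin))
  }
  t <- pooled_t(xa, xb)
  matrix(t, nch, nf, dimnames = list(spec_a$channels, NULL))
}

# vectorised two-sample pooled-variance t over columns
pooled_t <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  ssa <- colSums(xa^2) - na * ma^2
  ssb <- colSums(xb^2) - nb * mb^2
  s2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(s2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0] <- 0
  t
}

#' Cluster permutation test configuration
#'
#' @param cluster_alpha Tail probability of the two-sided t threshold that
#'   admits a cell into a cluster (default 0.01).
#' @param cluster_sig_alpha Monte Carlo significance level for clusters
#'   (default 0.05).
#' @param n_permutations Number of label permutations (default 1000,
#'   minimum 100).
#' @param seed Seed for the permutation draw (default 1).
#' @param f_range Frequency range tested, Hz (default 1-30, the union of
#'   the classical bands).
#' @return A `cluster_test_config`.
#' @export
cluster_test_config <- function(cluster_alpha = 0.01,
                                cluster_sig_alpha = 0.05,
                                n_permutations = 1000, seed = 1,
                                f_range = c(1, 30)) {
  if (cluster_alpha <= 0 || cluster_alpha >= 1 ||
      cluster_sig_alpha <= 0 || cluster_sig_alpha >= 1)
    stop("alphas must lie in (0, 1)", call. = FALSE)
  if (n_permutations < 100)
    stop("`n_permutations` must be >= 100", call. = FALSE)
  structure(list(cluster_alpha = cluster_alpha,
                 cluster_sig_alpha = cluster_sig_alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, f_range = f_range),
            class = "cluster_test_config")
}

adjacency_to_list <- function(adjacency) {
  lapply(seq_len(nrow(adjacency)), function(i) which(adjacency[i, ]))
}

#' Cluster-based permutation test over channels x frequencies
#'
#' Controls the family-wise error of the mass-univariate channel x
#' frequency comparison: cells with `|t|` above the two-sided critical
#' value at `cluster_alpha` are grouped into connected clusters (adjacent
#' frequency bins within a channel; spatially adjacent channels within a
#' bin), each cluster scored by its summed t. The observed cluster scores
#' are referred to the permutation distribution of the maximum |score|
#' under `n_permutations` random relabelings of the epochs; Monte Carlo
#' p-values use the +1/+1 correction so p is never 0. Deterministic under
#' a fixed `seed`.
#'
#' @param spec_a,spec_b `spectrum_set`s on identical grids (>= 2 epochs
#'   per group).
#' @param adjacency Logical channel adjacency matrix
#'   ([channel_adjacency()]).
#' @param cfg A [cluster_test_config()].
#' @return A `cluster_result`: `clusters` (list of `members` data frame,
#'   summed `stat`, `sign`, Monte Carlo `p`), the `t_map`, the tested
#'   `freqs`/`channels`, and `significant_channels` at
#'   `cluster_sig_alpha`.
#' @export
cluster_permutation <- function(spec_a, spec_b, adjacency,
                                cfg = cluster_test_config()) {
  stopifnot(identical(spec_a$channels, spec_b$channels))
  keep <- spec_a$freqs >= cfg$f_range[1] & spec_a$freqs <= cfg$f_range[2]
  freqs <- spec_a$freqs[keep]
  na <- dim(spec_a$power)[1]; nb <- dim(spec_b$power)[1]
  if (na < 2 || nb < 2) stop("need >= 2 epochs per group", call. = FALSE)
  nch <- dim(spec_a$power)[2]; nf <- sum(keep)
  xa <- matrix(spec_a$power[, , keep, drop = FALSE], na, nch * nf)
  xb <- matrix(spec_b$power[, , keep, drop = FALSE], nb, nch * nf)
  x <- log10(pmax(rbind(xa, xb), .Machine$double.xmin))
  n <- na + nb
  thresh <- stats::qt(1 - cfg$cluster_alpha / 2, df = n - 2)
  adj <- adjacency_to_list(adjacency)

  t_obs <- pooled_t(x[seq_len(na), , drop = FALSE],
                    x[na + seq_len(nb), , drop = FALSE])
  tmat <- matrix(t_obs, nch, nf, dimnames = list(spec_a$channels, NULL))
  comp <- .cluster_components(tmat, thresh, adj)

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  perm_max <- numeric(cfg$n_permutations)
  for (i in seq_len(cfg$n_permutations)) {
    idx <- sample.int(n)
    tp <- pooled_t(x[idx[seq_len(na)], , drop = FALSE],
                   x[idx[na + seq_len(nb)], , drop = FALSE])
    perm_max[i] <- .cluster_max_stat(matrix(tp, nch, nf), thresh, adj)
  }

  clusters <- list()
  if (length(comp$stats)) {
    ord <- order(-abs(comp$stats))
    for (ci in ord) {
      cells <- which(comp$labels == ci, arr.ind = TRUE)
      p <- (1 + sum(perm_max >= abs(comp$stats[ci]))) /
        (cfg$n_permutations + 1)
      clusters[[length(clusters) + 1L]] <- list(
        members = data.frame(channel = spec_a$channels[cells[, 1]],
                             freq_hz = freqs[cells[, 2]]),
        stat = comp$stats[ci], sign = comp$signs[ci], p = p)
    }
  }
  sig <- unique(unlist(lapply(clusters, function(cl)
    if (cl$p < cfg$cluster_sig_alpha) cl$members$channel else NULL)))
  sig <- spec_a$channels[spec_a$channels %in% sig]   # montage order
  structure(list(clusters = clusters, t_map = tmat, freqs = freqs,
                 channels = spec_a$channels, perm_max = perm_max,
                 significant_channels = sig, config = cfg),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) over %d channels x %d bins\n",
              length(x$clusters), length(x$channels), length(x$freqs)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d %s: stat %.1f, p = %.4g, %d cells, channels: %s\n",
                i, if (cl$sign > 0) "pos" else "neg", cl$stat, cl$p,
                nrow(cl$members),
                paste(unique(cl$members$channel), collapse = " ")))
  }
  if (length(x$significant_channels))
    cat("  significant channels:",
        paste(x$significant_channels, collapse = " "), "\n")
  invisible(x)
}

#' Channels participating in significant clusters
#'
#' @param result A `cluster_result`.
#' @param sig_alpha Significance level (default: the config's
#'   `cluster_sig_alpha`).
#' @return Character vector of channel labels in montage order (empty when
#'   no cluster is significant).
#' @export
effective_channels <- function(result, sig_alpha = NULL) {
  if (is.null(sig_alpha)) sig_alpha <- result$config$cluster_sig_alpha
  labs <- unique(unlist(lapply(result$clusters, function(cl)
    if (cl$p < sig_alpha) cl$members$channel else NULL)))
  result$channels[result$channels %in% labs]
}

#' Condition-contrast topography correlation between two pipelines
#'
#' The end-to-end fidelity measure: for each recording, the per-channel
#' mean band power difference (eyes-closed minus eyes-open) is computed;
#' the Pearson correlation of the two channel topographies measures how
#' well a processed (e.g. codec-round-tripped and filtered) recording
#' preserves the contrast of the clean one.
#'
#' @param rec_a,rec_b [raw_recording()]s on the same montage and protocol.
#' @param band Numeric `c(lo, hi)` in Hz (default the alpha band, 8-12).
#' @param epoch_s Epoch length for the spectra (default 30).
#' @param smoothing_hz Multitaper half-bandwidth (default 1).
#' @return `list(r, topo_a, topo_b)`: the correlation and the two
#'   per-channel contrast vectors (uV^2).
#' @export
compare_pipelines <- function(rec_a, rec_b, band = c(8, 12), epoch_s = 30,
                              smoothing_hz = 1) {
  topo <- function(rec) {
    ep <- epoch_recording(rec, epoch_s)
    stopifnot(!is.null(ep$eyes_closed), !is.null(ep$eyes_open))
    bp <- lapply(ep, function(e)
      colMeans(band_power(psd_multitaper(e, smoothing_hz), band)))
    bp$eyes_closed - bp$eyes_open
  }
  ta <- topo(rec_a); tb <- topo(rec_b)
  list(r = stats::cor(ta, tb), topo_a = ta, topo_b = tb)
}
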