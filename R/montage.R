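#' The 24-channel 10-20 montage
#'
#' Channel labels and schematic 2-D head-plane positions (unit head radius,
#' nose up: x to the right, y to the front) for the 24 electrodes of the
#' device layout: frontopolar (FP1/FPZ/FP2) through occipital (O1/OZ/O2),
#' plus the mastoids M1/M2. Positions follow the standard 10-20 schematic
#' projection and are bundled as a plain-text table.
#'
#' @return A data.frame with columns `label`, `x`, `y` (24 rows).
#' @examples
#' m <- montage_1020_24()
#' head(m)
#' @export
montage_1020_24 <- function() {
  path <- system.file("extdata", "montage_1020_24.tsv", package = "eegstream")
  m <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(nrow(m) == 24, !anyDuplicated(m$label), all(m$x^2 + m$y^2 <= 1))
  m
}

#' Spatial channel adjacency
#'
#' Two channels are neighbours iff their Euclidean distance in the 2-D
#' head-plane is at most `radius` (unit-head coordinates). The relation is
#' symmetric and irreflexive; it feeds the cluster-forming step of the
#' permutation test.
#'
#' @param montage A montage data.frame (`label`, `x`, `y`).
#' @param radius Neighbourhood radius; default 0.4 gives every channel of
#'   the default montage at least one neighbour without bridging across the
#'   head.
#' @return A logical `n x n` matrix with dimnames = channel labels and a
#'   `FALSE` diagonal.
#' @export
channel_adjacency <- function(montage, radius = 0.4) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  adj <- d <= radius
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$label, montage$label)
  adj
}
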