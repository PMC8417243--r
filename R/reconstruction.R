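# Information reconstruction: per-channel wavelet-packet band energies and
# the Pearson-correlation channel graph that together form the encoder
# input (node features + weighted adjacency).

#' Per-channel sub-band energy matrix
#'
#' Runs a full wavelet-packet decomposition on every channel of a segment
#' and summarizes each terminal sub-band by its energy. Rows are channels,
#' columns are sub-bands in ascending frequency order.
#'
#' @param seg An `eeg_segment`.
#' @param depth Decomposition depth (default 4: 16 sub-bands).
#' @param wavelet Wavelet name (default `"db4"`).
#' @return Object of class `band_energy_matrix`: list with `energies` and
#'   `relative` (channels x 2^depth matrices), `zero_rows` (logical per
#'   channel), `depth`, `wavelet`, `sampling_rate`.
#' @export
channel_energy_matrix <- function(seg, depth = 4L, wavelet = "db4") {
  stopifnot(inherits(seg, "eeg_segment"))
  nb <- 2L^as.integer(depth)
  nc <- nrow(seg$samples)
  energies <- matrix(0, nc, nb)
  relative <- matrix(0, nc, nb)
  zero_rows <- logical(nc)
  for (i in seq_len(nc)) {
    be <- band_energies(wpd_terminal_coefficients(seg$samples[i, ], depth,
                                                  wavelet))
    energies[i, ] <- be$energy
    relative[i, ] <- be$relative
    zero_rows[i] <- be$zero_energy
  }
  rownames(energies) <- rownames(relative) <- rownames(seg$samples)
  structure(list(energies = energies, relative = relative,
                 zero_rows = zero_rows, depth = as.integer(depth),
                 wavelet = wavelet, sampling_rate = seg$sampling_rate),
            class = "band_energy_matrix")
}

#' Pearson product-moment correlation with a degenerate-input policy
#'
#' Standard Pearson correlation; if either input is constant the
#' coefficient is undefined and is returned as 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ",
                                   length(y), call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Pearson correlation undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  stats::cor(x, y)
}

#' Build the weighted channel graph
#'
#' Channels are nodes; edge weights are absolute Pearson correlations
#' between per-channel vectors. By default the correlated vectors are the
#' 16-value relative band-energy rows (correlation computed after spectral
#' reconstruction); `mode = "raw_signals"` instead correlates the raw
#' time-series of the segment. Signed correlations are retained in
#' `raw_correlations`; the adjacency takes absolute values (the normalized
#' Laplacian requires nonnegative weights) and zeroes the diagonal. Node
#' features are the relative band-energy rows.
#'
#' @param bem A [channel_energy_matrix()] result.
#' @param mode `"energy_vectors"` (default) or `"raw_signals"`.
#' @param seg The source `eeg_segment`; required for `mode = "raw_signals"`.
#' @return Object of class `channel_graph`: list with `adjacency`,
#'   `node_features`, `raw_correlations`, `mode`.
#' @export
build_channel_graph <- function(bem, mode = c("energy_vectors",
                                              "raw_signals"), seg = NULL) {
  stopifnot(inherits(bem, "band_energy_matrix"))
  mode <- match.arg(mode)
  V <- if (mode == "energy_vectors") {
    bem$relative
  } else {
    if (is.null(seg)) stop("raw_signals mode requires seg", call. = FALSE)
    if (nrow(seg$samples) != nrow(bem$relative)) {
      stop("segment and energy matrix disagree on channel count",
           call. = FALSE)
    }
    seg$samples
  }
  nc <- nrow(V)
  r <- suppressWarnings(stats::cor(t(V)))
  if (anyNA(r)) {
    warning("constant channel vector(s): undefined correlations set to 0",
            call. = FALSE)
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  adj <- abs(r)
  diag(adj) <- 0
  dimnames(adj) <- dimnames(r) <- list(rownames(bem$relative),
                                       rownames(bem$relative))
  structure(list(adjacency = adj, node_features = bem$relative,
                 raw_correlations = r, mode = mode),
            class = "channel_graph")
}

#' Segment to channel graph in one step
#'
#' Convenience composition of [channel_energy_matrix()] and
#' [build_channel_graph()].
#'
#' @inheritParams channel_energy_matrix
#' @inheritParams build_channel_graph
#' @return A `channel_graph`.
#' @export
segment_graph <- function(seg, depth = 4L, wavelet = "db4",
                          mode = "energy_vectors") {
  bem <- channel_energy_matrix(seg, depth, wavelet)
  build_channel_graph(bem, mode = mode, seg = seg)
}

#' Band-energy percentage bar plot
#'
#' Plots the channel-averaged relative energy of each sub-band as a
#' percentage, bands in ascending frequency order.
#'
#' @param bem A [channel_energy_matrix()] result.
#' @param main Plot title.
#' @param ... Passed to [graphics::barplot()].
#' @return The relative-energy percentages, invisibly.
#' @export
plot_band_energy <- function(bem, main = "Sub-band energy percentage", ...) {
  stopifnot(inherits(bem, "band_energy_matrix"))
  nb <- ncol(bem$relative)
  width <- (bem$sampling_rate / 2) / nb
  pct <- 100 * colMeans(bem$relative)
  labs <- sprintf("%g-%g", (seq_len(nb) - 1) * width, seq_len(nb) * width)
  graphics::barplot(pct, names.arg = labs, las = 2, ylab = "energy (%)",
                    xlab = "frequency band (Hz)", main = main, ...)
  invisible(pct)
}
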