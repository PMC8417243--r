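# Orthogonal wavelet filter bank and periodized wavelet packet transform.
#
# The full packet tree splits both the approximation (low) and detail (high)
# branch at every level, so depth d yields 2^d terminal sub-bands that tile
# [0, Nyquist]. Circular (periodized) extension keeps the transform exactly
# orthonormal, so sub-band energies satisfy Parseval exactly for signal
# lengths divisible by 2^depth.

# Daubechies scaling (lowpass reconstruction) coefficients, standard tables.
.db_filters <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339,
          -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154,
          -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
  db4 = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.032883011666885197, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.077571493840045719, -0.0062414902127982744, -0.012580751999081999,
          0.0033357252854737712),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.097501605587323043, 0.027522865530305727, -0.03158203931748603,
          0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
  db7 = c(0.077852054085009184, 0.39653931948191729, 0.72913209084623509,
          0.46978228740519312, -0.14390600392856498, -0.22403618499387498,
          0.071309219266830259, 0.080612609151083078, -0.038029936935014413,
          -0.016574541630666881, 0.01255099855609984, 0.00042957797292136651,
          -0.0018016407040474908, 0.00035371379997452024),
  db8 = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
          0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
          0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
          -0.0048703529934515741, -0.00039174037337694705,
          0.00067544940645056933, -0.00011747678412476953)
)

#' Orthogonal wavelet analysis filters
#'
#' Returns the lowpass/highpass analysis pair for a Daubechies wavelet.
#' The highpass filter is the quadrature mirror of the lowpass one,
#' `g[m] = (-1)^m h[L - 1 - m]`, so the periodized filter bank is orthonormal.
#'
#' @param wavelet Wavelet name: `"haar"` or `"db1"` ... `"db8"`.
#' @return List with components `lo` and `hi`, numeric filters of equal length.
#' @export
#' @examples
#' f <- wavelet_filter("db4")
#' sum(f$lo^2)  # unit energy
wavelet_filter <- function(wavelet = "db4") {
  h <- .db_filters[[tolower(wavelet)]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.db_filters), collapse = ", "), call. = FALSE)
  }
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(lo = h, hi = g, length = L)
}

# One periodized analysis step: circular convolution + dyadic downsampling.
# Rows of the implied transform matrix are the filter circularly shifted by
# 2k, so [lo; hi] together form an orthonormal matrix. Odd-length inputs are
# extended by wrapping one sample (documented deviation from exactness).
.dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[1L])
    n <- n + 1L
  }
  L <- filt$length
  half <- n %/% 2L
  # row k (k = 0..half-1) holds positions (2k + m - (L/2 - 1)) mod n,
  # m = 0..L-1; this phase alignment matches the standard periodized
  # convolution-decimation used by reference wavelet implementations
  sft <- L %/% 2L - 1L
  idx <- ((outer(2L * (seq_len(half) - 1L) - sft, 0:(L - 1L), `+`) %% n +
             n) %% n) + 1L
  xi <- matrix(x[idx], nrow = half)
  list(lo = drop(xi %*% filt$lo), hi = drop(xi %*% filt$hi))
}

# Inverse of .dwt_step (orthonormal, so synthesis is the transpose):
# scatter-accumulate each coefficient pair back through the filter bank.
.idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  L <- filt$length
  sft <- L %/% 2L - 1L
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L) - sft
  for (m in 0:(L - 1L)) {
    idx <- ((base + m) %% n + n) %% n + 1L
    x[idx] <- x[idx] + filt$lo[m + 1L] * a + filt$hi[m + 1L] * d
  }
  x
}

# Reconstruct a signal from terminal packet coefficients given in
# frequency order (the order wpd_terminal_coefficients returns).
.wp_reconstruct <- function(coeff_sets_freq, wavelet = "db4") {
  nb <- length(coeff_sets_freq)
  depth <- as.integer(round(log2(nb)))
  if (2L^depth != nb) stop("coefficient count must be a power of two",
                           call. = FALSE)
  filt <- wavelet_filter(wavelet)
  i <- 0:(nb - 1L)
  gray <- bitwXor(i, bitwShiftR(i, 1L))
  nodes <- vector("list", nb)
  nodes[gray + 1L] <- coeff_sets_freq
  for (lev in seq_len(depth)) {
    nxt <- vector("list", length(nodes) %/% 2L)
    for (j in seq_along(nxt)) {
      nxt[[j]] <- .idwt_step(nodes[[2L * j - 1L]], nodes[[2L * j]], filt)
    }
    nodes <- nxt
  }
  nodes[[1L]]
}

#' Terminal wavelet-packet coefficients in frequency order
#'
#' Decomposes a signal with a full wavelet packet tree (both low- and
#' high-frequency branches split at every level) to the requested depth and
#' returns the `2^depth` terminal coefficient vectors ordered by ascending
#' frequency. The natural packet-tree order is not frequency order because
#' downsampling a highpass branch mirrors its spectrum; terminal nodes are
#' re-sorted by the binary-reflected Gray code permutation so that band `k`
#' covers `[k, k + 1) * nyquist / 2^depth`.
#'
#' @param signal Numeric vector, length at least `2^depth`.
#' @param depth Number of decomposition levels (default 4, giving 16 bands).
#' @param wavelet Wavelet name passed to [wavelet_filter()].
#' @return List of `2^depth` numeric vectors, frequency order ascending.
#' @export
#' @examples
#' x <- sin(2 * pi * 96 * (0:1279) / 256)  # 96 Hz tone at 256 Hz sampling
#' co <- wpd_terminal_coefficients(x, depth = 4, wavelet = "db4")
#' which.max(vapply(co, function(v) sum(v^2), 0))  # 13 (1-based): the 96-104 Hz band
wpd_terminal_coefficients <- function(signal, depth = 4L, wavelet = "db4") {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (!is.numeric(signal)) stop("signal must be numeric", call. = FALSE)
  if (length(signal) < 2L^depth) {
    stop("signal too short: length ", length(signal),
         " < 2^depth = ", 2L^depth, call. = FALSE)
  }
  filt <- wavelet_filter(wavelet)
  nodes <- list(as.numeric(signal))
  for (lev in seq_len(depth)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      st <- .dwt_step(nodes[[j]], filt)
      nxt[[2L * j - 1L]] <- st$lo
      nxt[[2L * j]] <- st$hi
    }
    nodes <- nxt
  }
  # natural index (0-based) of the node at ascending frequency rank i: gray(i)
  i <- 0:(2L^depth - 1L)
  gray <- bitwXor(i, bitwShiftR(i, 1L))
  nodes[gray + 1L]
}

#' Sub-band energies from wavelet-packet coefficients
#'
#' Energy of band `k` is the sum of squared coefficients of terminal node
#' `k`; relative energy is its share of the total. An all-zero input has no
#' defined relative distribution and is returned as zeros with
#' `zero_energy = TRUE`.
#'
#' @param coeff_sets List of coefficient vectors as returned by
#'   [wpd_terminal_coefficients()].
#' @return List with `energy` and `relative` (numeric vectors of the same
#'   length as `coeff_sets`) and logical flag `zero_energy`.
#' @export
band_energies <- function(coeff_sets) {
  if (!is.list(coeff_sets) || length(coeff_sets) == 0L) {
    stop("coeff_sets must be a nonempty list", call. = FALSE)
  }
  energy <- vapply(coeff_sets, function(v) sum(v^2), numeric(1))
  tot <- sum(energy)
  if (tot > 0) {
    list(energy = energy, relative = energy / tot, zero_energy = FALSE)
  } else {
    list(energy = energy, relative = rep(0, length(energy)),
         zero_energy = TRUE)
  }
}
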