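# Synthetic multichannel EEG with planted class structure. Each regime
# plants (a) a sub-band energy profile — band-limited components are
# synthesized in wavelet-packet coefficient space, so by orthonormality the
# energy share of band k equals weight k exactly in the noiseless signal —
# and (b) a cross-channel correlation level (each band's coefficient vector
# mixes a shared latent vector with a private one; the mixture weight is
# the coupling). White noise is added on top.
# All randomness flows through R's default Mersenne-Twister stream,
# seeded per call and restored afterwards, so results are reproducible and
# caller RNG state is untouched.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify one signal regime (class) for the synthetic generator
#'
#' @param band_weights Nonnegative weights summing to 1: target relative
#'   energy of each depth-4 terminal sub-band (length 16 by default;
#'   generally `2^depth`). Band `k` spans
#'   `[(k-1), k) * nyquist / length(band_weights)`.
#' @param coupling Cross-channel correlation level in `[0, 1]`: the share of
#'   each channel's oscillatory power drawn from a source shared by all
#'   channels.
#' @param noise_sd Additive white-noise standard deviation (microvolts).
#' @param amplitude Overall oscillation amplitude scale (microvolts).
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(band_weights, coupling, noise_sd = 1,
                        amplitude = 10) {
  band_weights <- as.numeric(band_weights)
  if (any(band_weights < 0)) stop("band weights must be nonnegative",
                                  call. = FALSE)
  if (abs(sum(band_weights) - 1) > 1e-9) {
    stop("band weights must sum to 1 (got ", sum(band_weights), ")",
         call. = FALSE)
  }
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]",
                                         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(band_weights = band_weights, coupling = coupling,
                 noise_sd = noise_sd, amplitude = amplitude),
            class = "regime_spec")
}

#' Default pre-ictal regime: high-frequency-dominant, strongly coupled
#'
#' Oscillatory energy concentrated in high sub-bands (11-13 of 16) with
#' coupling 0.9, reflecting increased high-frequency content and channel
#' synchronization ahead of seizures.
#' @return A [regime_spec()].
#' @export
default_pre_spec <- function() {
  w <- rep(0, 16)
  w[11:13] <- c(0.3, 0.4, 0.3)
  regime_spec(w, coupling = 0.9, noise_sd = 1)
}

#' Default inter-ictal regime: low-frequency-dominant, weakly coupled
#'
#' Oscillatory energy in low sub-bands (2-4 of 16) with coupling 0.1.
#' @return A [regime_spec()].
#' @export
default_inter_spec <- function() {
  w <- rep(0, 16)
  w[2:4] <- c(0.3, 0.4, 0.3)
  regime_spec(w, coupling = 0.1, noise_sd = 1)
}

#' Simulation configuration
#'
#' @param n_channels Number of channels (default 18, the montage size).
#' @param sampling_rate Hz (default 256).
#' @param window_seconds Segment length in seconds (default 5).
#' @param pre_spec,inter_spec [regime_spec()] per class.
#' @param seed Master seed for dataset-level generation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 18, sampling_rate = 256,
                       window_seconds = 5, pre_spec = default_pre_spec(),
                       inter_spec = default_inter_spec(), seed = 1) {
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  if (length(pre_spec$band_weights) != length(inter_spec$band_weights)) {
    stop("pre and inter specs must share band dimensionality", call. = FALSE)
  }
  structure(list(n_channels = n_channels, sampling_rate = sampling_rate,
                 window_seconds = window_seconds, pre_spec = pre_spec,
                 inter_spec = inter_spec, seed = seed),
            class = "sim_config")
}

# One multichannel block of n_samples drawn from a regime. Band-limited
# content is synthesized directly in wavelet-packet coefficient space: band
# b of channel c receives a coefficient vector of squared norm exactly
# amplitude^2 * n/2 * band_weight[b], built as the normalized mixture
# sqrt(coupling) * u_shared + sqrt(1 - coupling) * u_private of unit
# Gaussian vectors, then mapped to the time domain by the inverse packet
# transform. Because the transform is orthonormal, the relative band-energy
# profile of the noiseless signal equals band_weights exactly, while the
# coupling sets the expected cross-channel correlation (coupling 1 gives
# identical channels). White noise is added on top. Expects the RNG to be
# seeded by the caller.
.synth_block <- function(n_samples, spec, n_channels, sampling_rate,
                         wavelet = "db4") {
  nb <- length(spec$band_weights)
  n2 <- as.integer(ceiling(n_samples / nb) * nb)
  m <- n2 %/% nb
  scale2 <- spec$amplitude^2 * n2 / 2          # total oscillatory energy
  active <- which(spec$band_weights > 0)
  unitize <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v else v / nv
  }
  coeffs <- replicate(n_channels,
                      replicate(nb, numeric(m), simplify = FALSE),
                      simplify = FALSE)
  for (b in active) {
    u_sh <- unitize(stats::rnorm(m))
    norm_b <- sqrt(spec$band_weights[b] * scale2)
    for (ch in seq_len(n_channels)) {
      v <- sqrt(spec$coupling) * u_sh +
        sqrt(1 - spec$coupling) * unitize(stats::rnorm(m))
      coeffs[[ch]][[b]] <- norm_b * unitize(v)
    }
  }
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    x <- .wp_reconstruct(coeffs[[ch]], wavelet)
    out[ch, ] <- x[seq_len(n_samples)]
  }
  if (spec$noise_sd > 0) {
    out <- out + matrix(stats::rnorm(n_channels * n_samples,
                                     sd = spec$noise_sd),
                        n_channels, n_samples)
  }
  out
}

#' Generate one labeled synthetic segment
#'
#' Deterministic given `(label, cfg, seed)`.
#'
#' @param label `"pre_ictal"` or `"inter_ictal"`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed for this segment.
#' @return An `eeg_segment`.
#' @export
generate_segment <- function(label, cfg, seed) {
  label <- match.arg(label, c("pre_ictal", "inter_ictal"))
  spec <- if (label == "pre_ictal") cfg$pre_spec else cfg$inter_spec
  n_samp <- round(cfg$window_seconds * cfg$sampling_rate)
  samples <- .with_seed(seed, .synth_block(n_samp, spec, cfg$n_channels,
                                           cfg$sampling_rate))
  rownames(samples) <- paste0("CH", seq_len(cfg$n_channels))
  structure(list(samples = samples, label = label, start_time = 0,
                 source_id = sprintf("sim_seed%d", seed),
                 sampling_rate = cfg$sampling_rate),
            class = "eeg_segment")
}

#' Generate an annotated synthetic recording
#'
#' Lays out, for each seizure, an inter-ictal gap, a full pre-ictal lead-in
#' synthesized from the pre-ictal regime, and a short ictal span (the ictal
#' waveform itself is not modeled; it is filled from the inter-ictal regime
#' and excluded from both classes by the labeling rule), then a trailing
#' inter-ictal stretch. Onset/offset annotations are attached so that
#' [label_intervals()] recovers the planted structure.
#'
#' @param cfg A [sim_config()].
#' @param n_seizures Number of seizures (>= 0).
#' @param seed Integer seed.
#' @param lead_in Pre-ictal lead-in length before each onset (s; default
#'   3600 so each onset has a full 1 h pre-ictal history).
#' @param gap_seconds Inter-ictal gap before each lead-in and after the last
#'   seizure (s).
#' @param seizure_seconds Ictal span length (s).
#' @param source_id Case identifier.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(cfg, n_seizures, seed, lead_in = 3600,
                               gap_seconds = 600, seizure_seconds = 20,
                               source_id = "sim_case") {
  if (n_seizures < 0) stop("n_seizures must be >= 0", call. = FALSE)
  fs <- cfg$sampling_rate
  blocks <- list()   # list of c(duration_s, is_pre)
  if (n_seizures == 0) {
    blocks[[1]] <- c(gap_seconds + lead_in, 0)
  } else {
    for (i in seq_len(n_seizures)) {
      blocks[[length(blocks) + 1]] <- c(gap_seconds, 0)
      blocks[[length(blocks) + 1]] <- c(lead_in, 1)
      blocks[[length(blocks) + 1]] <- c(seizure_seconds, 0)
    }
    blocks[[length(blocks) + 1]] <- c(gap_seconds, 0)
  }
  samples <- .with_seed(seed, {
    do.call(cbind, lapply(blocks, function(b) {
      spec <- if (b[2] == 1) cfg$pre_spec else cfg$inter_spec
      .synth_block(round(b[1] * fs), spec, cfg$n_channels, fs)
    }))
  })
  onsets <- offsets <- numeric(0)
  t0 <- 0
  for (b in blocks) {
    if (b[2] == 1) {
      onsets <- c(onsets, t0 + b[1])
      offsets <- c(offsets, t0 + b[1] + seizure_seconds)
    }
    t0 <- t0 + b[1]
  }
  eeg_recording(samples, fs, paste0("CH", seq_len(cfg$n_channels)),
                onsets, offsets, source_id = source_id)
}

#' Generate a balanced labeled segment dataset
#'
#' Per-segment seeds are derived from the master seed by a counter scheme:
#' segment `i` of the inter-ictal half uses `seed + i`, segment `i` of the
#' pre-ictal half uses `seed + n_per_class + i`. Inter-ictal segments come
#' first, then pre-ictal.
#'
#' @param cfg A [sim_config()].
#' @param n_per_class Segments per class (>= 1).
#' @param seed Master seed (defaults to `cfg$seed`).
#' @return List of `eeg_segment` objects, length `2 * n_per_class`.
#' @export
make_dataset <- function(cfg, n_per_class, seed = cfg$seed) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  inter <- lapply(seq_len(n_per_class), function(i) {
    generate_segment("inter_ictal", cfg, seed + i)
  })
  pre <- lapply(seq_len(n_per_class), function(i) {
    generate_segment("pre_ictal", cfg, seed + n_per_class + i)
  })
  c(inter, pre)
}
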