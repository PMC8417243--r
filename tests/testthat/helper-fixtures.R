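# Shared fixtures: small, fast synthetic configurations. The default
# sim_config() is the full-size study condition (18 channels, 256 Hz);
# these shrink channels/rate for unit tests where size is irrelevant.

small_sim <- function(n_channels = 4, sampling_rate = 64,
                      window_seconds = 2, noise_sd = 0.5) {
  pre <- regime_spec(c(rep(0, 10), 0.3, 0.4, 0.3, rep(0, 3)),
                     coupling = 0.9, noise_sd = noise_sd)
  inter <- regime_spec(c(0, 0.3, 0.4, 0.3, rep(0, 12)),
                       coupling = 0.1, noise_sd = noise_sd)
  sim_config(n_channels = n_channels, sampling_rate = sampling_rate,
             window_seconds = window_seconds, pre_spec = pre,
             inter_spec = inter)
}

# a recording object with given annotations but trivial signal content
flat_recording <- function(duration, fs = 16, n_channels = 2,
                           onsets = numeric(0), offsets = numeric(0)) {
  n <- round(duration * fs)
  set.seed(99)
  eeg_recording(matrix(rnorm(n_channels * n), n_channels, n), fs,
                paste0("CH", seq_len(n_channels)), onsets, offsets)
}

# random connected-ish symmetric adjacency with zero diagonal
random_adjacency <- function(n) {
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}
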