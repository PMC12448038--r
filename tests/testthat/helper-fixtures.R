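# Shared fixtures: everything is generated in code at test time.

# a short, light synthetic recording (mains off so low fs is legal)
small_recording <- function(seed = 3, fs = 100, block_s = 30, n_cycles = 2,
                            ...) {
  generate_recording(protocol_spec(block_s = block_s, n_cycles = n_cycles),
                     params = signal_params(seed = seed, line_amp_uv = 0, ...),
                     fs = fs)
}

# random-walk 24-channel code matrix (signed 24-bit range, small steps)
walk_codes <- function(n, sd = 50, seed = 42) {
  set.seed(seed)
  matrix(as.integer(round(cumsum(rnorm(24 * n, sd = sd)))), 24, n)
}

# hand-built spectrum_set (for statistical tests that bypass the FFT path)
fake_spectrum_set <- function(power, freqs, channels,
                              condition = "eyes_closed") {
  structure(list(power = power, freqs = freqs, channels = channels,
                 condition = condition, fs = 2 * max(freqs),
                 n_tapers = NA, nw = NA, nfft = NA),
            class = "spectrum_set")
}

# amplitude of the final steady-state stretch of a sinusoidal response
steady_amplitude <- function(x, fraction = 0.5) {
  tail_x <- x[max(1, floor(length(x) * (1 - fraction))):length(x)]
  sqrt(2 * mean(tail_x^2))
}
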