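# Shared fixture builders. Everything is generated in code; sessions used in
# several files live here so the conditions stay identical across tests.

# Standard validation session: 100 ms / 100 uV square wave, brown noise mixed
# at a 3:1 signal-to-noise ratio, 10 trials at 2048 Hz over a 1 s window.
snr3_session <- function(seed = 42, K = 10, snr = 3, noise = "brown",
                         fs = 2048, window = c(0, 1)) {
  make_session(synth_spec(shape = "square", noise = noise, snr = snr, K = K,
                          fs = fs, window = window), seed = seed)
}

# Small random trial matrix for algebraic identity checks.
random_matrix <- function(T_ = 40, K = 6, seed = 1) {
  set.seed(seed)
  matrix(rnorm(T_ * K), T_, K)
}

# Pure-noise session (no signal component).
noise_session <- function(seed, K = 10, n = 1024, fs = 1024,
                          noise = c("brown", "white")) {
  noise <- match.arg(noise)
  set.seed(seed)
  gen <- if (noise == "brown") brown_noise else white_noise
  V <- vapply(seq_len(K), function(j) gen(n), numeric(n))
  crp_epochs(V, fs = fs, t1 = 0, t2 = n / fs)
}
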