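# Shared fixtures. Expensive deterministic objects (the 1000-beat reference
# bank, DPSS tapers) are built once per test run; the DPSS cache inside the
# package makes repeated multitaper calls cheap.

the_bank <- reference_bank(1000)
small_bank <- reference_bank(1000, n_realizations = 10, seed = 7)

# a typical synthetic RR signal: baseline + LF + HF oscillation + noise
make_rr_signal <- function(seed, n = 1000, mean_rr = 800, lf = 25, hf = 30,
                           noise = 40) {
  withr::with_seed(seed, {
    i <- seq_len(n)
    mean_rr + lf * sin(2 * pi * 0.10 * i + runif(1, 0, 2 * pi)) +
      hf * sin(2 * pi * 0.25 * i + runif(1, 0, 2 * pi)) +
      noise * rnorm(n)
  })
}

write_rr_tempfile <- function(values, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = env)
  writeLines(format(values, trim = TRUE, scientific = FALSE, digits = 15), path)
  path
}

# independent segment-averaged periodogram oracle: explicit DFT sums, no
# shared code with welch_psd beyond the window function values
oracle_welch <- function(x, seg = 256, fs = 1) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1)) / (seg - 1)) # symmetric Hamming
  n_seg <- floor(length(x) / seg)
  nbins <- seg / 2 + 1
  freqs <- (0:(seg / 2)) / seg
  t <- 0:(seg - 1)
  acc <- numeric(nbins)
  for (s in seq_len(n_seg)) {
    xs <- x[((s - 1) * seg + 1):(s * seg)] * w
    for (b in seq_len(nbins)) {
      f <- freqs[b]
      re <- sum(xs * cos(2 * pi * f * t))
      im <- -sum(xs * sin(2 * pi * f * t))
      acc[b] <- acc[b] + (re^2 + im^2) / (fs * sum(w^2))
    }
  }
  pxx <- acc / n_seg
  pxx[2:(nbins - 1)] <- 2 * pxx[2:(nbins - 1)]
  list(frequency = freqs * fs, power = pxx)
}
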