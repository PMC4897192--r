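#' Power spectral density estimates
#'
#' Both spectral estimators return a `psd_estimate`: a tibble with columns
#' `frequency` (cycles per beat; beats are treated as unit-spaced samples,
#' so with `fs = 1` this reads as Hz) and `power` (one-sided spectral
#' density), with the estimator settings attached as attributes. The grid
#' runs from 0 to `fs/2` with `nfft/2 + 1` points.
#'
#' @name psd_estimate
#' @seealso [welch_psd()], [mtm_psd()]
NULL

new_psd_estimate <- function(freqs, power, method, settings) {
  new_tibble(
    list(frequency = freqs, power = power),
    nrow = length(freqs),
    class = "psd_estimate",
    method = method,
    settings = settings
  )
}

#' @rdname psd_estimate
#' @param x A `psd_estimate`.
#' @export
psd_method <- function(x) attr(x, "method")

#' @rdname psd_estimate
#' @export
psd_settings <- function(x) attr(x, "settings")

hamming_window <- function(n) {
  # symmetric (MATLAB-convention) Hamming window
  as.numeric(signal::hamming(n))
}

#' Welch power spectrum of an RR series
#'
#' Averaged modified periodogram with the settings used throughout the
#' chaotic-globals computations: unit sampling frequency (one sample per
#' beat), Hamming window, zero overlap, no detrending (the mean is kept, so
#' a constant series shows all its power at frequency zero), FFT length
#' 256. The series is cut into `floor(n / segment_length)` complete
#' segments; a trailing incomplete segment is dropped.
#'
#' @param series An [rr_series()] or numeric vector (>= `segment_length`
#'   samples).
#' @param fs Sampling frequency; the per-beat convention is 1.
#' @param nfft FFT length (also the frequency grid: `nfft/2 + 1` bins).
#' @param segment_length Samples per segment; defaults to `nfft`.
#' @return A [psd_estimate] tibble with `method = "welch"`.
#' @export
#' @examples
#' x <- sin(2 * pi * 0.125 * seq_len(1000))
#' p <- welch_psd(x)
#' p$frequency[which.max(p$power)]
welch_psd <- function(series, fs = 1, nfft = 256, segment_length = nfft) {
  x <- rr_intervals(series)
  n <- length(x)
  if (segment_length > nfft) {
    abort("`segment_length` must not exceed `nfft`")
  }
  n_seg <- floor(n / segment_length)
  if (n_seg < 1) {
    abort(sprintf(
      "Welch estimate needs at least %d samples, got %d", segment_length, n
    ))
  }
  w <- hamming_window(segment_length)
  scale <- 1 / (fs * sum(w^2))
  nbins <- nfft / 2 + 1
  acc <- numeric(nbins)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * segment_length + 1):(s * segment_length)]
    padded <- c(w * seg, numeric(nfft - segment_length))
    X <- fft(padded)[seq_len(nbins)]
    acc <- acc + Re(X * Conj(X)) * scale
  }
  pxx <- acc / n_seg
  pxx[2:(nbins - 1)] <- 2 * pxx[2:(nbins - 1)] # fold negative frequencies
  new_psd_estimate(
    freqs = seq(0, fs / 2, length.out = nbins),
    power = pxx,
    method = "welch",
    settings = list(
      fs = fs, nfft = nfft, segment_length = segment_length,
      window = "hamming", overlap = 0, detrend = "none", n_segments = n_seg
    )
  )
}

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS of length `n` at time-bandwidth product
#' `nw`, via the classical symmetric tridiagonal eigenproblem, together
#' with their spectral concentrations (fraction of taper energy inside the
#' band `[-nw/n, nw/n]`, from the sinc-kernel quadratic form). Tapers are
#' unit-energy and mutually orthonormal. Results are cached per
#' `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (study setting: 3).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return A list with `tapers` (an `n` x `k` matrix) and `eigenvalues`
#'   (the `k` concentrations, all close to 1 for low orders).
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  key <- sprintf("dpss_%d_%s_%d", n, format(nw), k)
  hit <- .chaoglob_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  if (n < 2 * k) {
    abort(sprintf("need n >= %d samples for %d tapers", 2 * k, k))
  }
  W <- nw / n
  if (W >= 0.5) {
    abort("time-bandwidth `nw` too large for this series length (nw/n must be < 1/2)")
  }
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(t + 1, t + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  # polarity convention: symmetric tapers have positive mean, antisymmetric
  # tapers a positive initial lobe
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2, j] < V[1, j] || V[2, j] < 0) {
      V[, j] <- -V[, j]
    }
  }
  # concentrations: lambda = v' S v with S the band-limiting sinc kernel
  dt <- outer(t, t, "-")
  S <- sin(2 * pi * W * dt) / (pi * dt)
  diag(S) <- 2 * W
  lambda <- vapply(seq_len(k), function(j) drop(crossprod(V[, j], S %*% V[, j])), numeric(1))
  lambda <- pmin(pmax(lambda, 0), 1)
  out <- list(tapers = V, eigenvalues = lambda, nw = nw, n = n, k = k)
  assign(key, out, envir = .chaoglob_cache)
  out
}

#' Thomson adaptive multitaper power spectrum
#'
#' Multitaper estimate using DPSS tapers spanning the full series length
#' (time-bandwidth 3, five tapers by default) with Thomson's adaptive
#' nonlinear combination of the eigenspectra. The spectrum is evaluated on
#' the same `nfft`-point one-sided grid as [welch_psd()]: eigenspectra are
#' zero-padded to the smallest multiple of `nfft` that is a power-of-two
#' factor above the series length, then decimated to the `nfft` grid, which
#' evaluates the transform exactly at frequencies `j / nfft`. No
#' detrending: the mean is kept, so a constant series yields a pure DC
#' line, not an error.
#'
#' Adaptive weighting follows the standard iteration: starting from the
#' average of the two lowest-order eigenspectra, coefficients
#' `b_k(f) = S(f) / (lambda_k S(f) + (1 - lambda_k) sigma2)` are updated
#' until the normalized weights `lambda_k b_k^2 / sum(lambda_k b_k^2)`
#' (each in `[0, 1]`, summing to 1 at every frequency) change by less than
#' `adapt_tol`, or `max_iter` passes.
#'
#' @inheritParams welch_psd
#' @param nw Time-bandwidth product for the DPSS (default 3).
#' @param k Number of tapers (default `2 * nw - 1 = 5`).
#' @param adapt_tol Convergence tolerance on the weight change (default 1e-10).
#' @param max_iter Iteration cap (default 400; line-dominated spectra
#'   converge slowest — a pure sine needs ~110 passes and a strongly
#'   DC-dominated raw RR series ~210).
#' @return A [psd_estimate] tibble with `method = "mtm"`; the final
#'   normalized adaptive weights are attached as attribute `"weights"`
#'   (bins x tapers) and the iteration count in the settings.
#' @export
mtm_psd <- function(series, fs = 1, nfft = 256, nw = 3, k = 2 * nw - 1,
                    adapt_tol = 1e-10, max_iter = 400) {
  x <- rr_intervals(series)
  n <- length(x)
  dp <- dpss_tapers(n, nw = nw, k = k)
  nbins <- nfft / 2 + 1
  # evaluate the length-n tapered transforms exactly on the j/nfft grid
  npad <- nfft
  while (npad < n) npad <- npad * 2
  stride <- npad / nfft
  Sk <- matrix(0, nbins, k)
  for (j in seq_len(k)) {
    padded <- c(dp$tapers[, j] * x, numeric(npad - n))
    X <- fft(padded)[seq(1, npad / 2 + 1, by = stride)]
    Sk[, j] <- Re(X * Conj(X)) / fs
  }
  Sk[2:(nbins - 1), ] <- 2 * Sk[2:(nbins - 1), ]
  sigma2 <- mean(x^2) # total process power; mean retained by design
  lambda <- dp$eigenvalues
  converged <- TRUE
  if (sigma2 <= 0) {
    S <- numeric(nbins)
    wts <- matrix(1 / k, nbins, k)
    iters <- 0L
  } else {
    S <- rowMeans(Sk[, 1:2, drop = FALSE])
    wts <- matrix(1 / k, nbins, k)
    iters <- max_iter
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      B <- S / (outer(S, lambda) + outer(rep(sigma2, nbins), 1 - lambda))
      num <- (B^2 %*% diag(lambda, k)) # lambda_k b_k^2
      den <- rowSums(num)
      new_wts <- num / den
      S_new <- rowSums(new_wts * Sk)
      delta <- max(abs(new_wts - wts))
      wts <- new_wts
      S <- S_new
      if (delta < adapt_tol) {
        iters <- it
        converged <- TRUE
        break
      }
    }
  }
  out <- new_psd_estimate(
    freqs = seq(0, fs / 2, length.out = nbins),
    power = S,
    method = "mtm",
    settings = list(
      fs = fs, nfft = nfft, nw = nw, k = k, detrend = "none",
      adapt_tol = adapt_tol, iterations = iters, converged = converged,
      eigenvalues = lambda
    )
  )
  attr(out, "weights") <- wts
  out
}

#' Export a spectrum as two-column text or JSON
#'
#' @param x A [psd_estimate].
#' @param path Output path.
#' @param format `"text"` (two whitespace-separated columns, frequency and
#'   power) or `"json"` (frequencies, power and the full settings record).
#' @return `path`, invisibly.
#' @export
write_psd <- function(x, path, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "psd_estimate"))
  if (format == "text") {
    utils::write.table(
      data.frame(frequency = x$frequency, power = x$power),
      path,
      row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  } else {
    jsonlite::write_json(
      list(
        method = psd_method(x),
        settings = psd_settings(x),
        frequency = x$frequency,
        power = x$power
      ),
      path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
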