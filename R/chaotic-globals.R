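#' Shannon entropy of a discrete distribution
#'
#' `H = -sum(p * log(p))` in nats, with the convention `0 * log(0) = 0`.
#' Used on sum-normalized power spectra; the logarithm base cancels in the
#' downstream two-point normalization.
#'
#' @param p Nonnegative probability vector summing to 1 (within 1e-9).
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon_entropy(rep(1 / 128, 128)) # log(128)
shannon_entropy <- function(p) {
  if (any(p < 0)) {
    abort("probabilities must be nonnegative")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("probabilities must sum to 1 (got %.12f)", sum(p)))
  }
  nz <- p[p > 0]
  -sum(nz * log(nz))
}

#' Log-spaced DFA box sizes
#'
#' @param n_points Length of the sequence to be analysed.
#' @param n_min,n_max Smallest and largest box (defaults 4 and
#'   `floor(n_points / 4)`).
#' @param n_sizes Number of (unique, integer) log-spaced sizes.
#' @return Integer vector of box sizes.
#' @export
dfa_boxes <- function(n_points, n_min = 4, n_max = floor(n_points / 4),
                      n_sizes = 8) {
  stopifnot(n_min >= 4, n_max >= n_min)
  unique(round(exp(seq(log(n_min), log(n_max), length.out = n_sizes))))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Classic DFA-1: the mean-subtracted sequence is integrated to a profile,
#' cut into non-overlapping boxes of each size, a least-squares line is
#' removed per box, and `F(n)` is the root-mean-square residual over all
#' complete boxes. The exponent `alpha` is the least-squares slope of
#' `log F(n)` against `log n`. Uncorrelated noise gives `alpha ~ 0.5`,
#' its running sum `alpha ~ 1.5`. Here the sequence may equally be a power
#' spectrum indexed by frequency bin (the sDFA usage) — the algorithm is
#' axis-agnostic.
#'
#' @param y Ordered numeric sequence.
#' @param box_sizes Integer box sizes; all must lie in
#'   `[4, length(y) / 4]`. Default: [dfa_boxes()].
#' @return The scaling exponent `alpha` (dimensionless). The per-size
#'   fluctuations are attached as attribute `"fluctuations"`.
#' @export
dfa_exponent <- function(y, box_sizes = dfa_boxes(length(y))) {
  y <- as.numeric(y)
  N <- length(y)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 2) {
    abort("need at least two distinct box sizes")
  }
  if (min(box_sizes) < 4 || max(box_sizes) > N / 4) {
    abort(sprintf(
      "box sizes must lie in [4, %d] for a sequence of length %d",
      floor(N / 4), N
    ))
  }
  z <- cumsum(y - mean(y))
  Fn <- vapply(box_sizes, function(n) {
    nb <- N %/% n
    Y <- matrix(z[seq_len(nb * n)], nrow = n)
    t <- seq_len(n)
    St <- sum(t)
    Stt <- sum(t^2)
    Sy <- colSums(Y)
    Sty <- drop(crossprod(t, Y))
    slope <- (n * Sty - St * Sy) / (n * Stt - St^2)
    intercept <- (Sy - slope * St) / n
    res <- Y - outer(t, slope) - matrix(intercept, n, nb, byrow = TRUE)
    sqrt(mean(res^2))
  }, numeric(1))
  if (any(Fn <= 0)) {
    abort("degenerate fluctuation: F(n) = 0 for some box size")
  }
  fit <- lm(log(Fn) ~ log(box_sizes))
  alpha <- unname(coef(fit)[2])
  attr(alpha, "fluctuations") <- tibble(n = box_sizes, F = Fn)
  alpha
}

#' Reference bank for the three-condition normalization
#'
#' The chaotic globals are affinely rescaled so that a pure sine wave
#' scores 0 and uniformly distributed random noise scores 1. This object
#' holds the standardized (zero-mean, unit-SD) reference signals: one sine
#' at a bin-centred frequency and `n_realizations` seeded uniform-noise
#' realizations (averaging the random-reference statistic over
#' realizations reduces its sampling variance). When a series is scored it
#' is standardized to the same zero-mean, unit-SD footing, so the
#' comparison isolates spectral shape from amplitude and offset — the
#' globals are exactly invariant to uniform rescaling and shifts of the
#' input, and the otherwise-dominant DC term of a raw RR spectrum drops
#' out.
#'
#' @param n Reference length; must equal the length of the analysed series
#'   (study standard: 1000 beats).
#' @param sine_freq Sine frequency in cycles per beat; should sit on the
#'   `nfft`-point grid (default 0.125 = bin 32 of 256).
#' @param n_realizations Number of uniform-noise realizations (default 50).
#' @param seed Integer seed for the noise realizations.
#' @param nfft FFT grid the sine must be centred on (for the check only).
#' @return An object of class `reference_bank`.
#' @export
reference_bank <- function(n, sine_freq = 0.125, n_realizations = 50,
                           seed = 42, nfft = 256) {
  stopifnot(n >= nfft, n_realizations >= 1)
  if (abs(sine_freq * nfft - round(sine_freq * nfft)) > 1e-8) {
    warn(sprintf(
      "sine_freq %.5f is not bin-centred on the %d-point grid", sine_freq, nfft
    ))
  }
  t <- 0:(n - 1)
  z_sine <- sin(2 * pi * sine_freq * t)
  z_sine <- (z_sine - mean(z_sine)) / sd(z_sine)
  Z <- withr::with_seed(seed, matrix(runif(n * n_realizations), n, n_realizations))
  Z <- scale(Z) # exact zero mean, unit sd per column
  attributes(Z) <- attributes(Z)["dim"]
  structure(
    list(
      n = n, sine_freq = sine_freq, n_realizations = n_realizations,
      seed = seed, z_sine = as.numeric(z_sine), z_random = Z
    ),
    class = "reference_bank"
  )
}

#' @export
print.reference_bank <- function(x, ...) {
  cat(sprintf(
    "<reference_bank> n = %d, sine at %.4f cycles/beat, %d uniform realizations (seed %d)\n",
    x$n, x$sine_freq, x$n_realizations, x$seed
  ))
  invisible(x)
}

#' Materialize a reference signal at a given mean and SD
#'
#' Returns the exact signal a [reference_bank()] would compare a series of
#' that mean and standard deviation against. Feeding the sine reference
#' back into [spectral_entropy()] (or [sdfa()], [smtm()]) returns the
#' lower fixed point 0 exactly.
#'
#' @param bank A [reference_bank()].
#' @param type `"sine"` or `"random"`.
#' @param mean,sd Target sample mean and standard deviation (milliseconds,
#'   for RR usage).
#' @param realization Which noise realization (for `type = "random"`).
#' @return Numeric vector of length `bank$n`.
#' @export
reference_series <- function(bank, type = c("sine", "random"),
                             mean = 800, sd = 50, realization = 1) {
  type <- match.arg(type)
  stopifnot(inherits(bank, "reference_bank"))
  z <- if (type == "sine") bank$z_sine else bank$z_random[, realization]
  mean + sd * z
}

.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

.norm_psd <- function(power) power / sum(power)

.smtm_area <- function(psd, baseline, scale = "amplitude") {
  y <- switch(scale,
    amplitude = sqrt(psd$power),
    power = psd$power,
    abort("`scale` must be 'amplitude' or 'power'")
  )
  base <- switch(baseline,
    min = min(y),
    zero = 0,
    abort("`baseline` must be 'min' or 'zero'")
  )
  .trapz(psd$frequency, y - base)
}

# Shared engine: computes the requested globals and all raw intermediates
# for one series against its (rescaled) references.
.globals_engine <- function(x, bank, what = c("se", "sdfa", "smtm"),
                            nfft = 256, segment_length = nfft,
                            box_sizes = NULL, baseline = "min",
                            scale = "amplitude", nw = 3, k = 2 * nw - 1) {
  x <- rr_intervals(x)
  m <- base::mean(x)
  s <- sd(x)
  if (!is.finite(s) || s <= 0) {
    abort("chaotic globals are undefined for a constant series (zero variance)")
  }
  if (is.null(bank)) {
    bank <- reference_bank(length(x), nfft = nfft)
  }
  if (bank$n != length(x)) {
    abort(sprintf(
      "reference bank length (%d) must match series length (%d)",
      bank$n, length(x)
    ))
  }
  # the globals characterize spectral *shape*: the series is standardized
  # before spectral estimation so the statistics are compared against the
  # (equally standardized) references on equal footing. Without this, the
  # DC bin of a raw RR spectrum (mean ~800 ms vs SD ~40 ms) carries >99%
  # of the power and swamps every statistic.
  x <- (x - m) / s
  sine <- bank$z_sine
  rands <- lapply(seq_len(bank$n_realizations), function(r) bank$z_random[, r])
  raw <- list()
  out <- list()

  if (any(c("se", "sdfa") %in% what)) {
    p_sig <- .norm_psd(welch_psd(x, nfft = nfft, segment_length = segment_length)$power)
    p_sine <- .norm_psd(welch_psd(sine, nfft = nfft, segment_length = segment_length)$power)
    p_rand <- lapply(rands, function(r) {
      .norm_psd(welch_psd(r, nfft = nfft, segment_length = segment_length)$power)
    })
    if ("se" %in% what) {
      H_sig <- shannon_entropy(p_sig)
      H_sine <- shannon_entropy(p_sine)
      H_rand <- base::mean(vapply(p_rand, shannon_entropy, numeric(1)))
      if (H_rand <= H_sine) {
        abort("degenerate reference bank: random-reference entropy does not exceed the sine reference")
      }
      out$se <- (H_sig - H_sine) / (H_rand - H_sine)
      raw$H_sig <- H_sig
      raw$H_sine <- H_sine
      raw$H_rand <- H_rand
    }
    if ("sdfa" %in% what) {
      boxes <- box_sizes %||% dfa_boxes(length(p_sig), n_min = 4, n_max = 32, n_sizes = 8)
      a_sig <- as.numeric(dfa_exponent(p_sig, boxes))
      a_sine <- as.numeric(dfa_exponent(p_sine, boxes))
      a_rand <- base::mean(vapply(p_rand, function(p) as.numeric(dfa_exponent(p, boxes)), numeric(1)))
      if (abs(a_rand - a_sine) < 1e-12) {
        abort("degenerate reference bank: sine and random DFA exponents coincide")
      }
      out$sdfa <- (a_sig - a_sine) / (a_rand - a_sine)
      raw$alpha_sig <- a_sig
      raw$alpha_sine <- a_sine
      raw$alpha_rand <- a_rand
    }
  }
  if ("smtm" %in% what) {
    A_sig <- .smtm_area(mtm_psd(x, nfft = nfft, nw = nw, k = k), baseline, scale)
    A_sine <- .smtm_area(mtm_psd(sine, nfft = nfft, nw = nw, k = k), baseline, scale)
    A_rand <- base::mean(vapply(rands, function(r) {
      .smtm_area(mtm_psd(r, nfft = nfft, nw = nw, k = k), baseline, scale)
    }, numeric(1)))
    if (abs(A_rand - A_sine) < 1e-12) {
      abort("degenerate reference bank: sine and random multitaper areas coincide")
    }
    out$smtm <- (A_sig - A_sine) / (A_rand - A_sine)
    raw$area_sig <- A_sig
    raw$area_sine <- A_sine
    raw$area_rand <- A_rand
  }
  out$raw <- raw
  out
}

#' Normalized spectral entropy of an RR series
#'
#' Shannon entropy of the sum-normalized Welch power spectrum, rescaled by
#' the two-point map that sends the sine reference to 0 and the mean
#' uniform-noise reference to 1. Experimental RR series typically score
#' between the two fixed points; values slightly outside `[0, 1]` are
#' possible for extreme inputs and are returned as-is.
#'
#' @param series An [rr_series()] or numeric vector of interbeat intervals.
#' @param bank A [reference_bank()] of matching length; built with default
#'   settings when `NULL`.
#' @param nfft,segment_length Welch settings, see [welch_psd()].
#' @return The normalized spectral entropy (scalar).
#' @export
spectral_entropy <- function(series, bank = NULL, nfft = 256,
                             segment_length = nfft) {
  .globals_engine(series, bank,
    what = "se", nfft = nfft,
    segment_length = segment_length
  )$se
}

#' Normalized spectral DFA (sDFA) of an RR series
#'
#' Identical three-reference scheme to [spectral_entropy()], but the
#' statistic applied to each normalized Welch spectrum is the DFA scaling
#' exponent of power against frequency bin (default: 8 log-spaced box
#' sizes from 4 to 32 on the 129-bin spectrum). sDFA responds to chaotic
#' content in the opposite direction to the other two globals, which is
#' why CFP combination subtracts it from unity.
#'
#' @inheritParams spectral_entropy
#' @param box_sizes DFA box sizes on the spectrum (default 4..32,
#'   log-spaced, 8 sizes).
#' @return The normalized sDFA value (scalar).
#' @export
sdfa <- function(series, bank = NULL, nfft = 256, segment_length = nfft,
                 box_sizes = NULL) {
  .globals_engine(series, bank,
    what = "sdfa", nfft = nfft,
    segment_length = segment_length, box_sizes = box_sizes
  )$sdfa
}

#' Normalized spectral multitaper measure (sMTM) of an RR series
#'
#' The raw statistic is the area between the Thomson adaptive multitaper
#' spectrum and its baseline (the spectrum minimum by default), a measure
#' that grows with the intensity of broadband noise — the signature of
#' irregular, chaotic signals. The raw area is then passed through the
#' same sine-to-0 / noise-to-1 normalization as the other two globals so
#' that all three are commensurate when combined with equal weighting.
#'
#' By default the area is computed on the amplitude (root-power) spectrum.
#' On the power scale a handful of near-line bins carry almost the whole
#' area and the statistic is dominated by how the frequency grid samples
#' those peaks; the root-power scale keeps the broadband floor — the
#' quantity sMTM is meant to sense — visible in the area while preserving
#' the minimum-baseline definition. `scale = "power"` restores the plain
#' power-spectral area.
#'
#' @inheritParams spectral_entropy
#' @param baseline `"min"` (area above the spectrum minimum, default) or
#'   `"zero"` (plain integral).
#' @param scale `"amplitude"` (default; area of the root-power spectrum)
#'   or `"power"`.
#' @param nw,k Multitaper settings, see [mtm_psd()].
#' @return The normalized sMTM value (scalar).
#' @export
smtm <- function(series, bank = NULL, nfft = 256, baseline = c("min", "zero"),
                 scale = c("amplitude", "power"), nw = 3, k = 2 * nw - 1) {
  baseline <- match.arg(baseline)
  scale <- match.arg(scale)
  .globals_engine(series, bank,
    what = "smtm", nfft = nfft,
    baseline = baseline, scale = scale, nw = nw, k = k
  )$smtm
}

#' Raw sMTM area of a multitaper spectrum
#'
#' Trapezoidal integral of the spectrum above its baseline, before any
#' reference normalization.
#'
#' @param psd A [psd_estimate] (usually from [mtm_psd()]).
#' @param baseline `"min"` or `"zero"`.
#' @param scale `"amplitude"` (default) or `"power"`, see [smtm()].
#' @return The raw area.
#' @export
smtm_area <- function(psd, baseline = c("min", "zero"),
                      scale = c("amplitude", "power")) {
  stopifnot(inherits(psd, "psd_estimate"))
  .smtm_area(psd, match.arg(baseline), match.arg(scale))
}

#' All three chaotic globals of one series
#'
#' Computes normalized spectral entropy, sDFA and sMTM in one pass
#' (sharing the Welch spectra of the series and its references), returning
#' one tidy row per series.
#'
#' @inheritParams spectral_entropy
#' @inheritParams smtm
#' @inheritParams sdfa
#' @return A one-row tibble with columns `subject_id`, `group`, `se`,
#'   `sdfa`, `smtm` and a list-column `raw` holding the unnormalized
#'   intermediates (entropies, DFA exponents and multitaper areas of the
#'   signal and both references).
#' @export
#' @examples
#' \donttest{
#' bank <- reference_bank(1000, n_realizations = 5)
#' x <- 800 + 40 * sin(2 * pi * 0.1 * 1:1000) + rnorm(1000, sd = 20)
#' chaotic_globals(x, bank)
#' }
chaotic_globals <- function(series, bank = NULL, nfft = 256,
                            segment_length = nfft, box_sizes = NULL,
                            baseline = c("min", "zero"),
                            scale = c("amplitude", "power"),
                            nw = 3, k = 2 * nw - 1) {
  baseline <- match.arg(baseline)
  scale <- match.arg(scale)
  res <- .globals_engine(series, bank,
    what = c("se", "sdfa", "smtm"),
    nfft = nfft, segment_length = segment_length, box_sizes = box_sizes,
    baseline = baseline, scale = scale, nw = nw, k = k
  )
  tibble(
    subject_id = if (inherits(series, "rr_series")) attr(series, "subject_id") else "series",
    group = if (inherits(series, "rr_series")) attr(series, "group") else "unknown",
    se = res$se,
    sdfa = res$sdfa,
    smtm = res$smtm,
    raw = list(res$raw)
  )
}

#' Score every subject of a cohort
#'
#' Maps [chaotic_globals()] over a list of series (all of the same length)
#' with one shared reference bank, returning one row per subject.
#'
#' @param series_list List of [rr_series()] (or numeric vectors).
#' @inheritParams chaotic_globals
#' @return A tibble with one row per subject: `subject_id`, `group`, `se`,
#'   `sdfa`, `smtm`, `raw`.
#' @export
score_cohort <- function(series_list, bank = NULL, nfft = 256,
                         segment_length = nfft, box_sizes = NULL,
                         baseline = c("min", "zero"),
                         scale = c("amplitude", "power"),
                         nw = 3, k = 2 * nw - 1) {
  baseline <- match.arg(baseline)
  scale <- match.arg(scale)
  lens <- vapply(series_list, function(s) length(rr_intervals(s)), integer(1))
  if (length(unique(lens)) != 1) {
    abort("all series in a cohort must have the same analysed length")
  }
  if (is.null(bank)) {
    bank <- reference_bank(lens[1], nfft = nfft)
  }
  purrr::map_dfr(series_list, chaotic_globals,
    bank = bank, nfft = nfft,
    segment_length = segment_length, box_sizes = box_sizes,
    baseline = baseline, scale = scale, nw = nw, k = k
  )
}
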