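#' Specification of a synthetic RR cohort
#'
#' Describes a group of resting supine RR recordings as a sum of two
#' sinusoidal oscillations — placed at the conventional low-frequency and
#' high-frequency HRV bands in cycles per beat — plus broadband Gaussian
#' beat-to-beat noise, with per-subject amplitude variation. This is a
#' statistical stand-in with the spectral features the chaotic-globals
#' pipeline measures, not a physiological model of heart-rate control.
#'
#' @param n_subjects Subjects in the group (default 19).
#' @param n_beats Beats per series (default 1000; must be >= 256).
#' @param mean_rr Baseline interbeat interval in ms (default 800).
#' @param lf_freq,hf_freq Oscillation frequencies in cycles/beat
#'   (defaults 0.10 and 0.25).
#' @param lf_amp,hf_amp Oscillation amplitudes in ms.
#' @param noise_sd Broadband Gaussian beat-to-beat noise SD in ms.
#' @param between_subject_cv Fractional between-subject variation of the
#'   amplitudes and noise level (default 0.2).
#' @param group Group label for the generated series.
#' @param seed Master integer seed; generation is deterministic per
#'   `(seed, subject_index)`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 19, n_beats = 1000, mean_rr = 800,
                        lf_freq = 0.10, hf_freq = 0.25,
                        lf_amp = 25, hf_amp = 30, noise_sd = 40,
                        between_subject_cv = 0.2,
                        group = c("normal", "copd", "unknown"), seed = 1) {
  group <- match.arg(group)
  if (n_beats < 256) abort("`n_beats` must be at least 256")
  if (mean_rr <= 0) abort("`mean_rr` must be positive")
  if (any(c(lf_amp, hf_amp, noise_sd, between_subject_cv) < 0)) {
    abort("amplitudes, noise SD and CV must be nonnegative")
  }
  if (any(c(lf_freq, hf_freq) <= 0 | c(lf_freq, hf_freq) >= 0.5)) {
    abort("oscillation frequencies must lie in (0, 0.5) cycles/beat")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_beats = as.integer(n_beats),
      mean_rr = mean_rr, lf_freq = lf_freq, hf_freq = hf_freq,
      lf_amp = lf_amp, hf_amp = hf_amp, noise_sd = noise_sd,
      between_subject_cv = between_subject_cv, group = group,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# deterministic per-(seed, group, subject) stream seed, kept below 2^31
.subject_seed <- function(seed, group, subject_index) {
  offset <- switch(group, normal = 0, copd = 1000003, unknown = 2000003)
  as.integer((abs(as.numeric(seed)) * 10007 + offset + subject_index * 9973) %% 2147483629)
}

#' Generate one synthetic RR series
#'
#' Beat `i` is
#' `mean_rr + a_lf sin(2 pi lf_freq i + phi1) + a_hf sin(2 pi hf_freq i + phi2) + noise_sd_i e_i`
#' with subject-level amplitudes drawn once from the between-subject
#' distribution (truncated at zero), phases uniform, and `e_i` standard
#' Gaussian. Intervals that would fall at or below zero under pathological
#' settings are clamped to a 200 ms floor with a warning so downstream
#' spectra never see invalid input.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index 1-based subject number within the group.
#' @return An [rr_series()] of `spec$n_beats` beats.
#' @export
generate_series <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"), subject_index >= 1)
  s <- .subject_seed(spec$seed, spec$group, subject_index)
  withr::with_seed(s, {
    cv <- spec$between_subject_cv
    a_lf <- spec$lf_amp * max(0, 1 + cv * rnorm(1))
    a_hf <- spec$hf_amp * max(0, 1 + cv * rnorm(1))
    s_noise <- spec$noise_sd * max(0, 1 + cv * rnorm(1))
    phi <- runif(2, 0, 2 * pi)
    i <- seq_len(spec$n_beats)
    rr <- spec$mean_rr +
      a_lf * sin(2 * pi * spec$lf_freq * i + phi[1]) +
      a_hf * sin(2 * pi * spec$hf_freq * i + phi[2]) +
      s_noise * rnorm(spec$n_beats)
    n_clamped <- sum(rr < 200)
    if (n_clamped > 0) {
      warn(sprintf(
        "clamped %d nonpositive/implausible interval(s) to the 200 ms floor",
        n_clamped
      ))
      rr[rr < 200] <- 200
    }
    rr_series(
      rr,
      subject_id = sprintf("%s-%02d", spec$group, subject_index),
      group = spec$group
    )
  })
}

#' Generate the two demo cohorts
#'
#' The 19 + 19 synthetic study: a "normal" group with rich broadband and
#' high-frequency content, and a "COPD-like" group with the same baseline
#' rhythm but reduced beat-to-beat noise and reduced high-frequency
#' amplitude — the simplest mechanism producing a decreased chaotic
#' response, which is the direction the pipeline is designed to detect.
#' Defaults (frozen): normal `noise_sd = 40`, `hf_amp = 30`; COPD-like
#' `noise_sd = 15`, `hf_amp = 12`; both `mean_rr = 800`, `lf_amp = 25`,
#' `between_subject_cv = 0.2`.
#'
#' @param seed Master integer seed.
#' @param n_subjects Subjects per group (default 19).
#' @param normal,copd Optional [cohort_spec()] overrides for either group
#'   (their `group` and `seed` fields are forced to match).
#' @return A tibble with one row per subject: `subject_id`, `group` and a
#'   list-column `series` of [rr_series()].
#' @export
#' @examples
#' cohorts <- generate_demo_cohorts(seed = 1, n_subjects = 3)
#' table(cohorts$group)
generate_demo_cohorts <- function(seed = 1, n_subjects = 19,
                                  normal = NULL, copd = NULL) {
  normal <- normal %||% cohort_spec(
    n_subjects = n_subjects, group = "normal", seed = seed
  )
  copd <- copd %||% cohort_spec(
    n_subjects = n_subjects, group = "copd", seed = seed,
    noise_sd = 15, hf_amp = 12
  )
  normal$group <- "normal"
  copd$group <- "copd"
  normal$seed <- as.integer(seed)
  copd$seed <- as.integer(seed)
  one_group <- function(spec) {
    purrr::map(seq_len(spec$n_subjects), function(i) generate_series(spec, i))
  }
  series <- c(one_group(normal), one_group(copd))
  tibble(
    subject_id = vapply(series, function(s) attr(s, "subject_id"), character(1)),
    group = vapply(series, function(s) attr(s, "group"), character(1)),
    series = series
  )
}

#' Write a generated cohort to disk
#'
#' One-column RR text file per subject plus a `manifest.csv`
#' (`subject_id`, `group`, `file`, `seed`).
#'
#' @param cohorts Tibble from [generate_demo_cohorts()].
#' @param dir Output directory (created if absent).
#' @param seed The master seed to record in the manifest.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohorts, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(seq_len(nrow(cohorts)), function(i) {
    f <- file.path(dir, paste0(cohorts$subject_id[i], ".txt"))
    write_rr(cohorts$series[[i]], f, sidecar = FALSE)
    basename(f)
  }, character(1))
  manifest <- tibble(
    subject_id = cohorts$subject_id,
    group = cohorts$group,
    file = files,
    seed = seed
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Run the full demo study
#'
#' Generation, scoring, CFP combination and cohort report in one call:
#' the end-to-end pipeline on the seeded 19 + 19 synthetic cohorts.
#'
#' @inheritParams generate_demo_cohorts
#' @param bank_seed Seed for the [reference_bank()] (default 42).
#' @param combination CFP combining rule, see [compute_cfp()].
#' @param n_realizations Uniform-noise realizations in the reference bank.
#' @return A list: `cohorts` (generated series), `cfp` (per-subject CFP
#'   table) and `report` (the [cohort_report()]).
#' @export
run_demo_study <- function(seed = 1, n_subjects = 19, bank_seed = 42,
                           combination = c("euclidean", "normalized_euclidean"),
                           n_realizations = 50) {
  combination <- match.arg(combination)
  cohorts <- generate_demo_cohorts(seed = seed, n_subjects = n_subjects)
  bank <- reference_bank(
    length(rr_intervals(cohorts$series[[1]])),
    n_realizations = n_realizations, seed = bank_seed
  )
  scored <- score_cohort(cohorts$series, bank = bank)
  cfp <- compute_cfp(scored, combination = combination)
  list(
    cohorts = cohorts,
    cfp = cfp,
    report = cohort_report(cfp)
  )
}
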