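#' RR-interval series
#'
#' An `rr_series` is a tibble with one row per beat (`beat`, `rr`) carrying
#' provenance attributes: the subject label, cohort group, the raw beat count
#' before artefact filtering, and the indices of removed beats. The sinus
#' fraction `n_clean / n_raw` and the study eligibility rule (at least 1000
#' clean beats, more than 95% sinus rhythm) are derived from these.
#'
#' @param rr Numeric vector of interbeat intervals in milliseconds; all
#'   values must be finite and strictly positive.
#' @param subject_id Opaque subject label.
#' @param group Cohort group: `"normal"`, `"copd"` or `"unknown"`.
#' @param n_raw Beat count before any filtering (defaults to `length(rr)`).
#' @param removed Integer indices (into the raw series) of beats removed by
#'   filtering.
#'
#' @return A tibble of class `rr_series` with columns `beat` and `rr`.
#' @seealso [read_rr()], [filter_artefacts()], [take_window()]
#' @export
#' @examples
#' s <- rr_series(c(800, 810, 795), subject_id = "demo")
#' sinus_fraction(s)
rr_series <- function(rr, subject_id = "unknown",
                      group = c("unknown", "normal", "copd"),
                      n_raw = length(rr), removed = integer()) {
  group <- match.arg(group)
  rr <- as.numeric(rr)
  if (length(rr) == 0L) {
    abort("an rr_series needs at least one interval")
  }
  bad <- which(!is.finite(rr) | rr <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "all RR intervals must be finite and > 0 ms; first offender at beat %d (value %s)",
      bad[1], format(rr[bad[1]])
    ))
  }
  out <- new_tibble(
    list(beat = seq_along(rr), rr = rr),
    nrow = length(rr),
    class = "rr_series",
    subject_id = as.character(subject_id),
    group = group,
    n_raw = as.integer(n_raw),
    removed = as.integer(removed)
  )
  out
}

#' @rdname rr_series
#' @param x An `rr_series` (or, for `rr_intervals()`, any numeric vector,
#'   returned as-is).
#' @export
rr_intervals <- function(x) {
  if (inherits(x, "rr_series")) x$rr else as.numeric(x)
}

#' @rdname rr_series
#' @export
n_raw <- function(x) attr(x, "n_raw") %||% nrow(x)

#' @rdname rr_series
#' @export
sinus_fraction <- function(x) nrow(x) / n_raw(x)

#' @rdname rr_series
#' @param min_beats,min_sinus Eligibility thresholds: the study standard is
#'   at least 1000 clean beats and a sinus fraction above 0.95.
#' @export
is_eligible <- function(x, min_beats = 1000, min_sinus = 0.95) {
  nrow(x) >= min_beats && sinus_fraction(x) > min_sinus
}

#' Read an RR-interval series from a plain-text export
#'
#' Reads the beat-to-beat text files exported by HR monitors: either one RR
#' interval (milliseconds) per line, or a two-column whitespace-separated
#' dialect (elapsed time, RR) from which the second column is taken.
#' Non-numeric lines (headers, trailing blanks) are skipped with a message;
#' an interval that parses but is non-positive or non-finite is a hard error
#' naming the line.
#'
#' @param path Path to the text file.
#' @param dialect `"one-column"` or `"two-column"`.
#' @inheritParams rr_series
#' @return An [rr_series()].
#' @export
read_rr <- function(path, dialect = c("one-column", "two-column"),
                    subject_id = NULL, group = c("unknown", "normal", "copd")) {
  dialect <- match.arg(dialect)
  group <- match.arg(group)
  if (!file.exists(path)) {
    abort(sprintf("RR file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  fields <- if (dialect == "one-column") {
    trimws(lines)
  } else {
    vapply(strsplit(trimws(lines), "[[:space:]]+"), function(f) {
      if (length(f) >= 2) f[[2]] else if (length(f) == 1) f[[1]] else ""
    }, character(1))
  }
  suppressWarnings(vals <- as.numeric(fields))
  numeric_line <- !is.na(vals) & nzchar(fields)
  n_skipped <- sum(!numeric_line)
  if (!any(numeric_line)) {
    abort(sprintf("no numeric RR intervals found in %s", path))
  }
  bad <- which(numeric_line & (vals <= 0 | !is.finite(vals)))
  if (length(bad) > 0L) {
    abort(sprintf(
      "non-positive or non-finite RR interval at line %d of %s: %s",
      bad[1], path, fields[bad[1]]
    ))
  }
  if (n_skipped > 0L) {
    inform(sprintf("read_rr: skipped %d non-numeric line(s) in %s", n_skipped, path))
  }
  rr_series(
    vals[numeric_line],
    subject_id = subject_id %||% tools::file_path_sans_ext(basename(path)),
    group = group
  )
}

#' Remove ectopic beats and artefacts with a moving-median filter
#'
#' Replaces the study's manual artefact editing with a deterministic rule
#' standard in HRV preprocessing: a beat is flagged artefactual when it
#' deviates from the centred moving median of its neighbours by more than a
#' fraction of that median. Flagged beats are deleted (not interpolated),
#' because all downstream spectra treat beats as unit-spaced samples.
#'
#' @param series An [rr_series()].
#' @param threshold_pct Maximum allowed fractional deviation from the local
#'   median (default 0.20, i.e. 20%).
#' @param window Centred moving-median window in beats (odd; default 11).
#' @return A filtered [rr_series()]; `n_raw` is carried over so the sinus
#'   fraction reflects all removals since reading.
#' @export
filter_artefacts <- function(series, threshold_pct = 0.20, window = 11) {
  stopifnot(inherits(series, "rr_series"))
  if (window %% 2 != 1 || window < 3) {
    abort("`window` must be an odd integer >= 3")
  }
  if (nrow(series) < window) {
    abort(sprintf(
      "series of %d beats is shorter than the %d-beat filter window",
      nrow(series), window
    ))
  }
  rr <- series$rr
  med <- runmed(rr, k = window, endrule = "median")
  flagged <- abs(rr - med) > threshold_pct * med
  keep <- !flagged
  prior_removed <- attr(series, "removed")
  # map removals back to raw-series indices where possible
  raw_idx <- setdiff(seq_len(n_raw(series)), prior_removed)
  removed_now <- if (length(raw_idx) == nrow(series)) {
    raw_idx[flagged]
  } else {
    which(flagged)
  }
  rr_series(
    rr[keep],
    subject_id = attr(series, "subject_id"),
    group = attr(series, "group"),
    n_raw = n_raw(series),
    removed = sort(unique(c(prior_removed, removed_now)))
  )
}

#' Take the analysis window of clean beats
#'
#' The analyses operate on exactly `n` clean intervals (study standard:
#' 1000). The window is the first or last `n` beats of the cleaned series.
#'
#' @inheritParams filter_artefacts
#' @param n Number of beats to keep (default 1000).
#' @param anchor Take the `"first"` (default) or `"last"` `n` beats.
#' @return An [rr_series()] of exactly `n` beats.
#' @export
take_window <- function(series, n = 1000, anchor = c("first", "last")) {
  stopifnot(inherits(series, "rr_series"))
  anchor <- match.arg(anchor)
  if (nrow(series) < n) {
    abort(sprintf(
      "need %d clean beats but only %d available (shortfall %d)",
      n, nrow(series), n - nrow(series)
    ))
  }
  idx <- if (anchor == "first") seq_len(n) else seq.int(nrow(series) - n + 1L, nrow(series))
  rr_series(
    series$rr[idx],
    subject_id = attr(series, "subject_id"),
    group = attr(series, "group"),
    n_raw = n_raw(series),
    removed = attr(series, "removed")
  )
}

#' Write a cleaned series back to one-column text
#'
#' Writes one interval per line, plus (optionally) a JSON sidecar recording
#' `n_raw`, `n_clean`, `sinus_fraction` and the removed raw indices.
#'
#' @inheritParams filter_artefacts
#' @param path Output text file.
#' @param sidecar Write `<path>.json` with provenance (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_rr <- function(series, path, sidecar = TRUE) {
  stopifnot(inherits(series, "rr_series"))
  writeLines(format(series$rr, trim = TRUE, scientific = FALSE, digits = 15), path)
  if (isTRUE(sidecar)) {
    meta <- list(
      subject_id = attr(series, "subject_id"),
      group = attr(series, "group"),
      n_raw = n_raw(series),
      n_clean = nrow(series),
      sinus_fraction = sinus_fraction(series),
      eligible = is_eligible(series),
      removed = attr(series, "removed")
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> subject %s (%s): %d clean / %d raw beats, sinus fraction %.3f%s\n",
    attr(x, "subject_id"), attr(x, "group"), nrow(x), n_raw(x),
    sinus_fraction(x), if (is_eligible(x)) ", eligible" else ""
  ))
  NextMethod()
}
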