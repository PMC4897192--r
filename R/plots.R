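#' Plot a power spectrum
#'
#' Power against frequency (cycles per beat) on a log10 power scale, the
#' way HRV spectra are usually displayed.
#'
#' @param object A [psd_estimate].
#' @param log `TRUE` (default) for log10 power.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psd_estimate
#' @export
autoplot.psd_estimate <- function(object, log = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "frequency (cycles/beat)",
      y = "power spectral density",
      title = sprintf("%s spectrum", toupper(psd_method(object)))
    )
  if (isTRUE(log)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an RR series
#'
#' @param object An [rr_series()].
#' @param ... Unused.
#' @return A ggplot of RR interval against beat number.
#' @method autoplot rr_series
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beat, y = .data$rr)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "beat",
      y = "RR interval (ms)",
      title = sprintf("subject %s (%s)", attr(object, "subject_id"), attr(object, "group"))
    )
}

#' Scree plot of a CFP PCA
#'
#' @param object A `cfp_pca` from [pca_correlation()].
#' @param ... Unused.
#' @return A ggplot of eigenvalue per component with cumulative share.
#' @method autoplot cfp_pca
#' @export
autoplot.cfp_pca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(
      y = .data$cumulative * max(d$eigenvalue), group = 1
    ), linetype = 2) +
    ggplot2::labs(
      x = NULL, y = "eigenvalue",
      title = "correlation-matrix PCA of the seven CFPs",
      subtitle = "dashed: cumulative variance share (scaled)"
    )
}

#' Quartile comparison plot of a cohort report
#'
#' Q1-Q3 ranges per CFP and group (the numeric content of the study's
#' boxplot figures), with significant CFPs marked.
#'
#' @param object A [cohort_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  g <- object$groups
  d <- dplyr::bind_rows(
    tibble(
      cfp = object$table$cfp, group = g[1],
      q1 = object$table[[paste0("q1_", g[1])]],
      q3 = object$table[[paste0("q3_", g[1])]],
      mean = object$table[[paste0("mean_", g[1])]]
    ),
    tibble(
      cfp = object$table$cfp, group = g[2],
      q1 = object$table[[paste0("q1_", g[2])]],
      q3 = object$table[[paste0("q3_", g[2])]],
      mean = object$table[[paste0("mean_", g[2])]]
    )
  )
  sig <- object$table$cfp[object$table$significant]
  d$cfp_label <- ifelse(d$cfp %in% sig, paste0(d$cfp, " *"), d$cfp)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cfp_label, colour = .data$group)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
      position = ggplot2::position_dodge(width = 0.5), linewidth = 1.2
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$mean),
      position = ggplot2::position_dodge(width = 0.5), shape = 3, size = 2
    ) +
    ggplot2::labs(
      x = NULL, y = "CFP value",
      title = "Q1-Q3 range and mean (+) per CFP and group",
      subtitle = sprintf("* Kruskal-Wallis p < %g", object$alpha)
    )
}
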