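#' Tidy a correlation-matrix PCA
#'
#' @param x A `cfp_pca` from [pca_correlation()].
#' @param matrix `"eigenvalues"` (default) for one row per component, or
#'   `"loadings"` for one row per variable-component pair.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cfp_pca
#' @export
tidy.cfp_pca <- function(x, matrix = c("eigenvalues", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    tibble(
      component = paste0("PC", seq_along(x$eigenvalues)),
      eigenvalue = x$eigenvalues,
      proportion = x$proportion,
      cumulative = x$cumulative
    )
  } else {
    as_tibble(as.data.frame(x$loadings), rownames = "variable") |>
      tidyr::pivot_longer(-"variable", names_to = "component", values_to = "loading")
  }
}

#' @rdname tidy.cfp_pca
#' @return For `glance()`: a one-row tibble with the subject count,
#'   variable count, first-component variance share and the share covered
#'   by the first two components.
#' @method glance cfp_pca
#' @export
glance.cfp_pca <- function(x, ...) {
  tibble(
    n = x$n,
    n_vars = length(x$vars),
    pc1_eigenvalue = x$eigenvalues[1],
    pc1_proportion = x$proportion[1],
    pc2_cumulative = x$cumulative[2]
  )
}

#' Tidy a cohort report
#'
#' @param x A `cohort_report` from [cohort_report()].
#' @param ... Unused.
#' @return The per-CFP comparison table (quartiles, IQR, mean/SD per
#'   group, Kruskal-Wallis p, significance flag), one row per CFP.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) {
  x$table
}

#' @rdname tidy.cohort_report
#' @return For `glance()`: one row with group sizes, the number of CFPs
#'   significant at `alpha`, and which group shows the larger median IQR.
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  iqr_cols <- paste0("iqr_", x$groups)
  tibble(
    group_a = x$groups[1],
    group_b = x$groups[2],
    n_a = x$n[1],
    n_b = x$n[2],
    alpha = x$alpha,
    n_significant = sum(x$table$significant),
    median_iqr_a = stats::median(x$table[[iqr_cols[1]]]),
    median_iqr_b = stats::median(x$table[[iqr_cols[2]]]),
    combination = x$combination
  )
}
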