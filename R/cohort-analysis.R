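#' Quartiles by the (n+1) interpolation rule
#'
#' First and third quartiles using the `(n+1)p` linear-interpolation
#' convention (`stats::quantile` type 6), the rule used by the clinical
#' statistics software family this literature reports with. Quartile
#' summaries are rule-sensitive, so the rule is exposed.
#'
#' @param values Numeric sample, `n >= 3`.
#' @param type Quantile algorithm passed to [stats::quantile()] (default 6).
#' @return A named numeric vector `c(q1 = ..., q3 = ...)`.
#' @export
#' @examples
#' quartile_summary(1:5) # q1 = 1.5, q3 = 4.5
quartile_summary <- function(values, type = 6) {
  values <- as.numeric(values)
  if (length(values) < 3) {
    abort("quartiles need at least 3 observations")
  }
  q <- quantile(values, probs = c(0.25, 0.75), type = type, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' Two-group Kruskal-Wallis test
#'
#' Rank-based test of location between two cohorts (chi-square
#' approximation with 1 degree of freedom, midranks and the standard tie
#' correction). Retained in its Kruskal-Wallis form — rather than a
#' Mann-Whitney substitute — to mirror the study's analysis. Two samples
#' with all observations identical give `H = 0`, `p = 1`.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return A one-row tibble: `statistic` (H), `p_value`, `method`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3), c(4, 5, 6)) # H = 3.857
kruskal_wallis <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 observations")
  }
  if (length(unique(c(a, b))) == 1L) {
    return(tibble(statistic = 0, p_value = 1, method = "kruskal_wallis"))
  }
  kt <- kruskal.test(list(a, b))
  tibble(
    statistic = unname(kt$statistic),
    p_value = unname(kt$p.value),
    method = "kruskal_wallis"
  )
}

#' Ryan-Joiner correlation test of normality
#'
#' The Ryan-Joiner statistic is the Pearson correlation between the
#' ordered sample and Blom normal scores `qnorm((i - 3/8) / (n + 1/4))`;
#' values near 1 indicate normality. Its square is exactly the
#' Shapiro-Francia W' statistic (which uses the same plotting positions),
#' so the p-value is taken from Royston's validated approximation of the
#' W' null distribution (valid for 5 <= n <= 5000). The published
#' interpolation tables for the correlation form are accurate only up to
#' n of about 100 — their fitted critical values exceed 1 beyond that —
#' which is why the equivalent W' route is used for the p-value.
#'
#' @param values Numeric sample, `n >= 8`, non-constant.
#' @return A one-row tibble: `statistic`, `p_value`, `method`.
#' @export
ryan_joiner <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 8) {
    abort("Ryan-Joiner test needs at least 8 observations")
  }
  if (sd(x) == 0) {
    abort("Ryan-Joiner test is undefined for a zero-variance sample")
  }
  scores <- qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  r <- cor(x, scores)
  sf <- nortest::sf.test(x)
  tibble(
    statistic = r,
    p_value = unname(sf$p.value),
    method = "ryan_joiner"
  )
}

#' Normality screens: Anderson-Darling and Ryan-Joiner
#'
#' The two tests the study screens each CFP with before falling back to
#' nonparametric comparison: Anderson-Darling (empirical-CDF based, via
#' \pkg{nortest}) and Ryan-Joiner (correlation based, see
#' [ryan_joiner()]).
#'
#' @param values Numeric sample, `n >= 8`, non-constant.
#' @return A two-row tibble: `method`, `statistic`, `p_value`.
#' @export
normality_screen <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8) {
    abort("normality screens need at least 8 observations")
  }
  if (sd(values) == 0) {
    abort("normality screens are undefined for a zero-variance sample")
  }
  ad <- nortest::ad.test(values)
  rj <- ryan_joiner(values)
  dplyr::bind_rows(
    tibble(
      method = "anderson_darling",
      statistic = unname(ad$statistic),
      p_value = unname(ad$p.value)
    ),
    rj[, c("method", "statistic", "p_value")]
  )
}

#' Variance shares of PCA eigenvalues
#'
#' Converts eigenvalues to proportions of total variance and cumulative
#' shares. For a correlation-matrix PCA the total is the number of
#' variables (the trace of the correlation matrix), which may exceed the
#' number of eigenvalues supplied when only the leading components are of
#' interest.
#'
#' @param eigenvalues Nonnegative eigenvalues, in the order of interest.
#' @param total Total variance (default `sum(eigenvalues)`; use the
#'   variable count for a partial set from a correlation-matrix PCA).
#' @return A tibble: `eigenvalue`, `proportion`, `cumulative`.
#' @export
#' @examples
#' variance_shares(c(4.1588, 2.8078), total = 7)
variance_shares <- function(eigenvalues, total = sum(eigenvalues)) {
  if (any(eigenvalues < 0) || total <= 0) {
    abort("eigenvalues must be nonnegative and total positive")
  }
  tibble(
    eigenvalue = eigenvalues,
    proportion = eigenvalues / total,
    cumulative = cumsum(eigenvalues) / total
  )
}

#' Correlation-matrix PCA of the seven CFPs
#'
#' Principal component analysis of the subjects-by-CFP grid of one group:
#' each CFP column is standardized (mean 0, SD 1, `n - 1` denominator) and
#' the 7x7 correlation matrix is eigendecomposed, so eigenvalues sum to
#' the number of variables and `proportion = eigenvalue / n_vars`. The
#' loading sign convention fixes the largest-magnitude coefficient of each
#' component positive, making tables reproducible (published loadings may
#' use any sign convention).
#'
#' @param data Data frame with one row per subject.
#' @param cols Character vector of the variable columns (default
#'   `cfp1`..`cfp7`).
#' @return An object of class `cfp_pca`: eigenvalues, loadings (variables
#'   x components), proportion and cumulative variance shares, scores,
#'   `n` (subjects) and `vars`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
pca_correlation <- function(data, cols = paste0("cfp", 1:7)) {
  data <- as_tibble(data)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing variable columns: ", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[cols])
  if (nrow(X) < 2) {
    abort("PCA needs at least 2 subjects")
  }
  if (any(!is.finite(X))) {
    abort("PCA input contains missing or non-finite values")
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "zero-variance column(s): ", paste(cols[sds == 0], collapse = ", ")
    ))
  }
  Z <- scale(X)
  C <- cor(X)
  eg <- eigen(C, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  L <- eg$vectors
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(cols, paste0("PC", seq_along(cols)))
  shares <- variance_shares(values)
  structure(
    list(
      eigenvalues = values,
      loadings = L,
      proportion = shares$proportion,
      cumulative = shares$cumulative,
      scores = Z %*% L,
      n = nrow(X),
      vars = cols
    ),
    class = "cfp_pca"
  )
}

#' @export
print.cfp_pca <- function(x, ...) {
  cat(sprintf(
    "<cfp_pca> %d subjects x %d variables (correlation matrix)\n",
    x$n, length(x$vars)
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Cohort comparison report
#'
#' The study's full statistical layer over a scored cohort table: for each
#' CFP, per-group quartiles (and interquartile ranges), per-group mean and
#' SD, the two-group Kruskal-Wallis p-value with a significance flag, plus
#' a correlation-matrix PCA per group and normality screens per group and
#' CFP. A pure function of its input: repeated calls are bit-identical.
#'
#' @param data A tibble with columns `group` plus `cfp1`..`cfp7` (one row
#'   per subject), e.g. from [score_cohort()] then [compute_cfp()].
#' @param groups Length-2 character vector naming the two groups to
#'   compare (default: reference group `"normal"` first, then the other
#'   group present).
#' @param alpha Significance level for flagging (default 0.05).
#' @param quartile_type Quantile rule (default 6, the `(n+1)` rule).
#' @return An object of class `cohort_report` with elements `table` (one
#'   row per CFP), `pca` (named list of [pca_correlation()] results),
#'   `normality` (per group and CFP), `groups`, `n`, `alpha` and
#'   `combination`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
cohort_report <- function(data, groups = NULL, alpha = 0.05, quartile_type = 6) {
  data <- as_tibble(data)
  cfps <- paste0("cfp", 1:7)
  missing_cols <- setdiff(c("group", cfps), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` must contain columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(as.matrix(data[cfps])))) {
    abort("CFP table contains missing values")
  }
  present <- unique(data$group)
  if (is.null(groups)) {
    groups <- if ("normal" %in% present) {
      c("normal", setdiff(present, "normal")[1])
    } else {
      present[1:2]
    }
  }
  if (length(groups) != 2 || !all(groups %in% present)) {
    abort("need exactly two groups present in `data`")
  }
  g1 <- data[data$group == groups[1], ]
  g2 <- data[data$group == groups[2], ]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    abort("each group needs at least 2 subjects")
  }
  rows <- purrr::map_dfr(cfps, function(v) {
    x1 <- g1[[v]]
    x2 <- g2[[v]]
    q1v <- quartile_summary(x1, type = quartile_type)
    q2v <- quartile_summary(x2, type = quartile_type)
    kw <- kruskal_wallis(x1, x2)
    tibble(
      cfp = v,
      q1_a = q1v[["q1"]], q3_a = q1v[["q3"]], iqr_a = q1v[["q3"]] - q1v[["q1"]],
      mean_a = base::mean(x1), sd_a = sd(x1),
      q1_b = q2v[["q1"]], q3_b = q2v[["q3"]], iqr_b = q2v[["q3"]] - q2v[["q1"]],
      mean_b = base::mean(x2), sd_b = sd(x2),
      kw_statistic = kw$statistic,
      p_value = kw$p_value,
      significant = kw$p_value < alpha
    )
  })
  names(rows) <- sub("_a$", paste0("_", groups[1]), names(rows))
  names(rows) <- sub("_b$", paste0("_", groups[2]), names(rows))
  pca <- lapply(stats::setNames(groups, groups), function(g) {
    pca_correlation(data[data$group == g, ], cols = cfps)
  })
  normality <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(cfps, function(v) {
      x <- data[data$group == g, ][[v]]
      if (length(x) >= 8 && sd(x) > 0) {
        dplyr::mutate(normality_screen(x), group = g, cfp = v, .before = 1)
      } else {
        tibble(
          group = g, cfp = v, method = c("anderson_darling", "ryan_joiner"),
          statistic = NA_real_, p_value = NA_real_
        )
      }
    })
  })
  structure(
    list(
      table = rows,
      pca = pca,
      normality = normality,
      groups = groups,
      n = c(nrow(g1), nrow(g2)),
      alpha = alpha,
      quartile_type = quartile_type,
      combination = if ("combination" %in% names(data)) unique(data$combination) else NA_character_
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %s (n = %d) vs %s (n = %d), alpha = %g\n",
    x$groups[1], x$n[1], x$groups[2], x$n[2], x$alpha
  ))
  print(x$table, ...)
  invisible(x)
}

#' Write a cohort report to CSV and JSON
#'
#' The CSV holds the per-CFP comparison table; the JSON additionally
#' carries group sizes, the significance level, the CFP combination used,
#' the normality screens and both PCA decompositions (audit trail: every
#' setting that shaped the numbers travels with them).
#'
#' @param report A [cohort_report()].
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_cohort_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  if (!is.null(csv)) {
    utils::write.csv(report$table, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(
      groups = report$groups,
      n = report$n,
      alpha = report$alpha,
      quartile_type = report$quartile_type,
      combination = report$combination,
      table = report$table,
      normality = report$normality,
      pca = lapply(report$pca, function(p) {
        list(
          eigenvalues = p$eigenvalues,
          proportion = p$proportion,
          cumulative = p$cumulative,
          loadings = as.data.frame(p$loadings),
          n = p$n
        )
      })
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(report)
}
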