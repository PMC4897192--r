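#' Chaotic Forward Parameters (CFP1-CFP7)
#'
#' Combines the three normalized chaotic globals into the seven CFPs, one
#' per non-empty subset of \{spectral entropy, sMTM, sDFA\}. Because sDFA
#' responds to chaotic content in the opposite direction to the other two
#' globals, its component enters as `1 - sdfa`; spectral entropy and sMTM
#' enter as-is, with equal weighting. The member sets are:
#'
#' * CFP1: se, sMTM, sDFA (all three)
#' * CFP2: se, sDFA
#' * CFP3: se, sMTM
#' * CFP4: sMTM, sDFA
#' * CFP5: sDFA alone
#' * CFP6: sMTM alone
#' * CFP7: se alone
#'
#' Under the default `euclidean` combination, CFPk is the Euclidean norm
#' of its member components, so the single-member CFPs reduce to
#' `cfp7 = |se|`, `cfp6 = |smtm|`, `cfp5 = |1 - sdfa|`.
#' `normalized_euclidean` divides by the square root of the member count,
#' so that equal components give the same value at every subset size.
#' Components are not clipped: normalized globals slightly outside
#' `[0, 1]` propagate into the CFPs.
#'
#' @param data A data frame with numeric columns `se`, `sdfa`, `smtm`
#'   (e.g. from [score_cohort()]); other columns are preserved.
#' @param combination `"euclidean"` (default) or `"normalized_euclidean"`.
#' @return The input tibble with columns `cfp1`..`cfp7` and `combination`
#'   appended.
#' @export
#' @examples
#' compute_cfp(tibble::tibble(se = 0.4, sdfa = 0.3, smtm = 0.6))
compute_cfp <- function(data, combination = c("euclidean", "normalized_euclidean")) {
  combination <- match.arg(combination)
  data <- as_tibble(data)
  needed <- c("se", "sdfa", "smtm")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` must contain columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(data$se) | !is.finite(data$sdfa) | !is.finite(data$smtm))) {
    abort("chaotic globals must be finite to form CFPs")
  }
  c_se <- data$se
  c_dfa <- 1 - data$sdfa # sDFA responds oppositely: subtract from unity
  c_mtm <- data$smtm
  members <- cfp_members()
  comp <- list(se = c_se, sdfa = c_dfa, smtm = c_mtm)
  for (i in seq_along(members)) {
    mem <- members[[i]]
    ss <- Reduce(`+`, lapply(comp[mem], function(v) v^2))
    val <- sqrt(ss)
    if (combination == "normalized_euclidean") {
      val <- val / sqrt(length(mem))
    }
    data[[names(members)[i]]] <- val
  }
  data$combination <- combination
  data
}

#' @rdname compute_cfp
#' @return For `cfp_members()`: a named list mapping `cfp1`..`cfp7` to the
#'   chaotic globals each combines.
#' @export
cfp_members <- function() {
  list(
    cfp1 = c("se", "smtm", "sdfa"),
    cfp2 = c("se", "sdfa"),
    cfp3 = c("se", "smtm"),
    cfp4 = c("smtm", "sdfa"),
    cfp5 = "sdfa",
    cfp6 = "smtm",
    cfp7 = "se"
  )
}
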