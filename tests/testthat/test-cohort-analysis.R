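test_that("quartiles follow the (n+1) interpolation rule", {
  expect_equal(quartile_summary(1:5), c(q1 = 1.5, q3 = 4.5))
  expect_equal(quartile_summary(rep(3.2, 6)), c(q1 = 3.2, q3 = 3.2))
  expect_equal(quartile_summary(1:8), c(q1 = 2.25, q3 = 6.75))
  expect_error(quartile_summary(1:2), "at least 3")
})

test_that("Kruskal-Wallis H matches the hand-rank computation", {
  # ranks 1..6: R1 = 6, R2 = 15 -> H = 12/(6*7) * (36/3 + 225/3) - 3*7
  r <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 12 / 42 * (12 + 75) - 21, tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), 3.857)

  expect_equal(kruskal_wallis(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  same <- kruskal_wallis(c(2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(1, c(1, 2)), "at least 2")
})

test_that("tie-corrected H matches an exhaustive permutation oracle on the tie example", {
  a <- c(1, 1, 2)
  b <- c(1, 3, 3)
  pooled <- c(a, b)
  rk <- rank(pooled) # midranks
  # independent oracle: H computed from ranks for every one of the 20
  # assignments of 3-of-6 labels, with explicit tie correction
  h_from_ranks <- function(idx) {
    r1 <- rk[idx]
    r2 <- rk[-idx]
    n <- 6
    h <- 12 / (n * (n + 1)) * (sum(r1)^2 / 3 + sum(r2)^2 / 3) - 3 * (n + 1)
    ties <- table(pooled)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  combos <- utils::combn(6, 3)
  h_all <- apply(combos, 2, h_from_ranks)
  observed <- kruskal_wallis(a, b)$statistic
  expect_equal(observed, h_from_ranks(1:3), tolerance = 1e-12)
  # the observed statistic sits inside the exact permutation distribution
  expect_true(any(abs(h_all - observed) < 1e-12))
  # and the exact permutation p agrees in direction with the chi-square p
  p_exact <- mean(h_all >= observed - 1e-12)
  expect_gt(p_exact, 0.05)
  expect_gt(kruskal_wallis(a, b)$p_value, 0.05)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  withr::with_seed(19, {
    for (i in 1:5) {
      a <- rexp(12) + 0.1
      b <- rexp(15) + 0.3
      expect_equal(
        kruskal_wallis(a, b)$statistic,
        kruskal_wallis(log(a), log(b))$statistic,
        tolerance = 1e-12
      )
      expect_equal(
        kruskal_wallis(a, b)$statistic,
        kruskal_wallis(a^3, b^3)$statistic,
        tolerance = 1e-12
      )
    }
  })
})

test_that("normality screens behave under the null and a gross alternative", {
  expect_error(normality_screen(rep(1, 20)), "zero-variance")
  expect_error(normality_screen(rnorm(5)), "at least 8")

  set.seed(23)
  null_p <- replicate(200, normality_screen(rnorm(500))$p_value)
  expect_gte(mean(null_p[1, ] > 0.05), 0.90) # Anderson-Darling
  expect_gte(mean(null_p[2, ] > 0.05), 0.90) # Ryan-Joiner

  alt_p <- replicate(200, normality_screen(rnorm(500)^2)$p_value)
  expect_gte(mean(alt_p[1, ] < 0.05), 0.95)
  expect_gte(mean(alt_p[2, ] < 0.05), 0.95)

  # Ryan-Joiner statistic is a correlation, bounded by 1, and equals
  # sqrt of the Shapiro-Francia W' on the same sample
  x <- withr::with_seed(29, rnorm(60))
  rj <- ryan_joiner(x)
  expect_lte(rj$statistic, 1)
  expect_equal(rj$statistic^2, unname(nortest::sf.test(x)$statistic),
    tolerance = 1e-6
  )
})

test_that("correlation-matrix PCA has unit-trace structure and matches prcomp", {
  d <- withr::with_seed(31, {
    base <- matrix(rnorm(19 * 3), 19, 3)
    tibble::as_tibble(stats::setNames(
      as.data.frame(cbind(base, base %*% matrix(rnorm(12), 3, 4) + 0.3 * matrix(rnorm(19 * 4), 19, 4))),
      paste0("cfp", 1:7)
    ))
  })
  p <- pca_correlation(d)
  expect_equal(sum(p$eigenvalues), 7, tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(unname(crossprod(p$loadings)), diag(7), tolerance = 1e-8)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-12)

  ref <- prcomp(d, scale. = TRUE)
  expect_equal(p$eigenvalues, unname(ref$sdev^2), tolerance = 1e-10)
  expect_equal(abs(unname(unclass(p$loadings))), abs(unname(ref$rotation)), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading of each component is positive
  for (j in 1:7) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("PCA handles perfect correlation and rejects zero-variance columns", {
  d2 <- tibble::tibble(cfp1 = 1:10, cfp2 = 2 * (1:10) + 5)
  p2 <- pca_correlation(d2, cols = c("cfp1", "cfp2"))
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-12)

  dz <- tibble::tibble(cfp1 = rnorm(10), cfp2 = rep(1, 10))
  expect_error(pca_correlation(dz, cols = c("cfp1", "cfp2")), "cfp2")
})

test_that("PCA is invariant to affine rescaling of any input column", {
  d <- withr::with_seed(37, tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(19 * 7), 19, 7)), paste0("cfp", 1:7)
  )))
  p1 <- pca_correlation(d)
  d2 <- dplyr::mutate(d, cfp3 = 100 * .data$cfp3 - 7, cfp6 = 0.01 * .data$cfp6)
  p2 <- pca_correlation(d2)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-8)
})

test_that("variance shares convert eigenvalues to proportions of total variance", {
  vs <- variance_shares(c(4, 2, 1, 1))
  expect_equal(vs$proportion, c(0.5, 0.25, 0.125, 0.125))
  expect_equal(vs$cumulative[4], 1)
  partial <- variance_shares(c(4.2, 2.8), total = 7)
  expect_equal(partial$cumulative[2], 1)
  expect_error(variance_shares(c(-1, 2)), "nonnegative")
})

test_that("cohort_report assembles the full Table-1-style comparison", {
  cfp_tbl <- withr::with_seed(41, {
    d <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(runif(38 * 7), 38, 7)), paste0("cfp", 1:7)
    ))
    d$group <- rep(c("normal", "copd"), each = 19)
    d$cfp3[d$group == "copd"] <- d$cfp3[d$group == "copd"] - 0.5
    d
  })
  rep1 <- cohort_report(cfp_tbl)
  expect_equal(nrow(rep1$table), 7)
  expect_equal(rep1$groups, c("normal", "copd"))
  expect_true(rep1$table$significant[rep1$table$cfp == "cfp3"])
  expect_named(rep1$pca, c("normal", "copd"))
  expect_equal(nrow(rep1$normality), 28) # 2 groups x 7 CFPs x 2 tests

  # quartile columns agree with direct quartile_summary calls
  q <- quartile_summary(cfp_tbl$cfp1[cfp_tbl$group == "normal"])
  expect_equal(rep1$table$q1_normal[1], q[["q1"]])
  expect_equal(rep1$table$q3_normal[1], q[["q3"]])
  expect_equal(rep1$table$iqr_normal[1], q[["q3"]] - q[["q1"]])

  # pure function: a rerun is bit-identical
  rep2 <- cohort_report(cfp_tbl)
  expect_identical(rep1$table, rep2$table)
  expect_identical(rep1$pca$copd$eigenvalues, rep2$pca$copd$eigenvalues)

  # identical cohorts: no significance anywhere, p = 1
  same <- dplyr::bind_rows(
    dplyr::mutate(cfp_tbl[1:19, ], group = "normal"),
    dplyr::mutate(cfp_tbl[1:19, ], group = "copd")
  )
  rep_same <- cohort_report(same)
  expect_true(all(rep_same$table$p_value == 1))
  expect_false(any(rep_same$table$significant))

  expect_error(cohort_report(cfp_tbl[cfp_tbl$group == "normal", ]), "two groups")
})

test_that("tidiers and writers expose the report faithfully", {
  cfp_tbl <- withr::with_seed(43, {
    d <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(runif(20 * 7), 20, 7)), paste0("cfp", 1:7)
    ))
    d$group <- rep(c("normal", "copd"), each = 10)
    d$combination <- "euclidean"
    d
  })
  rep1 <- cohort_report(cfp_tbl)
  expect_identical(tidy(rep1), rep1$table)
  gl <- glance(rep1)
  expect_equal(gl$n_a, 10L)
  expect_equal(gl$combination, "euclidean")

  pca <- rep1$pca$normal
  td <- tidy(pca)
  expect_equal(td$eigenvalue, pca$eigenvalues)
  tl <- tidy(pca, matrix = "loadings")
  expect_equal(nrow(tl), 49)
  expect_equal(glance(pca)$pc1_proportion, pca$proportion[1])

  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cohort_report(rep1, csv = csv, json = js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 7)
  expect_equal(back$p_value, rep1$table$p_value, tolerance = 1e-12)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$alpha, 0.05)
  expect_equal(obj$pca$normal$eigenvalues, pca$eigenvalues, tolerance = 1e-9)
})
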