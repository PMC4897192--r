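test_that("Shannon entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(rep(1 / 128, 128)), log(128))
  expect_equal(shannon_entropy(c(1, rep(0, 9))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_error(shannon_entropy(c(0.7, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "nonnegative")
})

test_that("DFA recovers the theoretical exponents of noise and random walks", {
  set.seed(101)
  a_noise <- replicate(40, dfa_exponent(rnorm(4096)))
  expect_equal(mean(a_noise), 0.5, tolerance = 0.1) # 0.5 +/- 0.05 absolute
  expect_lt(abs(mean(a_noise) - 0.5), 0.05)
  a_walk <- replicate(40, dfa_exponent(cumsum(rnorm(4096))))
  expect_lt(abs(mean(a_walk) - 1.5), 0.1)
})

test_that("DFA is exactly scale invariant and rejects degenerate input", {
  y <- withr::with_seed(3, rnorm(256))
  expect_equal(
    as.numeric(dfa_exponent(3 * y)),
    as.numeric(dfa_exponent(y))
  )
  expect_error(dfa_exponent(rep(1, 256)), "degenerate fluctuation")
  expect_error(dfa_exponent(rnorm(256), box_sizes = c(2, 8)), "box sizes")
  expect_error(dfa_exponent(rnorm(256), box_sizes = c(8, 100)), "box sizes")
})

test_that("reference bank is reproducible and standardized", {
  b1 <- reference_bank(1000, seed = 5, n_realizations = 3)
  b2 <- reference_bank(1000, seed = 5, n_realizations = 3)
  expect_identical(b1, b2)
  expect_equal(mean(b1$z_sine), 0, tolerance = 1e-12)
  expect_equal(sd(b1$z_sine), 1, tolerance = 1e-12)
  expect_equal(colMeans(b1$z_random), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(b1$z_random, 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_warning(reference_bank(1000, sine_freq = 0.1234), "bin-centred")
})

test_that("the sine reference is the exact lower fixed point of all three globals", {
  sine_in <- reference_series(the_bank, "sine", mean = 800, sd = 50)
  # the affine map sends the sine reference to zero by construction; the
  # only slack is floating round-off from standardizing the rescaled copy
  expect_equal(spectral_entropy(sine_in, the_bank), 0, tolerance = 1e-12)
  expect_equal(sdfa(sine_in, the_bank), 0, tolerance = 1e-12)
  expect_equal(smtm(sine_in, the_bank), 0, tolerance = 1e-12)
})

test_that("uniform noise sits at the upper fixed point of all three globals", {
  se_vals <- vapply(1:25, function(i) {
    spectral_entropy(withr::with_seed(3000 + i, runif(1000)), the_bank)
  }, numeric(1))
  expect_lt(abs(mean(se_vals) - 1), 0.05)
  sdfa_vals <- vapply(1:25, function(i) {
    sdfa(withr::with_seed(3000 + i, runif(1000)), the_bank)
  }, numeric(1))
  expect_lt(abs(mean(sdfa_vals) - 1), 0.1)
  smtm_vals <- vapply(1:25, function(i) {
    smtm(withr::with_seed(3000 + i, runif(1000)), the_bank)
  }, numeric(1))
  expect_lt(abs(mean(smtm_vals) - 1), 0.1)
})

test_that("a noisy sine scores strictly between the fixed points", {
  x <- reference_series(the_bank, "sine", 800, 50) +
    withr::with_seed(17, rnorm(1000, sd = 10))
  se <- spectral_entropy(x, the_bank)
  expect_gt(se, 0)
  expect_lt(se, 1)
})

test_that("se and sdfa are exactly invariant to rescaling and shifts", {
  x <- make_rr_signal(23)
  g1 <- chaotic_globals(x, small_bank)
  g2 <- chaotic_globals(3 * x + 100, small_bank)
  expect_equal(g1$se, g2$se, tolerance = 1e-12)
  expect_equal(g1$sdfa, g2$sdfa, tolerance = 1e-12)
  expect_equal(g1$smtm, g2$smtm, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical globals", {
  x <- make_rr_signal(29)
  g1 <- chaotic_globals(x, reference_bank(1000, seed = 11, n_realizations = 5))
  g2 <- chaotic_globals(x, reference_bank(1000, seed = 11, n_realizations = 5))
  expect_identical(g1$se, g2$se)
  expect_identical(g1$sdfa, g2$sdfa)
  expect_identical(g1$smtm, g2$smtm)
})

test_that("se and sdfa stay in the soft range on cohort-like fixtures", {
  cohorts <- generate_demo_cohorts(seed = 4, n_subjects = 4)
  scored <- score_cohort(cohorts$series, bank = the_bank)
  expect_true(all(scored$se > -0.1 & scored$se < 1.1))
  expect_true(all(scored$sdfa > -0.1 & scored$sdfa < 1.1))
  expect_true(all(is.finite(scored$smtm)))
})

test_that("sdfa and se respond monotonically to the noise fraction of a mixture", {
  levels <- seq(0.05, 0.95, length.out = 8)
  mean_stat <- function(fun, offset) {
    vapply(levels, function(w) {
      mean(vapply(1:6, function(s) {
        x <- (1 - w) * the_bank$z_sine +
          w * withr::with_seed(offset + s + round(1000 * w), rnorm(1000))
        fun(x, the_bank)
      }, numeric(1)))
    }, numeric(1))
  }
  m_sdfa <- mean_stat(sdfa, 5000)
  expect_gt(abs(cor(m_sdfa, levels, method = "spearman")), 0.9)
  m_se <- mean_stat(spectral_entropy, 6000)
  expect_gt(abs(cor(m_se, levels, method = "spearman")), 0.9)
})

test_that("raw multitaper area increases with added broadband noise", {
  i <- seq_len(1000)
  sine <- 800 + 30 * sin(2 * pi * 0.125 * i)
  lv <- c(5, 15, 30, 50, 80)
  areas <- vapply(lv, function(sg) {
    mean(vapply(1:6, function(s) {
      x <- sine + withr::with_seed(s * 37 + sg, rnorm(1000, sd = sg))
      smtm_area(mtm_psd(x))
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(areas), seq_along(lv)) # strictly increasing means
  # and likewise on the literal power scale
  areas_pow <- vapply(lv, function(sg) {
    mean(vapply(1:4, function(s) {
      x <- sine + withr::with_seed(s * 41 + sg, rnorm(1000, sd = sg))
      smtm_area(mtm_psd(x), scale = "power")
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(areas_pow), seq_along(lv))
})

test_that("constant series and mismatched banks are rejected", {
  expect_error(spectral_entropy(rep(800, 1000), the_bank), "constant")
  expect_error(spectral_entropy(make_rr_signal(1, n = 512), the_bank), "length")
})
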