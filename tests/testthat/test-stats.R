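test_that("mean_ci matches the hand-computed t interval", {
  expect_equal(mean_ci(c(5, 5, 5, 5)), c(mean = 5, low = 5, high = 5))

  ci <- mean_ci(1:5)
  half <- stats::qt(0.975, 4) * sqrt(2.5) / sqrt(5)
  expect_equal(unname(ci), c(3, 3 - half, 3 + half), tolerance = 1e-12)
  expect_equal(unname(ci["low"]), 1.037, tolerance = 1e-3)
  expect_equal(unname(ci["high"]), 4.963, tolerance = 1e-3)

  expect_error(mean_ci(3), "2 values")
})

test_that("confidence intervals achieve nominal coverage", {
  set.seed(31)
  covered <- vapply(1:1000, function(i) {
    x <- stats::rnorm(10, mean = 2)
    ci <- mean_ci(x)
    ci[["low"]] <= 2 && 2 <= ci[["high"]]
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.02)
})

test_that("unpaired t-test matches the textbook pooled formula", {
  same <- t_test_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  shifted <- t_test_unpaired(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 0.001)

  # reference-formula oracle on random draws
  set.seed(5)
  for (i in 1:100) {
    a <- stats::rnorm(sample(3:12, 1)); b <- stats::rnorm(sample(3:12, 1))
    got <- t_test_unpaired(a, b)
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
      (n1 + n2 - 2)
    tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    pref <- 2 * stats::pt(-abs(tref), n1 + n2 - 2)
    expect_equal(got$t_statistic, tref, tolerance = 1e-10)
    expect_equal(got$p_value, pref, tolerance = 1e-10)
    # swapping groups negates t and preserves p
    sw <- t_test_unpaired(b, a)
    expect_equal(sw$t_statistic, -got$t_statistic, tolerance = 1e-10)
    expect_equal(sw$p_value, got$p_value, tolerance = 1e-12)
  }

  w <- t_test_unpaired(stats::rnorm(5), stats::rnorm(7), flavor = "welch")
  expect_identical(w$test_flavor, "welch")
  expect_error(t_test_unpaired(1, c(1, 2)), "2 values")

  # zero-variance convention
  expect_equal(t_test_unpaired(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(t_test_unpaired(c(2, 2), c(3, 3))$p_value, 0)
})

test_that("t-test type-I error is calibrated at the 5% level", {
  set.seed(77)
  rejections <- vapply(1:5000, function(i) {
    t_test_unpaired(stats::rnorm(12), stats::rnorm(10))$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.01)
})

test_that("ANOVA with Sidak correction follows the closed form", {
  set.seed(9)
  groups <- list(a = stats::rnorm(6), b = stats::rnorm(6) + 1,
                 c = stats::rnorm(6))
  out <- anova_sidak(groups)
  m <- nrow(out$comparisons)
  expect_identical(m, 3L)
  expect_equal(out$comparisons$p_adjusted,
               pmin(1, 1 - (1 - out$comparisons$p_raw)^m),
               tolerance = 1e-12)
  expect_true(all(out$comparisons$p_adjusted >=
                    out$comparisons$p_raw - 1e-15))

  # ANOVA F and p agree with stats::aov
  y <- unlist(groups); g <- factor(rep(names(groups), each = 6))
  s <- summary(stats::aov(y ~ g))[[1]]
  expect_equal(out$f_statistic, s[["F value"]][1], tolerance = 1e-10)
  expect_equal(out$p_value, s[["Pr(>F)"]][1], tolerance = 1e-10)

  # hand check of the Sidak arithmetic at the spec'd magnitudes
  expect_equal(1 - (1 - 0.01)^5, 0.0490, tolerance = 1e-3)

  # m = 1: adjusted equals raw
  one <- anova_sidak(groups, comparisons = list(c("a", "b")))
  expect_equal(one$comparisons$p_adjusted, one$comparisons$p_raw,
               tolerance = 1e-12)

  # degenerate all-constant input
  flat <- anova_sidak(list(a = c(1, 1), b = c(1, 1)))
  expect_equal(flat$p_value, 1)
  expect_error(anova_sidak(list(a = 1:3)), "2 groups")
  expect_error(anova_sidak(groups, comparisons = list()), "empty")
})

test_that("alteration concordance counts strict HH excess", {
  alt <- data.frame(g1 = c(1, 1, 0, 0), g2 = c(1, 0, 1, 0),
                    row.names = paste0("p", 1:4))
  calls <- data.frame(patient = paste0("p", 1:4),
                      group = c("HH", "HH", "HL", "HL"))
  out <- alteration_concordance(alt, calls)
  expect_identical(out$concordant_count, 1L + 0L)  # g1 strict, g2 tie
  expect_identical(out$total, 2L)
  expect_equal(out$per_gene$freq_HH, c(1, 0.5))
  expect_equal(out$per_gene$freq_HL, c(0, 0.5))

  # invariant under patient reordering
  perm <- sample.int(4)
  out2 <- alteration_concordance(alt[perm, ], calls)
  expect_identical(out2$concordant_count, out$concordant_count)

  expect_error(alteration_concordance(alt, calls, genes = c("g1", "gX")),
               "gX")
})
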