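test_that("goodness of fit reproduces the published backcross statistics", {
  # 13 yellow vs 5 fuzzy against 1:1 — the rejected single-locus expectation
  t11 <- chisq_gof(c(yellow = 13, f1_like = 5), c(yellow = 1, f1_like = 1))
  expect_equal(t11$statistic, 32 / 9, tolerance = 1e-12)
  expect_equal(format_signif(t11$statistic, 3), 3.56)
  expect_equal(t11$df, 1L)
  expect_equal(t11$p, 0.05934644, tolerance = 1e-6)

  # the same counts against the two-locus 1:3 expectation
  t13 <- chisq_gof(c(f1_like = 5, yellow = 13), c(f1_like = 1, yellow = 3))
  expect_equal(t13$statistic, 0.07407407, tolerance = 1e-6)
  expect_equal(format_signif(t13$statistic, 2), 0.074)
  expect_equal(t13$p, 0.7854947, tolerance = 1e-6)

  # perfect fit
  t0 <- chisq_gof(c(a = 10, b = 10), c(a = 1, b = 1))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
})

test_that("no continuity correction: agrees with stats::chisq.test(correct = FALSE)", {
  cases <- list(list(o = c(a = 13, b = 5), r = c(a = 1, b = 1)),
                list(o = c(a = 5, b = 13), r = c(a = 1, b = 3)),
                list(o = c(a = 33, b = 36), r = c(a = 1, b = 1)),
                list(o = c(a = 10, b = 30, c = 20), r = c(a = 1, b = 2, c = 1)))
  for (cs in cases) {
    mine <- chisq_gof(cs$o, cs$r)
    ref <- suppressWarnings(stats::chisq.test(cs$o, p = cs$r / sum(cs$r),
                                              correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-12)
  }
  # the uncorrected 13:5 statistic is 3.56; Yates-corrected would be 2.72
  expect_equal(format_signif(chisq_gof(c(a = 13, b = 5),
                                       c(a = 1, b = 1))$statistic, 3), 3.56)
})

test_that("gof is invariant to category order and ratio scaling; errors are typed", {
  a <- chisq_gof(c(x = 7, y = 21), c(x = 1, y = 3))
  b <- chisq_gof(c(y = 21, x = 7), c(y = 6, x = 2))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
  expect_error(chisq_gof(c(x = 1), c(x = 1, y = 0)), "positive")
  expect_error(chisq_gof(c(x = 1, z = 1), c(x = 1, y = 1)), "absent from hypothesis")
  expect_error(chisq_gof(c(x = 0, y = 0), c(x = 1, y = 1)), "at least 1")
  expect_error(chisq_gof(c(x = 1.5, y = 1), c(x = 1, y = 1)), "integers")
})

test_that("chi-square upper tail matches closed form and numerical integration", {
  expect_equal(chisq_upper_tail(3.556, 1), 0.0593, tolerance = 1e-3)
  expect_equal(chisq_upper_tail(0.0741, 1), 0.785, tolerance = 1e-3)
  expect_equal(chisq_upper_tail(0, 1), 1)
  # df = 1 closed form via the normal tail
  for (x in c(0.1, 1, 3.84, 13.09)) {
    expect_equal(chisq_upper_tail(x, 1), 2 * (1 - pnorm(sqrt(x))),
                 tolerance = 1e-12)
  }
  # independent numerical integration of the density
  for (df in c(1, 2, 5)) {
    for (x in c(0.5, 2, 8)) {
      num <- stats::integrate(stats::dchisq, x, Inf, df = df,
                              rel.tol = 1e-12)$value
      expect_equal(chisq_upper_tail(x, df), num, tolerance = 1e-8)
    }
  }
  expect_error(chisq_upper_tail(1, 0), "positive integer")
  expect_error(chisq_upper_tail(-1, 1), "non-negative")
})

test_that("co-segregation probability is (1/2)^n with the published printing", {
  c21 <- cosegregation_probability(21)
  expect_equal(c21$probability, 0.5^21)
  expect_equal(format_signif(c21$probability, 2, "truncate"), 4.7e-7) # as printed
  expect_equal(format_signif(c21$probability, 2, "round"), 4.8e-7)
  c15 <- cosegregation_probability(15)
  expect_equal(format_signif(c15$probability, 1), 3e-5)
  expect_equal(cosegregation_probability(0)$probability, 1)
  expect_error(cosegregation_probability(-1), "non-negative")
  # strictly halving per added informative individual, exactly
  for (n in 0:30) {
    expect_identical(cosegregation_probability(n + 1)$probability,
                     cosegregation_probability(n)$probability / 2)
  }
})

test_that("co-segregation counting uses definite calls and detects imperfection", {
  b14 <- brood_fixture("L14")
  cr <- coseg_test(b14, "Cr")
  expect_equal(cr$n, 21L)
  expect_true(attr(cr, "perfect"))
  expect_equal(cr$probability, 0.5^21)
  # Sd shows no association: same individuals, association not perfect
  sd <- coseg_test(b14, "Sd")
  expect_equal(sd$n, 21L)
  expect_false(attr(sd, "perfect"))
  expect_true(is.na(sd$probability))
  # melpomene brood: classify by inherited paternal allele
  b13 <- brood_fixture("L13")
  yb <- coseg_test(b13, "Yb", classify = "paternal_allele")
  expect_equal(yb$n, 15L)
  expect_true(attr(yb, "perfect"))
  expect_equal(format_signif(yb$probability, 1), 3e-5)
})

test_that("sex-ratio test reproduces the skewed melpomene brood and excludes unknowns", {
  skew <- sex_ratio_test(brood_fixture("L13"))
  expect_equal(skew$statistic, 288 / 22, tolerance = 1e-12) # 13.09
  expect_equal(format_signif(skew$statistic, 2), 13)
  expect_lt(skew$p, 0.001)
  expect_equal(skew$p, 2.967e-4, tolerance = 1e-3)

  even <- data.frame(id = as.character(1:5), cross_id = "x",
                     sex = c("female", "male", "female", "male", "unknown"),
                     phenotype = "YELLOW_BAR")
  t <- sex_ratio_test(brood_table(even, "x"))
  expect_equal(t$statistic, 0)
  expect_equal(sum(t$observed), 4) # unknown excluded
  none <- brood_table(data.frame(id = "1", cross_id = "x", sex = "unknown",
                                 phenotype = "YELLOW_BAR"), "x")
  expect_error(sex_ratio_test(none), "no sexed individuals")
})

test_that("both backcross broods are compatible with a 1:1 sex ratio", {
  for (id in c("L14", "L15")) {
    t <- sex_ratio_test(brood_fixture(id))
    expect_gt(t$p, 0.05)
  }
})

test_that("significant-figure truncation differs from rounding where expected", {
  expect_equal(format_signif(0.7855, 2, "truncate"), 0.78)
  expect_equal(format_signif(0.7855, 2, "round"), 0.79)
  expect_equal(format_signif(13.09, 2), 13)
  expect_equal(format_signif(-0.789, 2, "truncate"), -0.78)
  expect_equal(format_signif(0, 3, "truncate"), 0)
  expect_equal(format_signif(c(3.5556, 0.0741), 3), c(3.56, 0.0741))
})
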